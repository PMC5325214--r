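---
title: "Automated ROI extraction for phenocam time series: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ROI extraction for phenocam time series: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoroi)
```

# The problem

A fixed-view camera photographs the same landscape one to several times a
day across a year. The green chromatic coordinate of a pixel,
$\mathrm{GCC} = g/(r+g+b)$, rises at leaf-out and falls at senescence; the
mean GCC over a well-chosen region of interest (ROI) is a clean phenological
signal, while a badly chosen region (sky, roads, conifers) buries it.
`phenoroi` extracts informative ROIs automatically, by two complementary
routes, and ranks candidates with two optimality criteria.

The GCC ratio is the package's single greenness index. Averaging order
matters slightly and is fixed: per frame, GCC is computed per pixel and then
averaged over the ROI (not channel means first); frames sharing a
day-of-year (DOY) are then averaged into one daily value, so every
downstream window is indexed in calendar days. Missing days stay missing —
gaps are common in open-access archives and interpolation would manufacture
signal where there is none; all criteria therefore operate on observed days
only.

# Optimality criterion 1: change-point supF

The strongest, most localizable feature of a deciduous GCC year is the
spring green-up. OC1 keeps only DOYs $\le 240$ (dropping autumn, whose
coloring would otherwise compete with spring for the single change point)
and scans candidate change days $s \in [30, 210]$. For each $s$ a
4-parameter model — separate intercept and slope for days $< s$ and
$\ge s$ — is compared with the 2-parameter straight line:

$$F(s) = \frac{(\mathrm{RSS}_0 - \mathrm{RSS}_1(s))/k}{\mathrm{RSS}_1(s)/(n - 2k)},
\qquad k = 2 .$$

OC1 is $\max_s F(s)$. Design points:

* $n$ is the count of *observed* days actually used, not the constant 240,
  so gappy series remain scoreable.
* Candidates need at least 5 observed days on each side (configurable);
  boundary candidates otherwise make the 4-parameter fit singular.
* Exact fits: $\mathrm{RSS}_1 = 0$ with $\mathrm{RSS}_0 > 0$ gives
  $F = +\infty$, flagged via `exact_fit` but still comparable as a maximum;
  $\mathrm{RSS}_0 = \mathrm{RSS}_1 = 0$ (a perfect line) gives $F = 0$.
  Zero detection uses a relative tolerance of $10^{-12}$ on the series'
  total sum of squares.
* Ties take the earliest candidate day, for determinism.
* F is used purely as a ranking score; no significance calibration is
  attempted (none is needed to pick a maximum).

Both segment regressions are evaluated in closed form from first and second
moments; the test suite checks them against an independent normal-equations
brute force at every candidate day on random gappy series.

# Optimality criterion 2: template correlation

A deciduous GCC year has a known shape: flat winter, steep spring rise,
small post-peak dip, summer plateau, autumn decline, flat winter. OC2
encodes the shape as a piecewise-linear template parameterized by spring
onset $a$ and autumn end $b$, plus three shape parameters: peak day $c$,
plateau start $d$ and plateau end $e$, with
$a < c < d \le e < b$. The bank spans $a \in \{50,\dots,150\}$ and
$b \in \{265,\dots,365\}$ — 10 201 templates. OC2 of a series is its best
Pearson correlation over the bank, restricted to observed days; the winning
$(a, b)$ are rough SOS and EOS2 dates.

Shape defaults are $c = a + 20$, $d = c + 20$, $e = b - 60$, plateau level
0.7 of peak, winter level 0. Because Pearson correlation is invariant to
affine maps, absolute levels are immaterial — only relative geometry
matters — and these defaults reproduce the canonical deciduous silhouette.
All five are configurable; grassland or cereal template families are out of
scope. Ties (which essentially arise only in degenerate constant-series
cases) resolve to the lexicographically smallest $(a, b)$, which is the bank
order. Correlation against the whole bank is computed from cached column
moments and a single crossproduct, so one OC2 evaluation costs a few
milliseconds; templates that are constant over the observed days are
excluded (score $-\infty$) rather than undefined.

Correlating over observed days only — rather than interpolating the series
onto all 365 days — was a genuinely open choice; observed-days-only was
chosen because it never invents data and because gaps in practice are long
(weeks), where interpolation would dominate the correlation.

# The sROI route

A pinprick is a `side` × `side` (default 6 × 6) pixel square; its series is
the mean GCC over its 36 pixels. The correlation image holds Pearson's $r$
between every pixel's series and the pinprick series over shared observed
days (at least 3 required, else missing). Thresholding at τ keeps pixels
with $r \ge \tau$; masks are nested in τ by construction. The default grid
τ ∈ {0.05, 0.10, …, 0.95} brackets the typical single-threshold choice
(0.65) for forest scenes. Candidates smaller than `min_size` — default
$\max(25, 0.05\%\,n)$ pixels, since tiny ROIs give noisy criterion scores —
are dropped. The best candidate under the chosen criterion wins; ties
prefer the larger mask, then the smaller τ.

The automated variant scatters $q$ pinpricks uniformly without replacement
on a coarse grid with stride equal to the pinprick side (avoiding
near-duplicate seeds), skips degenerate pinpricks (zero-variance series,
e.g. fully saturated sky), and maximizes over all $q \times m$ candidates.
All randomness flows from one seed.

# The uROI route

Each frame is flattened into a vector
$(r_1,\dots,r_n, g_1,\dots,g_n, b_1,\dots,b_n)^\top$, pixels in row-major
order; the $3n \times T$ matrix is centered per row. A truncated SVD
(via `irlba` when the requested rank is small relative to the matrix, dense
LAPACK otherwise) yields the first $p$ eigenimages; rearranging gives the
$n \times 3p$ feature matrix whose row $i$ concatenates pixel $i$'s loadings
from the red, green and blue blocks. Two conventions are fixed where the
mathematics leaves freedom:

* singular-vector signs are normalized so each column's largest-magnitude
  entry is positive (SVD signs are otherwise arbitrary and would break
  reproducibility);
* features are the raw rows, unweighted by singular values (weighting is an
  off-by-default option) — clustering operates on the left singular vectors
  themselves.

`stats::kmeans` (squared-Euclidean, 10 random restarts, 300 iterations max,
seeded) partitions the pixels for every $(p, k)$ in the grid; the default
grid $p \in \{12, 24\}$, $k \in \{4,\dots,10\}$ gives 14 partitions and 98
candidate clusters. Every cluster is scored under both criteria and the
table is ranked by the selected one. `min_size` filtering defaults to *off*
(0) here — small clusters are still legitimately scoreable and the full
98-cluster accounting is preserved; it can be enabled explicitly. Missing
frames need no imputation: the matrix is built from available frames only,
and DOY gaps affect the criteria, not the SVD. Hierarchical clustering was
rejected as infeasible at megapixel scale; k-means is linear per iteration.

# Phenological dates

`dates_from_template()` simply reads SOS and EOS2 off the OC2 winner.
`segment_dates()` provides a multi-change-point segmentation yielding all
four dates (SOS, MAX, EOS1, EOS2): greedy binary segmentation with
piecewise-linear fits — repeatedly split the segment whose best
within-segment supF is largest, until four breaks or no split exceeds the F
floor (default 20, stopping spurious splits in flat noise) — followed by a
refinement sweep that re-optimizes each break between its neighbors by
total RSS until stable. The sweep matters: greedy splits are made against
segments that still contain other breaks, so their positions are biased;
one-at-a-time re-optimization converges to the exact knots on noise-free
piecewise-linear input. On exact fits a knot sample lies on both adjacent
lines, so the minimal-RSS split ties; ties resolve to the larger split,
i.e. the knot belongs to its left segment, and each break is reported as
the last observed day before the structure changes. Labels are positional
(1st → SOS, …, 4th → EOS2); no semantic check of greenness direction is
made at each break, a documented limitation. Bayesian multiple
change-point machinery, which would add uncertainty quantification and
automatic model order, is out of scope.

# The synthetic scene generator

Tests need ground truth, so `render_scene()` builds labeled scenes: disjoint
covering regions, each with a seasonal GCC profile — deciduous (template
shape with known $a, b$), evergreen (constant plus a +0.05 "May shoot" bump
on DOYs 120–170), grass (flatter template), sky (constant with shared daily
jitter, sd 0.01), constant (buildings) — rendered into RGB with
$g = \mathrm{gcc}\cdot s$, $r = b = (1-\mathrm{gcc})\,s/2$ at region
brightness $s$, plus iid Gaussian channel noise clipped to $[0,1]$. The
construction makes GCC exactly invertible at zero noise, so greenness
assertions are analytic. The evergreen bump is deliberate: criteria must
*out-rank* competing weak seasonality, not merely detect any.

The default scene is 64 × 64 px with daily frames over 365 days: sky (rows
1–16), deciduous ($a = 105$, $b = 308$, winter GCC 0.30, amplitude 0.25;
31 % of pixels), evergreen (level 0.42), building strip (level 0.33);
channel noise sd 0.02. The planted dates echo the canonical Central
European beech season; winter level and amplitude are typical phenocam GCC
magnitudes. At this size the full test suite and the acceptance script run
in well under two minutes while every recovery margin is wide (Jaccard ≈ 1,
date error ≤ 1 day).

What the generator does *not* emulate — exposure and white-balance drift,
shadows, snow, fog, camera shake, field-of-view shifts — bounds what
passing tests show: they validate the algorithms' correctness and their
noise robustness, not robustness to real-world imaging artifacts.
Registration of drifting fields of view is explicitly out of scope.

# Numerical and interface choices

* 8-/16-bit images are rescaled to $[0,1]$ on load; grayscale inputs are
  replicated to three channels with a warning.
* DOY is computed in the frame's own calendar year; stacks are assumed to
  span one year.
* Pixel indexing is row-major, origin top-left, everywhere a flat pixel
  index is exposed (feature rows, partition labels).
* The CLI (`synth`, `greenness`, `sroi`, `uroi`, `dates`) is a thin wrapper
  over the exported functions; one `--seed` flag feeds every source of
  randomness, and identical configuration plus seed give byte-identical
  outputs.

# Known limitations

* OC1's window constants (240 / 30–210) encode a Northern-hemisphere
  spring; Southern-hemisphere archives would need shifted windows.
* `segment_dates()` labels are positional; a series whose first structural
  change is not green-up will be mislabeled.
* Single-year stacks only; no multi-year stitching.
* No p-values anywhere: both criteria are ranking scores.
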