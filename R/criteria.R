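# OC1: supF structural change-point statistic on the spring window.
# OC2: best Pearson correlation against a bank of piecewise-linear seasonal
# templates indexed by spring onset a and autumn end b.

# residual sum of squares of a simple linear fit y ~ t, closed form.
# A single point (or none) fits exactly: RSS 0.
.lin_rss <- function(t, y) {
  n <- length(t)
  if (n <= 1L) return(0)
  tm <- t - mean(t); ym <- y - mean(y)
  sxx <- sum(tm^2)
  if (sxx == 0) return(sum(ym^2))
  syy <- sum(ym^2)
  sxy <- sum(tm * ym)
  max(syy - sxy^2 / sxx, 0)
}

#' Change-point F-statistic (optimality criterion 1)
#'
#' Scores how sharply a greenness series changes structure during spring.
#' Restricted to the first `window_end` days of the year, every candidate DOY
#' `s` in `[cand_lo, cand_hi]` is tried as a structural change point: a
#' 2-parameter straight line fitted to all observed days is compared with a
#' 4-parameter model whose intercept and slope both change at `s` (separate
#' lines for days `< s` and `>= s`). The statistic is
#' \deqn{F(s) = \frac{(RSS_0 - RSS_1(s))/k}{RSS_1(s)/(n - 2k)}, \quad k = 2,}
#' with `n` the number of observed days used, and OC1 is the maximum over
#' `s`. A large value means a strong, localized green-up signal.
#'
#' @param series a `greenness_series`.
#' @param window_end last DOY considered (default 240, dropping autumn).
#' @param cand_lo,cand_hi candidate change-point DOY range (defaults 30, 210).
#' @param min_side minimum observed days required on each side of a
#'   candidate (default 5); candidates with fewer are skipped.
#' @return object of class `oc1_result`: `f_max` (possibly `Inf` when the
#'   change-point model fits exactly), `change_doy`, `rss0`, `rss1`,
#'   `k_params`, `n_used`, `exact_fit`.
#' @export
oc1 <- function(series, window_end = 240L, cand_lo = 30L, cand_hi = 210L,
                min_side = 5L) {
  stopifnot(inherits(series, "greenness_series"))
  obs <- observed_doys(series)
  obs <- obs[obs <= window_end]
  t <- as.numeric(obs)
  y <- series$value[obs]
  n <- length(t)
  k <- 2L
  cand <- seq.int(cand_lo, cand_hi)
  n_left <- vapply(cand, function(s) sum(t < s), integer(1))
  cand <- cand[n_left >= min_side & (n - n_left) >= min_side]
  if (n <= 2L * k || length(cand) == 0L)
    stop("too few observed days in [1, ", window_end,
         "] for a change-point fit (n = ", n, ")")

  rss0 <- .lin_rss(t, y)
  eps <- 1e-12 * max(sum((y - mean(y))^2), .Machine$double.eps)
  f <- numeric(length(cand)); rss1 <- numeric(length(cand))
  for (i in seq_along(cand)) {
    left <- t < cand[i]
    r1 <- .lin_rss(t[left], y[left]) + .lin_rss(t[!left], y[!left])
    rss1[i] <- r1
    f[i] <- if (r1 <= eps) {
      if (rss0 <= eps) 0 else Inf
    } else {
      ((rss0 - r1) / k) / (r1 / (n - 2 * k))
    }
  }
  best <- which.max(f)   # ties: earliest candidate
  structure(
    list(f_max = f[best], change_doy = cand[best],
         rss0 = rss0, rss1 = rss1[best], k_params = k, n_used = n,
         exact_fit = is.infinite(f[best])),
    class = "oc1_result"
  )
}

#' @export
print.oc1_result <- function(x, ...) {
  cat(sprintf("<oc1_result> F = %s at DOY %d (n = %d)\n",
              format(x$f_max, digits = 6), x$change_doy, x$n_used))
  invisible(x)
}

#' Seasonal template time series
#'
#' Builds the piecewise-linear deciduous greenness template: constant winter
#' level 0 up to spring onset `a`, steep rise to the peak 1 at `c`, small
#' decline to the summer plateau at `d`, plateau until `e`, decline back to 0
#' at autumn end `b`, constant thereafter. Only the relative geometry
#' matters for correlation scoring, so levels are in arbitrary units.
#'
#' @param a spring-onset DOY.
#' @param b autumn-end DOY.
#' @param c_peak DOY of maximum greenness (default `a + 20`).
#' @param d_plateau DOY where the summer plateau starts (default
#'   `c_peak + 20`).
#' @param e_plateau DOY where the plateau ends (default `b - 60`).
#' @param plateau_level plateau height as a fraction of the peak
#'   (default 0.7).
#' @return object of class `greenness_template`: parameters plus `values`,
#'   the template evaluated at DOY 1..365.
#' @export
make_template <- function(a, b, c_peak = a + 20, d_plateau = c_peak + 20,
                          e_plateau = b - 60, plateau_level = 0.7) {
  if (!(1 <= a && a < c_peak && c_peak < d_plateau && d_plateau <= e_plateau &&
        e_plateau < b && b <= 365))
    stop("template parameters must satisfy 1 <= a < c < d <= e < b <= 365")
  kx <- c(1, a, c_peak, d_plateau, e_plateau, b, 365)
  ky <- c(0, 0, 1, plateau_level, plateau_level, 0, 0)
  if (d_plateau == e_plateau) { kx <- kx[-5]; ky <- ky[-5] }
  if (a == 1) { kx <- kx[-1]; ky <- ky[-1] }
  if (b == 365) { kx <- kx[-length(kx)]; ky <- ky[-length(ky)] }
  vals <- stats::approx(kx, ky, xout = 1:365, rule = 2)$y
  structure(
    list(a = a, b = b, c_peak = c_peak, d_plateau = d_plateau,
         e_plateau = e_plateau, plateau_level = plateau_level,
         values = vals),
    class = "greenness_template"
  )
}

#' Bank of seasonal templates over an (a, b) grid
#'
#' The default grid `a` in 50..150 and `b` in 265..365 gives 101 x 101 =
#' 10201 templates. Templates are ordered lexicographically by (a, b), which
#' fixes tie-breaking in [oc2()].
#'
#' @param a_grid,b_grid integer DOY grids for spring onset and autumn end.
#' @inheritParams make_template
#' @return object of class `template_bank`: `a`, `b` (per template),
#'   `values` (365 x n_templates matrix), and the shape parameters used.
#' @export
template_bank <- function(a_grid = 50:150, b_grid = 265:365,
                          plateau_level = 0.7) {
  stopifnot(length(a_grid) >= 1, length(b_grid) >= 1)
  grid <- expand.grid(b = b_grid, a = a_grid)   # a-major order
  m <- matrix(NA_real_, 365L, nrow(grid))
  for (i in seq_len(nrow(grid)))
    m[, i] <- make_template(grid$a[i], grid$b[i],
                            plateau_level = plateau_level)$values
  cm <- colMeans(m)
  structure(
    list(a = grid$a, b = grid$b, values = m, plateau_level = plateau_level,
         # cached full-year column moments; reused when a series has no
         # missing days
         col_mean = cm, col_ss = colSums(m^2) - 365 * cm^2),
    class = "template_bank"
  )
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("<template_bank> %d templates, a in [%d, %d], b in [%d, %d]\n",
              length(x$a), min(x$a), max(x$a), min(x$b), max(x$b)))
  invisible(x)
}

#' Best template correlation (optimality criterion 2)
#'
#' Pearson correlation of the series with every template in the bank,
#' restricted to observed days; the maximum is OC2 and its (a, b) are rough
#' start-of-season and end-of-season dates. Ties are broken by the smallest
#' `a`, then the smallest `b`.
#'
#' @param series a `greenness_series` with at least 3 observed days and
#'   nonzero variance.
#' @param bank a [template_bank()].
#' @return object of class `oc2_result`: `rho_max`, `a_hat`, `b_hat`,
#'   `index` (bank column attaining the maximum).
#' @export
oc2 <- function(series, bank = template_bank()) {
  stopifnot(inherits(series, "greenness_series"),
            inherits(bank, "template_bank"))
  obs <- observed_doys(series)
  y <- series$value[obs]
  if (length(y) < 3L) stop("need at least 3 observed days")
  if (stats::sd(y) == 0) stop("zero-variance series: correlation undefined")
  # Pearson correlation against all templates at once via column moments;
  # one crossprod instead of 10201 cor() calls
  n <- length(y)
  if (n == 365L && !is.null(bank$col_mean)) {
    M <- bank$values
    cm <- bank$col_mean
    ss <- bank$col_ss
  } else {
    M <- bank$values[obs, , drop = FALSE]
    cm <- colMeans(M)
    ss <- colSums(M^2) - n * cm^2
  }
  num <- as.vector(crossprod(M, y)) - n * cm * mean(y)
  den <- sqrt(ss * sum((y - mean(y))^2))
  rho <- num / den
  rho[den <= 0] <- -Inf                # templates constant over obs days
  rho[rho > 1] <- 1; rho[rho < -1 & is.finite(rho)] <- -1
  best <- which.max(rho)    # first max: smallest a, then smallest b
  structure(
    list(rho_max = rho[best], a_hat = bank$a[best], b_hat = bank$b[best],
         index = best),
    class = "oc2_result"
  )
}

#' @export
print.oc2_result <- function(x, ...) {
  cat(sprintf("<oc2_result> rho = %.4f at (a = %d, b = %d)\n",
              x$rho_max, x$a_hat, x$b_hat))
  invisible(x)
}
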