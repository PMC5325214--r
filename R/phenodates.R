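# Phenological dates from a selected ROI's greenness series: rough SOS/EOS2
# from the OC2-winning template, and a multi-change-point segmentation
# labeling SOS, MAX, EOS1, EOS2.

#' Construct a phenological date set
#'
#' @param sos start of growing season (DOY).
#' @param max_doy date of maximum greenness (DOY), optional.
#' @param eos1 start of autumn leaf coloring (DOY), optional.
#' @param eos2 end of autumn leaf coloring (DOY).
#' @param method `"template"` or `"segmentation"`.
#' @return object of class `pheno_dates`.
#' @export
pheno_dates <- function(sos, eos2, max_doy = NA_integer_,
                        eos1 = NA_integer_, method) {
  vals <- c(sos, max_doy, eos1, eos2)
  vals <- vals[!is.na(vals)]
  if (length(vals) >= 2L && is.unsorted(vals))
    stop("dates must satisfy sos <= max <= eos1 <= eos2")
  if (!is.na(sos) && !is.na(eos2) && sos >= eos2)
    stop("sos must precede eos2")
  structure(list(sos = sos, max = max_doy, eos1 = eos1, eos2 = eos2,
                 method = method),
            class = "pheno_dates")
}

#' @export
print.pheno_dates <- function(x, ...) {
  f <- function(v) if (is.na(v)) "-" else as.character(v)
  cat(sprintf("<pheno_dates> SOS %s  MAX %s  EOS1 %s  EOS2 %s  [%s]\n",
              f(x$sos), f(x$max), f(x$eos1), f(x$eos2), x$method))
  invisible(x)
}

#' Rough season dates from the winning template
#'
#' The (a, b) of the best-correlated template are rough estimates of the
#' start of season and the end of autumn coloring.
#'
#' @param oc2_result an `oc2_result` from [oc2()].
#' @return a [pheno_dates()] with `sos = a_hat`, `eos2 = b_hat`,
#'   `method = "template"`.
#' @export
dates_from_template <- function(oc2_result) {
  stopifnot(inherits(oc2_result, "oc2_result"))
  pheno_dates(sos = oc2_result$a_hat, eos2 = oc2_result$b_hat,
              method = "template")
}

# supF scan over one segment of observed points (t, y): candidates are
# observed time values with >= min_side points on each side; the change at s
# separates t < s from t >= s. Returns NULL when no admissible candidate.
.segment_supf <- function(t, y, min_side = 5L) {
  n <- length(t)
  k <- 2L
  if (n <= 2L * k) return(NULL)
  cand <- t[(t > t[min_side]) & (t <= t[n - min_side + 1L])]
  if (length(cand) == 0L) return(NULL)
  rss0 <- .lin_rss(t, y)
  eps <- 1e-12 * max(sum((y - mean(y))^2), .Machine$double.eps)
  best <- NULL
  for (s in cand) {
    left <- t < s
    r1 <- .lin_rss(t[left], y[left]) + .lin_rss(t[!left], y[!left])
    f <- if (r1 <= eps) { if (rss0 <= eps) 0 else Inf }
    else ((rss0 - r1) / k) / (r1 / (n - 2 * k))
    if (is.null(best) || f > best$f) best <- list(s = s, f = f, rss1 = r1)
  }
  best
}

# total RSS of a piecewise-linear fit with breaks `br` (first days of their
# right segments) on observed points (t, y)
.breaks_rss <- function(t, y, br) {
  bounds <- c(-Inf, sort(br), Inf)
  tot <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    inseg <- t >= bounds[i] & t < bounds[i + 1L]
    tot <- tot + .lin_rss(t[inseg], y[inseg])
  }
  tot
}

#' Season dates by greedy change-point segmentation
#'
#' Splits the observed series into piecewise-linear segments by greedy binary
#' segmentation: the segment whose best within-segment supF statistic is
#' largest is split, until `max_changepoints` breaks are placed or no split
#' exceeds `f_floor`. A refinement sweep then re-optimizes each break given
#' its neighbors (minimizing total residual sum of squares) until stable, so
#' exactly piecewise-linear series are segmented at their knots. Breaks are
#' reported as the last observed day before the structure changes and
#' labeled positionally SOS, MAX, EOS1, EOS2; missing labels are `NA` with a
#' warning.
#'
#' @param series a `greenness_series` with at least 30 observed days.
#' @param max_changepoints maximum number of breaks (default 4).
#' @param f_floor minimum supF for accepting a split (default 20).
#' @param min_side minimum observed days per side of a break (default 5).
#' @return a [pheno_dates()] with `method = "segmentation"` and attribute
#'   `"changepoints"` (all break DOYs found).
#' @export
segment_dates <- function(series, max_changepoints = 4L, f_floor = 20,
                          min_side = 5L) {
  stopifnot(inherits(series, "greenness_series"))
  obs <- observed_doys(series)
  if (length(obs) < 30L) stop("need at least 30 observed days")
  t <- as.numeric(obs)
  y <- series$value[obs]

  breaks <- numeric(0)   # each break = first t of its right-hand segment
  repeat {
    if (length(breaks) >= max_changepoints) break
    bounds <- c(-Inf, sort(breaks), Inf)
    best <- NULL
    for (i in seq_len(length(bounds) - 1L)) {
      inseg <- t >= bounds[i] & t < bounds[i + 1L]
      sp <- .segment_supf(t[inseg], y[inseg], min_side)
      if (!is.null(sp) && (is.null(best) || sp$f > best$f)) best <- sp
    }
    if (is.null(best) || best$f < f_floor) break
    breaks <- sort(c(breaks, best$s))
  }

  # refinement sweep: re-optimize each break between its neighbors
  if (length(breaks) > 1L) {
    for (sweep in 1:10) {
      changed <- FALSE
      for (i in seq_along(breaks)) {
        lo <- if (i == 1L) -Inf else breaks[i - 1L]
        hi <- if (i == length(breaks)) Inf else breaks[i + 1L]
        inwin <- t >= lo & t < hi
        tw <- t[inwin]; yw <- y[inwin]
        nw <- length(tw)
        if (nw < 2L * min_side) next
        cand <- tw[(tw > tw[min_side]) & (tw <= tw[nw - min_side + 1L])]
        if (length(cand) == 0L) next
        rss <- vapply(cand, function(s) {
          left <- tw < s
          .lin_rss(tw[left], yw[left]) + .lin_rss(tw[!left], yw[!left])
        }, numeric(1))
        # a knot sample lies on both adjacent lines, so exact fits tie;
        # prefer the largest split = knot assigned to the left segment
        eps <- 1e-12 * max(sum((yw - mean(yw))^2), .Machine$double.eps)
        s_new <- max(cand[rss <= min(rss) + eps])
        if (s_new != breaks[i]) { breaks[i] <- s_new; changed <- TRUE }
      }
      breaks <- sort(breaks)
      if (!changed) break
    }
  }

  # report each break as the last observed day of its left segment
  dates <- vapply(breaks, function(s) max(t[t < s]), numeric(1))
  lab <- rep(NA_real_, 4L)
  lab[seq_along(dates)] <- dates[seq_len(min(4L, length(dates)))]
  if (length(dates) < 4L)
    warning("only ", length(dates),
            " change point(s) found; remaining labels set to NA")
  out <- pheno_dates(sos = lab[1], max_doy = lab[2], eos1 = lab[3],
                     eos2 = lab[4], method = "segmentation")
  attr(out, "changepoints") <- dates
  out
}

#' Write phenological dates as CSV
#'
#' Columns `roi_id,method,sos,max,eos1,eos2`.
#'
#' @param dates a `pheno_dates` object or list of them.
#' @param path CSV file path.
#' @param roi_id identifier(s) for the ROI column.
#' @return `path`, invisibly.
#' @export
write_dates_csv <- function(dates, path, roi_id = "roi") {
  if (inherits(dates, "pheno_dates")) dates <- list(dates)
  df <- do.call(rbind, lapply(seq_along(dates), function(i) {
    d <- dates[[i]]
    data.frame(roi_id = roi_id[min(i, length(roi_id))], method = d$method,
               sos = d$sos, max = d$max, eos1 = d$eos1, eos2 = d$eos2)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
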