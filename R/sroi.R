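# Semi-supervised ROI growth: a tiny seed square ("pinprick") of pixels is
# correlated against every pixel's greenness series; thresholding the
# correlation image yields nested candidate ROIs which are ranked by OC1/OC2.

# run expr with a private RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default minimum candidate-ROI size
#'
#' `max(25, 0.05% of n)` pixels: very small ROIs give noisy criterion scores.
#'
#' @param n pixel count of the image grid.
#' @return integer pixel count.
#' @export
default_min_size <- function(n) max(25L, ceiling(5e-4 * n))

#' Seed pinprick
#'
#' A small `side x side` square of pixels (default 6 x 6) marking, e.g., the
#' crown of a deciduous tree. Its mean greenness series anchors the
#' correlation image.
#'
#' @param center `c(row, col)` of the square's center (1-based).
#' @param stack the `image_stack` the pinprick lives on (for bounds checks).
#' @param side square side length in pixels.
#' @return object of class `pinprick`: `center`, `side`, `rows`, `cols`,
#'   `mask`.
#' @export
pinprick <- function(center, stack, side = 6L) {
  stopifnot(length(center) == 2L, side >= 1L)
  r0 <- center[1] - (side - 1L) %/% 2L
  c0 <- center[2] - (side - 1L) %/% 2L
  rows <- r0:(r0 + side - 1L)
  cols <- c0:(c0 + side - 1L)
  if (min(rows) < 1L || max(rows) > stack$n1 ||
      min(cols) < 1L || max(cols) > stack$n2)
    stop("pinprick square extends outside the image grid")
  m <- matrix(FALSE, stack$n1, stack$n2)
  m[rows, cols] <- TRUE
  structure(list(center = center, side = side, rows = rows, cols = cols,
                 mask = m),
            class = "pinprick")
}

#' Correlation image against a pinprick
#'
#' Pearson correlation between each pixel's daily greenness series and the
#' pinprick's mean series, over the days observed in both. Pixels sharing
#' fewer than 3 observed days with the pinprick, or with zero variance, are
#' missing.
#'
#' @param stack an `image_stack`.
#' @param pp a [pinprick()].
#' @param psm optional precomputed [pixel_series_matrix()] of `stack`.
#' @return numeric `n1 x n2` matrix of correlations in `[-1, 1]` (class
#'   `correlation_image`), `NA` where undefined.
#' @export
correlation_image <- function(stack, pp, psm = NULL) {
  stopifnot(inherits(stack, "image_stack"), inherits(pp, "pinprick"))
  if (is.null(psm)) psm <- pixel_series_matrix(stack)
  ref <- roi_series(stack, pp$mask)
  yv <- ref$value
  if (sum(!is.na(yv)) < 3L || stats::sd(yv, na.rm = TRUE) == 0)
    stop("degenerate pinprick series (needs >= 3 observed days, nonzero variance)")
  r <- suppressWarnings(
    as.vector(stats::cor(t(psm), yv, use = "pairwise.complete.obs"))
  )
  shared <- colSums(!is.na(t(psm)) & !is.na(yv))
  r[shared < 3L] <- NA_real_
  out <- matrix(r, stack$n1, stack$n2, byrow = TRUE)   # row-major pixel order
  class(out) <- c("correlation_image", class(out))
  out
}

#' Write a correlation image
#'
#' Exports as 16-bit grayscale PNG (`[-1, 1]` mapped to `[0, 65535]`, missing
#' mapped to 0) or as CSV of `(row, col, r)`.
#'
#' @param cimg a correlation image matrix.
#' @param path output path; format chosen by extension (`.png` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_correlation_image <- function(cimg, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    v <- (unclass(cimg) + 1) / 2
    v[is.na(v)] <- 0
    png::writePNG(v, path, dpi = NULL)
  } else {
    idx <- which(!is.na(cimg), arr.ind = TRUE)
    utils::write.csv(
      data.frame(row = idx[, 1], col = idx[, 2], r = cimg[idx]),
      path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Candidate ROIs from thresholding a correlation image
#'
#' One candidate per threshold: all pixels with correlation at or above it.
#' Masks are nested — a higher threshold always yields a subset.
#'
#' @param cimg a [correlation_image()].
#' @param thresholds correlation thresholds in `[0, 1)` (default
#'   `seq(0.05, 0.95, by = 0.05)`).
#' @param min_size candidates with fewer pixels are dropped (with a message).
#' @return list of `candidate_roi` objects (fields `mask`, `size`,
#'   `provenance`).
#' @export
threshold_candidates <- function(cimg, thresholds = seq(0.05, 0.95, by = 0.05),
                                 min_size = 25L) {
  if (length(thresholds) == 0L) stop("empty threshold grid")
  stopifnot(all(thresholds >= 0 & thresholds < 1))
  thresholds <- sort(thresholds)
  out <- list()
  for (tau in thresholds) {
    m <- !is.na(cimg) & unclass(cimg) >= tau
    if (sum(m) < min_size) {
      message(sprintf("threshold %.2f: candidate of %d px below min_size %d, dropped",
                      tau, sum(m), min_size))
      next
    }
    out[[length(out) + 1L]] <- structure(
      list(mask = m, size = sum(m),
           provenance = list(kind = "threshold", tau = tau)),
      class = "candidate_roi")
  }
  out
}

#' @export
print.candidate_roi <- function(x, ...) {
  pv <- x$provenance
  src <- if (identical(pv$kind, "threshold")) {
    sprintf("tau = %.2f%s", pv$tau,
            if (!is.null(pv$pinprick)) sprintf(", pinprick (%d, %d)",
                                               pv$pinprick[1], pv$pinprick[2])
            else "")
  } else sprintf("p = %d, k = %d, cluster %d", pv$p, pv$k, pv$cluster)
  cat(sprintf("<candidate_roi> %d px [%s]", x$size, src))
  if (!is.null(x$score))
    cat(sprintf("; %s = %s", x$criterion, format(x$score, digits = 6)))
  cat("\n")
  invisible(x)
}

# criterion score of a mask given the per-pixel daily series matrix
.score_mask <- function(psm, mask, criterion, bank) {
  pix <- which(as.vector(t(mask)))
  series <- .series_from_psm(psm, pix)
  res <- tryCatch(
    switch(criterion, oc1 = oc1(series), oc2 = oc2(series, bank)),
    error = function(e) NULL)
  score <- if (is.null(res)) -Inf
  else if (criterion == "oc1") res$f_max else res$rho_max
  list(result = res, score = score, series = series)
}

#' Semi-supervised ROI from an expert pinprick
#'
#' Grows the pinprick into an ROI by thresholding its correlation image and
#' picks the threshold whose ROI scores best under the chosen criterion
#' (ties: larger mask, then smaller threshold).
#'
#' @inheritParams correlation_image
#' @inheritParams threshold_candidates
#' @param criterion `"oc1"` (change-point F) or `"oc2"` (template
#'   correlation).
#' @param min_size minimum candidate size in pixels; default
#'   [default_min_size()].
#' @param bank template bank for `criterion = "oc2"`.
#' @return the winning `candidate_roi`, with `score`, `criterion`, `result`
#'   (the full `oc1_result`/`oc2_result`) and `series` attached.
#' @export
sroi_semi <- function(stack, pp, thresholds = seq(0.05, 0.95, by = 0.05),
                      criterion = c("oc2", "oc1"),
                      min_size = default_min_size(stack$n),
                      bank = NULL, psm = NULL) {
  criterion <- match.arg(criterion)
  if (is.null(psm)) psm <- pixel_series_matrix(stack)
  if (criterion == "oc2" && is.null(bank)) bank <- template_bank()
  cimg <- correlation_image(stack, pp, psm = psm)
  cands <- threshold_candidates(cimg, thresholds, min_size)
  if (length(cands) == 0L)
    stop("all candidates below min_size = ", min_size,
         "; consider lowering min_size")
  best <- NULL
  for (cand in cands) {
    sc <- .score_mask(psm, cand$mask, criterion, bank)
    cand$score <- sc$score; cand$result <- sc$result
    cand$series <- sc$series; cand$criterion <- criterion
    cand$provenance$pinprick <- pp$center
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$size > best$size) ||
        (cand$score == best$score && cand$size == best$size &&
         cand$provenance$tau < best$provenance$tau))
      best <- cand
  }
  best
}

#' Fully automated sROI from random pinpricks
#'
#' Distributes `q` pinpricks uniformly over the image (without replacement on
#' a coarse grid with stride equal to the pinprick side, avoiding
#' near-duplicate seeds), evaluates all pinprick-by-threshold candidates and
#' returns the global criterion maximizer. Pinpricks with degenerate
#' (zero-variance) series are skipped with a message.
#'
#' @inheritParams sroi_semi
#' @param q number of random pinpricks.
#' @param seed RNG seed; fixed seed gives identical results across runs.
#' @param side pinprick side length in pixels.
#' @return the winning `candidate_roi` (provenance records the pinprick).
#' @export
sroi_auto <- function(stack, q, thresholds = seq(0.05, 0.95, by = 0.05),
                      criterion = c("oc2", "oc1"),
                      min_size = default_min_size(stack$n),
                      seed = 0L, side = 6L, bank = NULL, psm = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(q >= 1L)
  if (is.null(psm)) psm <- pixel_series_matrix(stack)
  if (criterion == "oc2" && is.null(bank)) bank <- template_bank()
  half_lo <- (side - 1L) %/% 2L
  half_hi <- side - 1L - half_lo
  row_pos <- seq.int(1L + half_lo, stack$n1 - half_hi, by = side)
  col_pos <- seq.int(1L + half_lo, stack$n2 - half_hi, by = side)
  centers <- as.matrix(expand.grid(row = row_pos, col = col_pos))
  if (q > nrow(centers))
    stop("q = ", q, " exceeds the ", nrow(centers), " available positions")
  picks <- .with_seed(seed, centers[sample.int(nrow(centers), q), , drop = FALSE])

  best <- NULL
  for (i in seq_len(q)) {
    pp <- pinprick(picks[i, ], stack, side = side)
    cand <- tryCatch(
      sroi_semi(stack, pp, thresholds, criterion, min_size,
                bank = bank, psm = psm),
      error = function(e) {
        message(sprintf("pinprick (%d, %d) skipped: %s",
                        picks[i, 1], picks[i, 2], conditionMessage(e)))
        NULL
      })
    if (is.null(cand)) next
    if (is.null(best) || cand$score > best$score) best <- cand
  }
  if (is.null(best)) stop("all pinpricks degenerate or below min_size")
  best
}
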