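# %greenness = green chromatic coordinate (GCC): g / (r + g + b).
# Series live on a fixed DOY 1..365 axis; unobserved days are NA and are
# never interpolated.

#' Green chromatic coordinate of a pixel
#'
#' Fraction of total channel intensity carried by the green channel,
#' `g / (r + g + b)` — the standard vegetation greenness signal for RGB
#' camera imagery. Vectorized over pixels.
#'
#' @param r,g,b channel intensities in `[0, 1]`.
#' @return greenness fraction in `[0, 1]`; `NA` where `r + g + b == 0`.
#' @examples
#' pixel_greenness(0, 1, 0)        # 1
#' pixel_greenness(0.4, 0.4, 0.4)  # 1/3
#' @export
pixel_greenness <- function(r, g, b) {
  if (any(c(r, g, b) < 0 | c(r, g, b) > 1, na.rm = TRUE))
    stop("channel intensities must lie in [0, 1]")
  s <- r + g + b
  out <- g / s
  out[s == 0] <- NA_real_
  out
}

#' Construct a greenness series
#'
#' A daily %greenness series on a fixed day-of-year axis 1..365 with missing
#' days allowed.
#'
#' @param values numeric vector of length 365; `NA` for unobserved days.
#' @param source_size pixel count of the region the series was computed from.
#' @return object of class `greenness_series` with fields `value` (length
#'   365), `n_obs`, `source_size`.
#' @export
greenness_series <- function(values, source_size = NA_integer_) {
  stopifnot(is.numeric(values), length(values) == 365L)
  if (any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop("greenness values must lie in [0, 1]")
  structure(
    list(value = as.numeric(values), n_obs = sum(!is.na(values)),
         source_size = source_size),
    class = "greenness_series"
  )
}

#' @export
print.greenness_series <- function(x, ...) {
  cat(sprintf("<greenness_series> %d observed DOYs, source %s px\n",
              x$n_obs, format(x$source_size)))
  invisible(x)
}

#' @export
as.data.frame.greenness_series <- function(x, ...) {
  data.frame(doy = 1:365, greenness = x$value,
             n_pixels = rep(x$source_size, 365L))
}

#' Observed day-of-year values of a series
#'
#' @param series a `greenness_series`.
#' @return integer vector of DOYs with a non-missing value.
#' @export
observed_doys <- function(series) which(!is.na(series$value))

# frame t as an [n1, n2, 3] array, dims preserved for degenerate grids
.frame <- function(stack, t) {
  array(stack$pixels[, , , t, drop = FALSE], dim = dim(stack$pixels)[1:3])
}

# per-frame greenness maps averaged into one value per DOY.
# Returns n_pixels x 365 matrix in row-major pixel order, plus the frame
# greenness maps are discarded.
.daily_pixel_greenness <- function(stack) {
  n <- stack$n
  out <- matrix(NA_real_, n, 365L)
  counts <- matrix(0L, n, 365L)
  acc <- matrix(0, n, 365L)
  for (t in seq_len(stack$T)) {
    fr <- .frame(stack, t)
    gcc <- pixel_greenness(fr[, , 1], fr[, , 2], fr[, , 3])
    v <- as.vector(t(gcc))                      # row-major pixel order
    d <- stack$doy[t]
    ok <- !is.na(v)
    acc[ok, d] <- acc[ok, d] + v[ok]
    counts[ok, d] <- counts[ok, d] + 1L
  }
  obs <- counts > 0L
  out[obs] <- acc[obs] / counts[obs]
  out
}

#' Per-pixel daily greenness matrix
#'
#' Computes the %greenness time series of every pixel: per frame the GCC of
#' each pixel, then frames sharing a DOY averaged into one daily value.
#'
#' @param stack an `image_stack`.
#' @return numeric matrix `n x 365` (pixels in row-major order, columns DOY
#'   1..365), `NA` on unobserved days.
#' @export
pixel_series_matrix <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  .daily_pixel_greenness(stack)
}

#' %greenness time series of a region of interest
#'
#' For each frame, the mean GCC over the mask's pixels (pixels with undefined
#' greenness excluded); frames sharing a DOY are then averaged into one daily
#' value.
#'
#' @param stack an `image_stack`.
#' @param mask logical `n1 x n2` matrix; must contain at least one pixel.
#' @return a [greenness_series()] with `source_size = sum(mask)`.
#' @export
roi_series <- function(stack, mask) {
  stopifnot(inherits(stack, "image_stack"), is.logical(mask))
  if (!identical(dim(mask), c(stack$n1, stack$n2)))
    stop("mask shape does not match stack grid")
  if (sum(mask) == 0L) stop("empty mask")
  acc <- numeric(365L); cnt <- integer(365L)
  for (t in seq_len(stack$T)) {
    fr <- .frame(stack, t)
    gcc <- pixel_greenness(fr[, , 1][mask], fr[, , 2][mask], fr[, , 3][mask])
    if (all(is.na(gcc))) next
    d <- stack$doy[t]
    acc[d] <- acc[d] + mean(gcc, na.rm = TRUE)
    cnt[d] <- cnt[d] + 1L
  }
  v <- rep(NA_real_, 365L)
  v[cnt > 0L] <- acc[cnt > 0L] / cnt[cnt > 0L]
  greenness_series(v, source_size = sum(mask))
}

# mean of precomputed per-pixel daily series over a pixel-index set
.series_from_psm <- function(psm, pix_idx) {
  sub <- psm[pix_idx, , drop = FALSE]
  v <- colMeans(sub, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  greenness_series(v, source_size = length(pix_idx))
}

#' Export and import greenness series as CSV
#'
#' Columns `doy,greenness,n_pixels`; unobserved days are written with an
#' empty greenness field.
#'
#' @param series a `greenness_series`.
#' @param path CSV file path.
#' @return `write_series_csv` returns `path` invisibly; `read_series_csv`
#'   returns a `greenness_series`.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("doy", "greenness") %in% names(df)))
  v <- rep(NA_real_, 365L)
  v[df$doy] <- df$greenness
  sz <- if ("n_pixels" %in% names(df)) df$n_pixels[1] else NA_integer_
  greenness_series(v, source_size = sz)
}
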