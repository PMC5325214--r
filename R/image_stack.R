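# Frames are stored as a single numeric array [n1, n2, 3, T] with channel
# values in [0, 1]. Pixel indices exposed to users (feature rows, partition
# labels) are row-major: pixel i = (row - 1) * n2 + col, top-left origin.

#' Construct an image stack
#'
#' Low-level constructor bundling timestamped RGB frames on a common pixel
#' grid into a stack with a day-of-year (DOY) time axis. Most users will call
#' [load_stack()] or [render_scene()] instead.
#'
#' @param pixels numeric array `[n1, n2, 3, T]`, channel values in `[0, 1]`.
#' @param timestamps `POSIXct` vector of length `T`, strictly increasing.
#' @return An object of class `image_stack` with fields `pixels`,
#'   `timestamps`, `doy`, `n1`, `n2`, `n`, `T`, `year`.
#' @export
image_stack <- function(pixels, timestamps) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 4L, dim(pixels)[3] == 3L)
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (dim(pixels)[4] != length(timestamps))
    stop("number of frames does not match number of timestamps")
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  rng <- range(pixels, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("channel values must lie in [0, 1]")
  d <- dim(pixels)
  lt <- as.POSIXlt(timestamps)
  structure(
    list(
      pixels = pixels,
      timestamps = timestamps,
      doy = lt$yday + 1L,
      n1 = d[1], n2 = d[2], n = d[1] * d[2], T = d[4],
      year = lt$year[1] + 1900L
    ),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf(
    "<image_stack> %d frames of %d x %d px (year %d, DOY %d..%d)\n",
    x$T, x$n1, x$n2, x$year, min(x$doy), max(x$doy)
  ))
  invisible(x)
}

#' Number of pixels per frame
#'
#' @param x an `image_stack`, or a length-2 integer vector `c(n1, n2)` of
#'   pixel rows and columns.
#' @return `n1 * n2`, the number of pixel units per image.
#' @examples
#' pixel_count(c(1276, 960))  # 1224960
#' @export
pixel_count <- function(x) {
  if (inherits(x, "image_stack")) return(x$n1 * x$n2)
  stopifnot(is.numeric(x), length(x) == 2L, all(x >= 0))
  prod(x)
}

.parse_frame_name <- function(fname) {
  base <- sub("\\.(jpe?g|png)$", "", basename(fname), ignore.case = TRUE)
  if (!grepl("^[0-9]{8}_[0-9]{6}$", base)) return(NULL)
  ts <- as.POSIXct(strptime(base, "%Y%m%d_%H%M%S", tz = "UTC"))
  if (is.na(ts)) return(NULL)
  ts
}

.read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.jpe?g$", path, ignore.case = TRUE)) {
    img <- jpeg::readJPEG(path)
  } else {
    return(NULL)
  }
  # readPNG/readJPEG already rescale 8- and 16-bit samples to [0, 1]
  if (length(dim(img)) == 2L) {
    warning("grayscale image '", basename(path),
            "' replicated into three channels")
    img <- array(img, dim = c(dim(img), 3L))
  } else if (dim(img)[3] > 3L) {
    img <- img[, , 1:3, drop = FALSE]   # drop alpha
  }
  img
}

#' Load a directory of camera images into a stack
#'
#' Reads JPEG/PNG frames whose filenames encode the acquisition time as
#' `yyyymmdd_hhmmss.(jpg|png)`, sorts them by timestamp, optionally crops the
#' top pixel rows (timestamp banners) and keeps only frames of a given hour.
#' For nonconforming filenames a `manifest` CSV with columns
#' `filename,datetime` may be supplied instead.
#'
#' @param directory path containing the image files.
#' @param crop_top_rows number of top pixel rows to discard from every frame.
#' @param hour_filter optional hour of day (0-23); frames taken at any other
#'   hour are dropped.
#' @param manifest optional CSV path mapping `filename` to `datetime`
#'   (any format `as.POSIXct` understands).
#' @return An [image_stack()].
#' @export
load_stack <- function(directory, crop_top_rows = 0L, hour_filter = NULL,
                       manifest = NULL) {
  stopifnot(dir.exists(directory), crop_top_rows >= 0)
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!is.null(manifest)) {
    man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    stopifnot(all(c("filename", "datetime") %in% names(man)))
    ts <- as.POSIXct(man$datetime, tz = "UTC")
    files <- file.path(directory, man$filename)
    keep <- file.exists(files)
    files <- files[keep]; ts <- ts[keep]
  } else {
    ts <- rep(as.POSIXct(NA), length(files))
    for (i in seq_along(files)) {
      p <- .parse_frame_name(files[i])
      if (is.null(p)) {
        warning("skipping '", basename(files[i]),
                "': filename does not parse as yyyymmdd_hhmmss")
      } else ts[i] <- p
    }
    keep <- !is.na(ts)
    files <- files[keep]; ts <- ts[keep]
  }
  if (!is.null(hour_filter)) {
    keep <- as.POSIXlt(ts)$hour == hour_filter
    files <- files[keep]; ts <- ts[keep]
  }
  o <- order(ts)
  files <- files[o]; ts <- ts[o]

  frames <- list()
  kept_ts <- as.POSIXct(character(0), tz = "UTC")
  shape <- NULL
  for (i in seq_along(files)) {
    img <- tryCatch(.read_image(files[i]), error = function(e) {
      warning("skipping '", basename(files[i]), "': ", conditionMessage(e))
      NULL
    })
    if (is.null(img)) next
    if (crop_top_rows > 0) {
      if (crop_top_rows >= dim(img)[1])
        stop("crop_top_rows (", crop_top_rows, ") >= image height (",
             dim(img)[1], ")")
      img <- img[-seq_len(crop_top_rows), , , drop = FALSE]
    }
    if (is.null(shape)) shape <- dim(img)[1:2]
    if (!identical(dim(img)[1:2], shape))
      stop("inconsistent frame resolutions: ", paste(shape, collapse = "x"),
           " vs ", paste(dim(img)[1:2], collapse = "x"),
           " ('", basename(files[i]), "')")
    frames[[length(frames) + 1L]] <- img
    kept_ts <- c(kept_ts, ts[i])
  }
  if (length(frames) == 0L)
    stop("no loadable frames found in '", directory, "'")
  px <- array(NA_real_, dim = c(shape[1], shape[2], 3L, length(frames)))
  for (i in seq_along(frames)) px[, , , i] <- frames[[i]]
  image_stack(px, kept_ts)
}

#' Read and write ROI masks
#'
#' Masks are logical `n1 x n2` matrices stored on disk as single-channel
#' PNG images with values 0 (outside) and 255 (inside).
#'
#' @param path PNG file path.
#' @param stack optional `image_stack`; if given, the mask shape is checked
#'   against the stack grid.
#' @return `read_mask` returns a logical matrix; `write_mask` returns `path`
#'   invisibly.
#' @export
read_mask <- function(path, stack = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  m <- img > 0.5
  if (!is.null(stack) && !identical(dim(m), c(stack$n1, stack$n2)))
    stop("mask shape ", paste(dim(m), collapse = "x"),
         " does not match stack grid ",
         paste(c(stack$n1, stack$n2), collapse = "x"))
  m
}

#' @param mask logical matrix.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Mask size and overlap
#'
#' `mask_size` counts member pixels; `jaccard` is the intersection-over-union
#' of two masks, the standard score for comparing a recovered ROI against a
#' ground-truth region.
#'
#' @param mask,a,b logical matrices on the same grid.
#' @return a number.
#' @export
mask_size <- function(mask) sum(mask)

#' @rdname mask_size
#' @export
jaccard <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
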