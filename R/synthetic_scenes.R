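# Ground-truthed synthetic camera scenes: labeled regions with seasonal
# greenness profiles rendered into RGB stacks. The channel construction
# (g = gcc * s, r = b = (1 - gcc) * s / 2) makes the green chromatic
# coordinate exactly invertible at zero noise, so greenness tests are
# analytic.

#' Region specifications for synthetic scenes
#'
#' Each region has a mask on the scene grid, a seasonal greenness profile
#' and a base brightness `s` (total channel intensity `r + g + b`).
#'
#' * `region_deciduous()`: winter level plus a seasonal amplitude following
#'   the deciduous template of [make_template()] with onset `a`, end `b`.
#' * `region_evergreen()`: constant level plus a small May-shoot bump
#'   (`+bump` over DOYs 120-170) — evergreen conifers show weak spring
#'   seasonality that the criteria must out-rank, not merely detect.
#' * `region_grass()`: like deciduous but a flatter profile (higher plateau,
#'   lower amplitude).
#' * `region_sky()`: constant level with a shared daily jitter (weather).
#' * `region_constant()`: buildings and other static structures.
#'
#' @param mask logical matrix on the scene grid.
#' @param a,b spring-onset and autumn-end DOYs of the seasonal profile.
#' @param winter winter greenness level.
#' @param amplitude seasonal amplitude on top of `winter`.
#' @param level constant greenness level.
#' @param bump May-bump height (evergreen).
#' @param jitter_sd standard deviation of the shared daily level jitter
#'   (sky).
#' @param base_brightness total channel intensity `s` in `(0, 1]`.
#' @param name region label.
#' @return a `region_spec` object.
#' @export
region_deciduous <- function(mask, a = 105, b = 308, winter = 0.30,
                             amplitude = 0.25, base_brightness = 0.75,
                             name = "deciduous") {
  .region(name, mask, base_brightness, list(
    type = "deciduous", a = a, b = b, winter = winter, amplitude = amplitude))
}

#' @rdname region_deciduous
#' @export
region_evergreen <- function(mask, level = 0.42, bump = 0.05,
                             base_brightness = 0.75, name = "evergreen") {
  .region(name, mask, base_brightness,
          list(type = "evergreen", level = level, bump = bump))
}

#' @rdname region_deciduous
#' @export
region_grass <- function(mask, a = 90, b = 330, winter = 0.32,
                         amplitude = 0.12, base_brightness = 0.75,
                         name = "grass") {
  .region(name, mask, base_brightness, list(
    type = "grass", a = a, b = b, winter = winter, amplitude = amplitude))
}

#' @rdname region_deciduous
#' @export
region_sky <- function(mask, level = 0.30, jitter_sd = 0.01,
                       base_brightness = 0.9, name = "sky") {
  .region(name, mask, base_brightness,
          list(type = "sky", level = level, jitter_sd = jitter_sd))
}

#' @rdname region_deciduous
#' @export
region_constant <- function(mask, level = 0.33, base_brightness = 0.6,
                            name = "building") {
  .region(name, mask, base_brightness,
          list(type = "constant", level = level))
}

.region <- function(name, mask, base_brightness, profile) {
  stopifnot(is.logical(mask), is.matrix(mask),
            base_brightness > 0, base_brightness <= 1)
  structure(list(name = name, mask = mask, base_brightness = base_brightness,
                 profile = profile),
            class = "region_spec")
}

# deterministic part of a region's greenness profile at the given DOYs
.profile_values <- function(profile, doys) {
  switch(profile$type,
    deciduous = ,
    grass = {
      tpl <- make_template(profile$a, profile$b,
                           plateau_level = if (profile$type == "grass") 0.85
                                           else 0.7)
      profile$winter + profile$amplitude * tpl$values[doys]
    },
    evergreen = profile$level +
      ifelse(doys >= 120 & doys <= 170, profile$bump, 0),
    sky = rep(profile$level, length(doys)),
    constant = rep(profile$level, length(doys)),
    stop("unknown profile type '", profile$type, "'")
  )
}

#' Synthetic scene specification
#'
#' @param n1,n2 grid size in pixel rows and columns.
#' @param doys observed DOYs (strictly increasing, within 1..365; gaps
#'   allowed).
#' @param regions list of `region_spec` objects; masks must be pairwise
#'   disjoint and cover the grid.
#' @param noise_sd iid Gaussian channel noise standard deviation.
#' @param seed RNG seed used when rendering.
#' @param year calendar year of the scene (default 2014).
#' @return a `scene_spec` object.
#' @export
scene_spec <- function(n1, n2, doys = 1:365, regions, noise_sd = 0.02,
                       seed = 1L, year = 2014L) {
  stopifnot(n1 >= 1, n2 >= 1, length(regions) >= 1)
  doys <- as.integer(doys)
  if (is.unsorted(doys, strictly = TRUE) || min(doys) < 1 || max(doys) > 365)
    stop("doys must be strictly increasing within 1..365")
  cover <- matrix(0L, n1, n2)
  for (rg in regions) {
    stopifnot(inherits(rg, "region_spec"))
    if (!identical(dim(rg$mask), c(as.integer(n1), as.integer(n2))))
      stop("region '", rg$name, "' mask does not match the scene grid")
    cover <- cover + rg$mask
  }
  if (any(cover > 1L)) stop("region masks overlap")
  if (any(cover == 0L)) stop("region masks do not cover the grid")
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), doys = doys,
                 regions = regions, noise_sd = noise_sd, seed = seed,
                 year = as.integer(year)),
            class = "scene_spec")
}

#' Default four-region test scene
#'
#' A 64 x 64 grid observed daily over a full year: sky (top), a deciduous
#' canopy with spring onset DOY 105 and autumn end DOY 308, an evergreen
#' block with a May-shoot bump, and a building strip. Channel noise sd 0.02.
#'
#' @param seed RNG seed for rendering.
#' @param noise_sd channel noise standard deviation.
#' @return a [scene_spec()].
#' @export
default_scene <- function(seed = 1L, noise_sd = 0.02) {
  n1 <- 64L; n2 <- 64L
  blank <- function() matrix(FALSE, n1, n2)
  sky <- blank(); sky[1:16, ] <- TRUE
  dec <- blank(); dec[17:48, 1:40] <- TRUE
  evg <- blank(); evg[17:48, 41:64] <- TRUE
  bld <- blank(); bld[49:64, ] <- TRUE
  scene_spec(n1, n2, doys = 1:365,
             regions = list(region_sky(sky),
                            region_deciduous(dec, a = 105, b = 308),
                            region_evergreen(evg),
                            region_constant(bld)),
             noise_sd = noise_sd, seed = seed)
}

#' Render a scene into an image stack plus ground truth
#'
#' For each observed DOY the greenness `gcc` of every pixel is set by its
#' region's profile; channels are `g = gcc * s`, `r = b = (1 - gcc) * s / 2`
#' with `s` the region's base brightness, then iid Gaussian channel noise is
#' added and values are clipped to `[0, 1]`. One frame per DOY at 12:00.
#' Deterministic under the spec's seed.
#'
#' @param spec a [scene_spec()].
#' @return list with `stack` (an `image_stack`) and `truth` (per-region
#'   `masks` and `params`).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n1 <- spec$n1; n2 <- spec$n2; T <- length(spec$doys)
  px <- array(NA_real_, dim = c(n1, n2, 3L, T))
  .with_seed(spec$seed, {
    profiles <- lapply(spec$regions, function(rg) {
      v <- .profile_values(rg$profile, spec$doys)
      if (identical(rg$profile$type, "sky") && rg$profile$jitter_sd > 0)
        v <- v + stats::rnorm(T, 0, rg$profile$jitter_sd)
      pmin(pmax(v, 0), 1)
    })
    for (t in seq_len(T)) {
      gmap <- matrix(NA_real_, n1, n2)
      smap <- matrix(NA_real_, n1, n2)
      for (i in seq_along(spec$regions)) {
        rg <- spec$regions[[i]]
        gmap[rg$mask] <- profiles[[i]][t]
        smap[rg$mask] <- rg$base_brightness
      }
      g <- gmap * smap
      rb <- (1 - gmap) * smap / 2
      fr <- array(c(rb, g, rb), dim = c(n1, n2, 3L))
      if (spec$noise_sd > 0)
        fr <- fr + stats::rnorm(length(fr), 0, spec$noise_sd)
      px[, , , t] <- pmin(pmax(fr, 0), 1)
    }
  })
  dates <- as.Date(spec$doys - 1L, origin = as.Date(sprintf("%d-01-01",
                                                            spec$year)))
  ts <- as.POSIXct(paste(dates, "12:00:00"), tz = "UTC")
  truth <- list(
    masks = stats::setNames(lapply(spec$regions, `[[`, "mask"),
                            vapply(spec$regions, `[[`, "", "name")),
    params = lapply(stats::setNames(spec$regions,
                                    vapply(spec$regions, `[[`, "", "name")),
                    `[[`, "profile")
  )
  list(stack = image_stack(px, ts), truth = truth)
}

#' Write a rendered scene to image files
#'
#' One PNG per frame, named `yyyymmdd_hhmmss.png`, so [load_stack()] can
#' round-trip the stack (within 8-bit quantization).
#'
#' @param stack an `image_stack`.
#' @param directory output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_scene_images <- function(stack, directory) {
  stopifnot(inherits(stack, "image_stack"))
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE))
      stop("cannot create directory '", directory, "'")
  for (t in seq_len(stack$T)) {
    fname <- format(stack$timestamps[t], "%Y%m%d_%H%M%S.png", tz = "UTC")
    png::writePNG(.frame(stack, t), file.path(directory, fname))
  }
  invisible(directory)
}
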