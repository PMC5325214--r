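# Shared fixtures (cached across tests) and independent oracles.

.fx <- new.env(parent = emptyenv())

fx_scene <- function() {
  if (is.null(.fx$scene)) .fx$scene <- render_scene(default_scene(seed = 1))
  .fx$scene
}

fx_psm <- function() {
  if (is.null(.fx$psm)) .fx$psm <- pixel_series_matrix(fx_scene()$stack)
  .fx$psm
}

fx_bank <- function() {
  if (is.null(.fx$bank)) .fx$bank <- template_bank()
  .fx$bank
}

# coarse bank for cheap unit tests
fx_small_bank <- function() {
  if (is.null(.fx$small_bank))
    .fx$small_bank <- template_bank(a_grid = seq(80, 130, by = 5),
                                    b_grid = seq(280, 330, by = 5))
  .fx$small_bank
}

# random stack with uniform channels, daily frames starting at the given date
rand_stack <- function(n1, n2, T, seed = 1, year = 2014) {
  set.seed(seed)
  px <- array(runif(n1 * n2 * 3 * T), dim = c(n1, n2, 3, T))
  ts <- as.POSIXct(sprintf("%d-01-01 12:00:00", year), tz = "UTC") +
    (seq_len(T) - 1) * 86400
  image_stack(px, ts)
}

# noise-free piecewise-linear series with knots at 105/119/303/308
knot_series <- function() {
  t <- 1:365
  y <- numeric(365)
  y[t <= 105] <- 0.35
  r <- t > 105 & t <= 119
  y[r] <- 0.35 + (t[r] - 105) * (0.6 - 0.35) / 14
  r <- t > 119 & t <= 303
  y[r] <- 0.6 + (t[r] - 119) * (0.55 - 0.6) / 184
  r <- t > 303 & t <= 308
  y[r] <- 0.55 + (t[r] - 303) * (0.35 - 0.55) / 5
  y[t > 308] <- 0.35
  greenness_series(y)
}

# seasonal template plus iid Gaussian noise, clipped to [0, 1]
noisy_template_series <- function(seed, a = 105, b = 308, sd = 0.02) {
  set.seed(seed)
  v <- make_template(a, b)$values + rnorm(365, 0, sd)
  greenness_series(pmin(pmax(v, 0), 1))
}

# random gappy series for oracle comparisons
rand_series <- function(seed) {
  set.seed(seed)
  v <- rep(NA_real_, 365)
  obs <- sort(sample(1:365, sample(120:365, 1)))
  v[obs] <- pmin(pmax(0.4 + 0.1 * sin(obs / 40 + runif(1, 0, 6)) +
                        rnorm(length(obs), 0, 0.03), 0), 1)
  greenness_series(v)
}

# Independent OC1 oracle: both regressions solved with lm() at every
# admissible candidate DOY; never touches the package's closed forms.
oracle_oc1 <- function(series, window_end = 240, cand_lo = 30, cand_hi = 210,
                       min_side = 5) {
  obs <- which(!is.na(series$value))
  obs <- obs[obs <= window_end]
  t <- as.numeric(obs)
  y <- series$value[obs]
  n <- length(t)
  rss0 <- sum(resid(lm(y ~ t))^2)
  f_best <- -Inf; s_best <- NA
  for (s in cand_lo:cand_hi) {
    nl <- sum(t < s)
    if (nl < min_side || n - nl < min_side) next
    left <- t < s
    fit_l <- lm(y[left] ~ t[left])
    fit_r <- lm(y[!left] ~ t[!left])
    rss1 <- sum(resid(fit_l)^2) + sum(resid(fit_r)^2)
    f <- if (rss1 <= 1e-12 * max(rss0, 1e-300)) {
      if (rss0 <= 1e-12) 0 else Inf
    } else ((rss0 - rss1) / 2) / (rss1 / (n - 4))
    if (f > f_best) { f_best <- f; s_best <- s }
  }
  list(f_max = f_best, change_doy = s_best)
}

# Independent OC2 oracle: plain cor() loop over every template
oracle_oc2 <- function(series, bank) {
  obs <- which(!is.na(series$value))
  y <- series$value[obs]
  best_rho <- -Inf; best_i <- NA
  for (i in seq_len(ncol(bank$values))) {
    r <- suppressWarnings(cor(bank$values[obs, i], y))
    if (!is.na(r) && r > best_rho) { best_rho <- r; best_i <- i }
  }
  list(rho_max = best_rho, a_hat = bank$a[best_i], b_hat = bank$b[best_i])
}
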