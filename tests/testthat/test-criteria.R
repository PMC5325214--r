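test_that("oc1 flags an exact change-point fit and a structureless line", {
  # level 0.3 on DOYs 1-119, line rising 0.3 -> 0.6 on 120-240
  v <- rep(NA_real_, 365)
  v[1:119] <- 0.3
  v[120:240] <- 0.3 + (0:120) * 0.3 / 120
  r <- oc1(greenness_series(v))
  expect_equal(r$change_doy, 120)
  expect_true(is.infinite(r$f_max))
  expect_true(r$exact_fit)
  expect_gt(r$rss0, 0)

  # straight line: both models fit exactly, F = 0 by convention
  v2 <- rep(NA_real_, 365)
  v2[1:240] <- 0.2 + (1:240) * 0.001
  r2 <- oc1(greenness_series(v2))
  expect_equal(r2$f_max, 0)

  # constant series: same convention
  v3 <- rep(NA_real_, 365); v3[1:240] <- 0.4
  expect_equal(oc1(greenness_series(v3))$f_max, 0)
})

test_that("oc1 matches an independent lm-based brute force on random series", {
  for (seed in 1:12) {
    s <- rand_series(seed)
    r <- oc1(s)
    o <- oracle_oc1(s)
    expect_equal(r$change_doy, o$change_doy, info = sprintf("seed %d", seed))
    expect_equal(r$f_max, o$f_max, tolerance = 1e-8,
                 info = sprintf("seed %d", seed))
    expect_lte(r$rss1, r$rss0)
    expect_true(r$change_doy >= 30 && r$change_doy <= 210)
  }
})

test_that("oc1 never decreases when a planted level shift doubles", {
  set.seed(99)
  noise <- rnorm(240, 0, 0.02)
  for (shift in c(0.05, 0.1)) {
    build <- function(delta) {
      v <- rep(NA_real_, 365)
      v[1:240] <- 0.4 + delta * (1:240 >= 120) + noise
      greenness_series(pmin(pmax(v, 0), 1))
    }
    f1 <- oc1(build(shift))$f_max
    f2 <- oc1(build(2 * shift))$f_max
    expect_gte(f2, f1)
  }
})

test_that("oc1 errors on too few observations", {
  v <- rep(NA_real_, 365); v[c(100, 110, 120, 130)] <- c(0.3, 0.4, 0.5, 0.6)
  expect_error(oc1(greenness_series(v)), "too few")
})

test_that("templates follow the piecewise seasonal geometry", {
  tpl <- make_template(100, 300)
  expect_equal(tpl$values[120], 1)            # peak at c = a + 20
  expect_equal(tpl$values[110], 0.5)          # midpoint of the rise
  expect_equal(tpl$values[100], 0)            # winter level at onset
  expect_true(all(tpl$values[1:100] == 0))
  expect_true(all(tpl$values[300:365] == 0))
  expect_equal(tpl$values[150], 0.7)          # plateau (d = 140, e = 240)

  # hand-rolled piecewise evaluation at all 365 DOYs
  hand <- vapply(1:365, function(t) {
    if (t <= 100) 0
    else if (t <= 120) (t - 100) / 20
    else if (t <= 140) 1 - 0.3 * (t - 120) / 20
    else if (t <= 240) 0.7
    else if (t <= 300) 0.7 * (300 - t) / 60
    else 0
  }, numeric(1))
  expect_equal(tpl$values, hand, tolerance = 1e-12)

  expect_error(make_template(100, 150), "a < c < d")
})

test_that("default bank has the 101 x 101 (a, b) grid in lexicographic order", {
  bank <- fx_bank()
  expect_equal(length(bank$a), 10201)
  expect_equal(sort(unique(bank$a)), 50:150)
  expect_equal(sort(unique(bank$b)), 265:365)
  expect_true(!is.unsorted(bank$a))
  expect_true(all(diff(bank$b[bank$a == 50]) == 1))
})

test_that("oc2 recovers a bank template from itself and affine transforms", {
  bank <- fx_bank()
  tpl <- make_template(100, 300)
  r <- oc2(greenness_series(tpl$values), bank)
  expect_equal(r$rho_max, 1.0, tolerance = 1e-12)
  expect_equal(c(r$a_hat, r$b_hat), c(100, 300))

  # Pearson correlation is invariant to positive affine maps
  tpl2 <- make_template(80, 330)
  r2 <- oc2(greenness_series(0.2 + 0.3 * tpl2$values), bank)
  expect_equal(r2$rho_max, 1.0, tolerance = 1e-12)
  expect_equal(c(r2$a_hat, r2$b_hat), c(80, 330))
})

test_that("oc2 equals an exhaustive cor() loop on noisy series", {
  bank <- fx_small_bank()
  for (seed in 1:5) {
    s <- noisy_template_series(seed, a = 105, b = 308)
    r <- oc2(s, bank)
    o <- oracle_oc2(s, bank)
    expect_equal(r$rho_max, o$rho_max, tolerance = 1e-10)
    expect_equal(c(r$a_hat, r$b_hat), c(o$a_hat, o$b_hat))
    expect_true(r$rho_max >= -1 && r$rho_max <= 1)
  }
  # gappy series: correlation restricted to observed days
  s <- noisy_template_series(9)
  s$value[seq(1, 365, by = 3)] <- NA
  s <- greenness_series(s$value)
  r <- oc2(s, bank)
  o <- oracle_oc2(s, bank)
  expect_equal(r$rho_max, o$rho_max, tolerance = 1e-10)
  expect_equal(c(r$a_hat, r$b_hat), c(o$a_hat, o$b_hat))
})

test_that("oc2 result is invariant to shifting and positive scaling", {
  bank <- fx_small_bank()
  s <- noisy_template_series(31)
  r0 <- oc2(s, bank)
  for (tf in list(function(v) v * 0.5, function(v) 0.2 + v * 0.3)) {
    r <- oc2(greenness_series(tf(s$value)), bank)
    expect_equal(r$rho_max, r0$rho_max, tolerance = 1e-10)
    expect_equal(c(r$a_hat, r$b_hat), c(r0$a_hat, r0$b_hat))
  }
})

test_that("oc2 rejects degenerate series", {
  v <- rep(NA_real_, 365); v[100:102] <- 0.4
  expect_error(oc2(greenness_series(v), fx_small_bank()), "zero-variance")
  v2 <- rep(NA_real_, 365); v2[c(100, 200)] <- c(0.3, 0.5)
  expect_error(oc2(greenness_series(v2), fx_small_bank()), "at least 3")
})

test_that("template (a, b) recovery under noise stays within 5 days", {
  bank <- fx_bank()
  hits <- 0L
  n_rep <- 100L
  for (seed in seq_len(n_rep)) {
    s <- noisy_template_series(seed, a = 105, b = 308, sd = 0.02)
    r <- oc2(s, bank)
    if (abs(r$a_hat - 105) <= 5 && abs(r$b_hat - 308) <= 5) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
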