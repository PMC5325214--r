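test_that("the data matrix stacks channels and centers rows", {
  # hand-computed 2x2 stack, T = 3
  px <- array(NA_real_, dim = c(2, 2, 3, 3))
  vals <- matrix(seq(0.1, 0.9, length.out = 12), 4, 3)  # pixel x time, red
  for (t in 1:3) {
    px[, , 1, t] <- matrix(vals[, t], 2, 2, byrow = TRUE)
    px[, , 2, t] <- matrix(vals[, t] / 2, 2, 2, byrow = TRUE)
    px[, , 3, t] <- 0.2
  }
  ts <- as.POSIXct("2014-01-01 12:00", tz = "UTC") + 0:2 * 86400
  st <- image_stack(px, ts)
  X <- build_data_matrix(st)
  expect_equal(dim(X), c(12L, 3L))
  expect_equal(X[1:4, ], vals - rowMeans(vals), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(X[5:8, ], (vals - rowMeans(vals)) / 2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(abs(X[9:12, ]) < 1e-12))        # constant blue centers to 0
  expect_true(all(abs(rowMeans(X)) < 1e-12))

  # constant stack centers to the zero matrix
  stc <- image_stack(array(0.4, dim = c(2, 2, 3, 3)), ts)
  expect_true(all(build_data_matrix(stc) == 0))

  st1 <- image_stack(array(0.4, dim = c(2, 2, 3, 1)),
                     as.POSIXct("2014-01-01", tz = "UTC"))
  expect_error(build_data_matrix(st1), "at least 2 frames")
})

test_that("truncated features match a dense SVD up to column signs", {
  st <- rand_stack(8, 8, 20, seed = 13)
  X <- build_data_matrix(st)
  feats <- svd_features(st, p = 5)

  dec <- svd(X)     # dense oracle
  expect_equal(feats$singular_values, dec$d[1:5], tolerance = 1e-8)
  n <- 64
  for (j in 1:5) {
    u <- dec$u[, j]
    u_star_col <- c(feats$U_star[, j], feats$U_star[, 5 + j],
                    feats$U_star[, 10 + j])
    agree <- max(abs(u_star_col - u)) < 1e-8 ||
      max(abs(u_star_col + u)) < 1e-8
    expect_true(agree, info = sprintf("column %d", j))
    # sign convention: largest-magnitude entry positive
    expect_gt(u_star_col[which.max(abs(u_star_col))], 0)
  }
  # orthonormality of the rearranged factor
  U <- rbind(feats$U_star[, 1:5], feats$U_star[, 6:10], feats$U_star[, 11:15])
  expect_equal(crossprod(U), diag(5), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(diff(feats$singular_values) <= 1e-8))

  expect_error(svd_features(st, p = 0), "p must lie")
  expect_error(svd_features(st, p = 21), "p must lie")
})

test_that("a rank-1 temporal pattern yields one dominant singular value", {
  n1 <- 6; n2 <- 6; T <- 15
  pattern <- sin(seq_len(T))
  set.seed(2)
  scalep <- matrix(runif(n1 * n2, 0.5, 1), n1, n2)
  px <- array(NA_real_, dim = c(n1, n2, 3, T))
  for (t in seq_len(T))
    for (ch in 1:3)
      px[, , ch, t] <- 0.5 + 0.1 * scalep * pattern[t]
  st <- image_stack(px, as.POSIXct("2014-01-01", tz = "UTC") +
                      seq_len(T) * 86400)
  feats <- svd_features(st, p = 3)
  expect_lte(feats$singular_values[2], 1e-10 * feats$singular_values[1])
})

test_that("full-rank reconstruction reproduces the centered matrix", {
  st <- rand_stack(4, 4, 10, seed = 17)
  X <- build_data_matrix(st)
  p <- min(dim(X))
  dec <- svd(X, nu = p, nv = p)
  expect_equal(dec$u %*% diag(dec$d[1:p]) %*% t(dec$v), X, tolerance = 1e-8,
               ignore_attr = TRUE)
  # truncation consistency: leading singular values agree across ranks
  f2 <- svd_features(st, p = 2)
  f6 <- svd_features(st, p = 6)
  expect_equal(f2$singular_values, f6$singular_values[1:2], tolerance = 1e-8)
})

test_that("k-means separates well-separated feature groups deterministically", {
  st <- rand_stack(5, 3, 8, seed = 23)
  feats <- svd_features(st, p = 2)
  # plant three exactly repeated feature rows
  feats$U_star <- matrix(rep(c(0, 0, 0, 10, 10, 10, -10, 0, 10, 0, -10, 10),
                             each = 5), nrow = 15)
  part <- kmeans_partition(feats, k = 3, seed = 1)
  expect_equal(part$k, 3)
  expect_equal(sort(part$sizes), c(5L, 5L, 5L))
  expect_equal(length(unique(part$labels[1:5])), 1)
  expect_equal(length(unique(part$labels[6:10])), 1)
  expect_equal(length(unique(part$labels[11:15])), 1)

  part2 <- kmeans_partition(feats, k = 3, seed = 1)
  expect_identical(part$labels, part2$labels)

  expect_error(kmeans_partition(feats, k = 4, seed = 1), "distinct")

  # 1-D features {0,0,0,10,10}: the optimal 2-means splits at the gap
  feats$U_star <- matrix(c(0, 0, 0, 10, 10, rep(0, 10)), nrow = 5)
  feats$U_star <- feats$U_star[, 1, drop = FALSE]
  p2 <- kmeans_partition(feats, k = 2, seed = 7)
  expect_equal(length(unique(p2$labels[1:3])), 1)
  expect_equal(length(unique(p2$labels[4:5])), 1)
  expect_false(p2$labels[1] == p2$labels[4])
})

test_that("uroi_select recovers the deciduous region on the default scene", {
  sc <- fx_scene()
  res <- uroi_select(sc$stack, p_grid = 3, k_grid = 4, seed = 1,
                     bank = fx_bank(), psm = fx_psm())
  expect_equal(res$n_partitions, 1)
  expect_equal(res$n_candidates, 4)
  expect_equal(nrow(res$table), 4)
  expect_gte(jaccard(res$best$mask, sc$truth$masks$deciduous), 0.9)
  expect_true(all(c("p", "k", "cluster_id", "size", "oc1", "oc2",
                    "a_hat", "b_hat", "rank") %in% names(res$table)))
  expect_equal(sort(res$table$rank), 1:4)
})

test_that("size filtering drops small clusters but keeps the rest", {
  sc <- fx_scene()
  res <- uroi_select(sc$stack, p_grid = 3, k_grid = 2, seed = 1,
                     min_size = 0, bank = fx_bank(), psm = fx_psm())
  sizes <- sort(res$table$size)
  suppressMessages(
    res2 <- uroi_select(sc$stack, p_grid = 3, k_grid = 2, seed = 1,
                        min_size = sizes[1] + 1, bank = fx_bank(),
                        psm = fx_psm()))
  expect_equal(nrow(res2$table), sum(sizes > sizes[1]))
  expect_error(
    suppressMessages(uroi_select(sc$stack, p_grid = 3, k_grid = 2, seed = 1,
                                 min_size = sc$stack$n, bank = fx_bank(),
                                 psm = fx_psm())),
    "below min_size")
})
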