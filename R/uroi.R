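# Unsupervised ROI extraction: truncated SVD of the centered pixel-channel x
# time matrix, per-pixel features from the left singular vectors, k-means
# over a grid of k, criterion scoring of every cluster.

#' Centered pixel-channel by time data matrix
#'
#' Stacks every frame as a column vector
#' `(r_1..r_n, g_1..g_n, b_1..b_n)` (pixels in row-major order) and centers
#' each of the `3n` rows to mean zero across time.
#'
#' @param stack an `image_stack` with at least 2 frames.
#' @return numeric `3n x T` matrix.
#' @export
build_data_matrix <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$T < 2L) stop("need at least 2 frames")
  n <- stack$n
  X <- matrix(NA_real_, 3L * n, stack$T)
  for (t in seq_len(stack$T)) {
    fr <- .frame(stack, t)
    X[, t] <- c(as.vector(t(fr[, , 1])),
                as.vector(t(fr[, , 2])),
                as.vector(t(fr[, , 3])))
  }
  X - rowMeans(X)
}

#' Per-pixel SVD features (eigenimage loadings)
#'
#' Truncated SVD `X = U D V'` of the centered data matrix; the first `p`
#' left singular vectors (eigenimages) are rearranged so that each pixel is
#' described by `3p` variables — its `p` loadings for the red, green and
#' blue channel blocks, in that order. Column signs are fixed so that each
#' singular vector's largest-magnitude entry is positive.
#'
#' @param stack an `image_stack`.
#' @param p truncation rank, `1 <= p <= min(3n, T)`.
#' @param X optional precomputed [build_data_matrix()] output.
#' @return object of class `pixel_features`: `U_star` (`n x 3p`), `p`,
#'   `singular_values` (first `p`), `n1`, `n2`.
#' @export
svd_features <- function(stack, p, X = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(X)) X <- build_data_matrix(stack)
  mn <- min(dim(X))
  if (p < 1L || p > mn)
    stop("p must lie in [1, ", mn, "]")
  # irlba pays off for large sparse-spectrum problems; small p relative to
  # the matrix is its requirement
  if (p <= mn %/% 3L && mn > 20L) {
    dec <- irlba::irlba(X, nv = p, nu = p)
    U <- dec$u; d <- dec$d
  } else {
    dec <- svd(X, nu = p, nv = 0)
    U <- dec$u; d <- dec$d[seq_len(p)]
  }
  for (j in seq_len(p)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  n <- stack$n
  U_star <- cbind(U[seq_len(n), , drop = FALSE],
                  U[n + seq_len(n), , drop = FALSE],
                  U[2L * n + seq_len(n), , drop = FALSE])
  structure(
    list(U_star = U_star, p = p, singular_values = d,
         n1 = stack$n1, n2 = stack$n2),
    class = "pixel_features"
  )
}

#' @export
print.pixel_features <- function(x, ...) {
  cat(sprintf("<pixel_features> %d pixels x %d features (p = %d)\n",
              nrow(x$U_star), ncol(x$U_star), x$p))
  invisible(x)
}

#' k-means partition of the pixels
#'
#' Squared-Euclidean k-means on the rows of the feature matrix, best inertia
#' over `restarts` seeded initializations; deterministic under a fixed seed.
#'
#' @param features a [svd_features()] result.
#' @param k number of clusters (`>= 2`).
#' @param seed RNG seed.
#' @param restarts number of random initializations (default 10).
#' @param iter_max maximum Lloyd iterations (default 300).
#' @return object of class `pixel_partition`: `labels` (cluster id per pixel,
#'   row-major), `k`, `p`, `seed`, `sizes`.
#' @export
kmeans_partition <- function(features, k, seed = 0L, restarts = 10L,
                             iter_max = 300L) {
  stopifnot(inherits(features, "pixel_features"), k >= 2L)
  U <- features$U_star
  if (k > nrow(U)) stop("k exceeds the number of pixels")
  if (k > nrow(unique(U))) stop("k exceeds the number of distinct feature rows")
  km <- .with_seed(seed,
                   stats::kmeans(U, centers = k, nstart = restarts,
                                 iter.max = iter_max))
  structure(
    list(labels = km$cluster, k = k, p = features$p, seed = seed,
         sizes = as.integer(table(km$cluster)),
         n1 = features$n1, n2 = features$n2),
    class = "pixel_partition"
  )
}

#' Mask of one cluster of a partition
#'
#' @param partition a [kmeans_partition()] result.
#' @param cluster cluster id.
#' @return logical `n1 x n2` matrix.
#' @export
cluster_mask <- function(partition, cluster) {
  matrix(partition$labels == cluster, partition$n1, partition$n2, byrow = TRUE)
}

#' Unsupervised ROI selection over a (p, k) grid
#'
#' For every rank `p` in `p_grid` and cluster count `k` in `k_grid`, the
#' image is partitioned by k-means on the SVD features; every cluster (of at
#' least `min_size` pixels; `min_size = 0` scores all, the default) becomes a
#' candidate ROI scored by both criteria. The default grid
#' `p in {12, 24}`, `k in {4..10}` yields 14 partitions and 98 candidate
#' clusters. Returns the global maximizer of the chosen criterion plus the
#' full candidate table ranked by it.
#'
#' @param stack an `image_stack`.
#' @param p_grid ranks to try (default `c(12, 24)`).
#' @param k_grid cluster counts to try (default `4:10`).
#' @param criterion `"oc2"` (default) or `"oc1"`; used for ranking and
#'   selection.
#' @param min_size minimum cluster size in pixels; 0 disables filtering.
#' @param seed RNG seed for all k-means runs.
#' @param bank template bank for OC2 scoring.
#' @param psm optional precomputed [pixel_series_matrix()].
#' @return object of class `uroi_result`: `best` (a `candidate_roi`),
#'   `table` (data frame `p, k, cluster_id, size, oc1, oc2, a_hat, b_hat,
#'   rank`), `n_partitions`, `n_candidates`, `criterion`, `partitions`.
#' @export
uroi_select <- function(stack, p_grid = c(12L, 24L), k_grid = 4:10,
                        criterion = c("oc2", "oc1"), min_size = 0L,
                        seed = 0L, bank = NULL, psm = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(length(p_grid) >= 1L, length(k_grid) >= 1L)
  if (is.null(bank)) bank <- template_bank()
  if (is.null(psm)) psm <- pixel_series_matrix(stack)
  X <- build_data_matrix(stack)

  rows <- list(); cands <- list(); partitions <- list()
  for (p in p_grid) {
    feats <- svd_features(stack, p, X = X)
    for (k in k_grid) {
      part <- kmeans_partition(feats, k, seed = seed)
      partitions[[sprintf("p%d_k%d", p, k)]] <- part
      for (cl in seq_len(k)) {
        m <- cluster_mask(part, cl)
        sz <- sum(m)
        if (min_size > 0L && sz < min_size) {
          message(sprintf("p=%d k=%d cluster %d (%d px) below min_size %d, dropped",
                          p, k, cl, sz, min_size))
          next
        }
        pix <- which(as.vector(t(m)))
        series <- .series_from_psm(psm, pix)
        r1 <- tryCatch(oc1(series), error = function(e) NULL)
        r2 <- tryCatch(oc2(series, bank), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          p = p, k = k, cluster_id = cl, size = sz,
          oc1 = if (is.null(r1)) NA_real_ else r1$f_max,
          oc2 = if (is.null(r2)) NA_real_ else r2$rho_max,
          a_hat = if (is.null(r2)) NA_integer_ else r2$a_hat,
          b_hat = if (is.null(r2)) NA_integer_ else r2$b_hat)
        cand <- structure(
          list(mask = m, size = sz,
               provenance = list(kind = "cluster", p = p, k = k, cluster = cl),
               criterion = criterion,
               score = switch(criterion,
                              oc1 = if (is.null(r1)) -Inf else r1$f_max,
                              oc2 = if (is.null(r2)) -Inf else r2$rho_max),
               result = switch(criterion, oc1 = r1, oc2 = r2),
               oc1_result = r1, oc2_result = r2, series = series),
          class = "candidate_roi")
        cands[[length(cands) + 1L]] <- cand
      }
    }
  }
  if (length(cands) == 0L)
    stop("all clusters below min_size = ", min_size)
  tab <- do.call(rbind, rows)
  score <- tab[[criterion]]
  score[is.na(score)] <- -Inf
  ord <- order(score, decreasing = TRUE)
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_len(nrow(tab))
  best <- cands[[ord[1]]]
  structure(
    list(best = best, table = tab,
         n_partitions = length(p_grid) * length(k_grid),
         n_candidates = nrow(tab), criterion = criterion,
         partitions = partitions),
    class = "uroi_result"
  )
}

#' @export
print.uroi_result <- function(x, ...) {
  cat(sprintf("<uroi_result> %d partitions, %d candidate clusters (by %s)\n",
              x$n_partitions, x$n_candidates, x$criterion))
  print(x$best)
  invisible(x)
}

#' Write the uROI candidate table as CSV
#'
#' @param result a [uroi_select()] result.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(result, path) {
  utils::write.csv(result$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
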