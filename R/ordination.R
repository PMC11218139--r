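#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})},
#' bounded in \[0, 1\]; computed with [vegan::vegdist()].
#'
#' @param t A `feature_table` with non-negative values and positive row sums.
#' @return A `distance_matrix`.
#' @export
bray_curtis <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (any(t$values < 0)) {
    stopf("Bray-Curtis needs non-negative values; use raw or relative data")
  }
  if (any(rowSums(t$values) <= 0)) stopf("Bray-Curtis: sample(s) with zero total")
  d <- as.matrix(vegan::vegdist(t$values, method = "bray"))
  diag(d) <- 0
  distance_matrix((d + t(d)) / 2, method = "bray_curtis")
}

#' Euclidean distance between samples
#'
#' @param t A `feature_table`.
#' @return A `distance_matrix`.
#' @export
euclidean_distance <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  d <- as.matrix(stats::dist(t$values))
  diag(d) <- 0
  distance_matrix((d + t(d)) / 2, method = "euclidean")
}

ordination_result <- function(scores, loadings, explained, eigenvalues,
                              method) {
  structure(
    list(scores = scores, loadings = loadings, explained = explained,
         eigenvalues = eigenvalues, method = method),
    class = "ordination_result"
  )
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %s: %d samples, %d axes; explained = %s\n",
              x$method, nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$explained), collapse = ", ")))
  invisible(x)
}

#' Principal component analysis
#'
#' Singular-value decomposition of the (column-centered, optionally
#' unit-variance-scaled) matrix via [stats::prcomp()]. The explained
#' fraction of each axis is its eigenvalue over the total variance. Axis
#' signs are fixed so the loading of largest magnitude on each axis is
#' positive, making runs comparable.
#'
#' @param t A `feature_table` with at least 2 samples.
#' @param center Column-center first? Default `TRUE`.
#' @param unit_scale Scale columns to unit variance? Default `FALSE`
#'   (community data; metabolite tables are expected Pareto-scaled upstream).
#' @param n_axes Number of axes to keep; at most
#'   `min(n_samples - 1, n_features)`.
#' @return An `ordination_result` with scores, loadings, per-axis explained
#'   fraction and eigenvalues.
#' @export
pca <- function(t, center = TRUE, unit_scale = FALSE, n_axes = 2) {
  stopifnot(inherits(t, "feature_table"))
  x <- t$values
  if (nrow(x) < 2L) stopf("PCA needs at least 2 samples")
  max_axes <- min(nrow(x) - 1L, ncol(x))
  if (n_axes > max_axes) stopf("n_axes must be <= %d", max_axes)
  if (unit_scale) {
    if (any(apply(x, 2L, stats::sd) == 0)) {
      stopf("unit scaling impossible: constant feature(s) present")
    }
  }
  centered <- scale(x, center = center, scale = FALSE)
  if (all(abs(centered) < 1e-300)) stopf("matrix is constant after centering")
  fit <- stats::prcomp(x, center = center, scale. = unit_scale)
  ev <- fit$sdev^2
  keep <- seq_len(n_axes)
  scores <- fit$x[, keep, drop = FALSE]
  loadings <- fit$rotation[, keep, drop = FALSE]
  sg <- axis_signs(loadings)
  scores <- sweep(scores, 2L, sg, "*")
  loadings <- sweep(loadings, 2L, sg, "*")
  colnames(scores) <- colnames(loadings) <- paste0("PC", keep)
  ordination_result(scores, loadings, explained = ev[keep] / sum(ev),
                    eigenvalues = ev, method = "pca")
}

#' Principal coordinates analysis (metric MDS)
#'
#' Gower double-centering of \eqn{-\tfrac12 d^2} followed by an
#' eigendecomposition. Negative eigenvalues (metric violations) are
#' reported; the explained-fraction denominator uses positive eigenvalues
#' only. Axis signs are fixed by the largest-|score| convention.
#'
#' @param d A `distance_matrix` over at least 3 samples.
#' @param n_axes Number of axes to return.
#' @return An `ordination_result` (no loadings; `eigenvalues` carries the
#'   full spectrum including any negative part).
#' @export
pcoa <- function(d, n_axes = 2) {
  dm <- dm_values(d)
  n <- nrow(dm)
  if (n < 3L) stopf("PCoA needs at least 3 samples")
  if (n_axes > n - 1L) stopf("n_axes must be <= %d", n - 1L)
  a <- -0.5 * dm^2
  # sequential double-centering: A - row means - column means + grand mean
  g <- sweep(a, 1L, rowMeans(a), "-")
  g <- sweep(g, 2L, colMeans(g), "-")
  g <- (g + t(g)) / 2
  eg <- eigen(g, symmetric = TRUE)
  ev <- eg$values
  pos <- which(ev > max(ev, 0) * 1e-12 & ev > 0)
  if (length(pos) == 0L) stopf("no positive eigenvalue; degenerate distances")
  keep <- pos[seq_len(min(n_axes, length(pos)))]
  scores <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev[keep]), length(keep), length(keep))
  sg <- axis_signs(scores)
  scores <- sweep(scores, 2L, sg, "*")
  dimnames(scores) <- list(rownames(dm), paste0("Axis", seq_along(keep)))
  ordination_result(scores, loadings = NULL,
                    explained = ev[keep] / sum(ev[ev > 0]),
                    eigenvalues = ev, method = "pcoa")
}
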