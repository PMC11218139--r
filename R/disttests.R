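# Distance-based hypothesis tests: single-factor PERMANOVA and fuzzy set
# ordination. Both are permutation tests with the +1/+1 correction so p is
# never 0 and has resolution 1/(n_perm + 1).

# sum of squares partition for one labelling; d2 is the squared distance
# matrix, groups an integer vector of group codes
permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

#' Permutational multivariate analysis of variance (single factor)
#'
#' Partitions the total sum of squared distances by a grouping factor:
#' \eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2},
#' \eqn{SS_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2}, and
#' pseudo-F = \eqn{(SS_B/(a-1)) / (SS_W/(N-a))}. Significance comes from
#' random relabelling of samples; \eqn{R^2 = SS_B/SS_{total}} measures the
#' variability the grouping accounts for. Samples with a missing group
#' label are dropped and reported.
#'
#' @param d A `distance_matrix`.
#' @param groups Factor/character vector named by sample id, or aligned
#'   with the rows of `d`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed; fixed seed gives identical results.
#' @return A list of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `df_between`, `df_within`, `ss` (between/within/total), `n_perm`,
#'   `seed`, `dropped`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  dm <- dm_values(d)
  groups <- align_variable(groups, rownames(dm))
  keep <- !is.na(groups)
  dropped <- rownames(dm)[!keep]
  dm <- dm[keep, keep, drop = FALSE]
  groups <- factor(groups[keep])
  n <- nrow(dm)
  a <- nlevels(groups)
  if (a < 2L) stopf("PERMANOVA needs at least 2 groups with samples")
  if (any(table(groups) < 1L)) stopf("empty group after dropping missing labels")
  if (n - a < 1L) stopf("no residual degrees of freedom (N - a = 0)")
  d2 <- dm^2
  ss <- permanova_ss(d2, as.integer(groups))
  if (ss["total"] <= 0) stopf("degenerate distances: total sum of squares is 0")
  df_b <- a - 1L
  df_w <- n - a
  f_obs <- (ss["between"] / df_b) / (ss["within"] / df_w)
  gi <- as.integer(groups)
  f_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ssp <- permanova_ss(d2, gi[sample.int(n)])
      (ssp["between"] / df_b) / (ssp["within"] / df_w)
    }, numeric(1))
  })
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
  structure(
    list(pseudo_F = unname(f_obs), R2 = unname(ss["between"] / ss["total"]),
         p = p, df_between = df_b, df_within = df_w,
         ss = ss, n_perm = n_perm, seed = seed, dropped = dropped),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$df_between, x$df_within, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' Fuzzy set ordination against one continuous covariate
#'
#' Single-variable fuzzy set ordination: similarities
#' \eqn{s = 1 - d/\max(d)}, fuzzy memberships
#' \eqn{\mu_i = (x_i - \min x)/(\max x - \min x)}, apparent values
#' \eqn{\hat y_i = \sum_{j \ne i} s_{ij}\mu_j / \sum_{j \ne i} s_{ij}}, and
#' the correlation \eqn{r = cor(\mu, \hat y)} measuring how well the
#' covariate is expressed in community structure. Significance by
#' permutation of the covariate across samples.
#'
#' @param d A `distance_matrix` over at least 4 samples.
#' @param x Continuous covariate, named by sample id or aligned with `d`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return A list of class `fso_result`: `r`, `p`, `mu`, `apparent`,
#'   `n_perm`, `seed`, `dropped`.
#' @export
fso <- function(d, x, n_perm = 999, seed = 1) {
  dm <- dm_values(d)
  x <- align_variable(x, rownames(dm), numeric_ok = TRUE)
  keep <- is.finite(x)
  dropped <- rownames(dm)[!keep]
  dm <- dm[keep, keep, drop = FALSE]
  x <- x[keep]
  n <- nrow(dm)
  if (n < 4L) stopf("FSO needs at least 4 samples with finite covariate")
  dmax <- max(dm)
  if (dmax <= 0) stopf("all distances are zero; FSO undefined")
  if (max(x) == min(x)) stopf("constant covariate; FSO undefined")
  s <- 1 - dm / dmax
  diag(s) <- 0
  fso_fit <- function(xv) {
    mu <- (xv - min(xv)) / (max(xv) - min(xv))
    apparent <- as.vector(s %*% mu) / rowSums(s)
    list(mu = mu, apparent = apparent,
         r = stats::cor(mu, apparent))
  }
  obs <- fso_fit(x)
  r_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) fso_fit(x[sample.int(n)])$r,
           numeric(1))
  })
  p <- (sum(r_perm >= obs$r) + 1) / (n_perm + 1)
  structure(
    list(r = obs$r, p = p,
         mu = stats::setNames(obs$mu, rownames(dm)),
         apparent = stats::setNames(obs$apparent, rownames(dm)),
         n_perm = n_perm, seed = seed, dropped = dropped),
    class = "fso_result"
  )
}

#' @export
print.fso_result <- function(x, ...) {
  cat(sprintf("FSO: r = %.4f, p = %.4g (%d permutations, %d samples)\n",
              x$r, x$p, x$n_perm, length(x$mu)))
  invisible(x)
}

# match a metadata variable to distance-matrix ids: accept a named vector
# (matched by name) or an unnamed vector of the right length
align_variable <- function(v, ids, numeric_ok = FALSE) {
  if (!is.null(names(v))) {
    miss <- setdiff(ids, names(v))
    if (length(miss) > 0L) {
      stopf("variable has no value for sample(s): %s", paste(miss, collapse = ", "))
    }
    v <- v[ids]
  } else if (length(v) != length(ids)) {
    stopf("variable length %d does not match %d samples", length(v), length(ids))
  }
  if (numeric_ok) as.numeric(v) else as.character(v)
}
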