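#' Cophenetic (tip-to-tip) distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of tips,
#' computed by [ape::cophenetic.phylo()], with ids put in lexicographic
#' order for reproducibility.
#'
#' @param tree A rooted `phylo` tree with labelled tips.
#' @return A `distance_matrix`.
#' @export
cophenetic_matrix <- function(tree) {
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  ord <- lex_sort(rownames(d))
  d <- d[ord, ord]
  # guard against representation noise from path summation
  d <- (d + t(d)) / 2
  diag(d) <- 0
  distance_matrix(d, method = "cophenetic")
}

#' Observed MPD or MNTD of one community
#'
#' MPD is the mean pairwise phylogenetic distance over unordered pairs of
#' present taxa; MNTD the mean distance from each present taxon to its
#' nearest present neighbour. Undefined (`NA`) for fewer than two taxa.
#'
#' @param present Character vector of present feature ids.
#' @param d A `distance_matrix` containing all of them.
#' @param statistic `"mpd"` or `"mntd"`.
#' @return A single number, or `NA_real_` if fewer than 2 taxa are present.
#' @export
community_phylo_stat <- function(present, d, statistic = c("mpd", "mntd")) {
  statistic <- match.arg(statistic)
  missing_ids <- setdiff(present, rownames(d))
  if (length(missing_ids) > 0L) {
    stopf("taxa absent from distance matrix: %s",
          paste(missing_ids, collapse = ", "))
  }
  idx <- match(unique(present), rownames(d))
  phylo_stat_idx(dm_values(d), idx, statistic)
}

# statistic on integer tip positions; the permutation-null workhorse
phylo_stat_idx <- function(dm, idx, statistic) {
  k <- length(idx)
  if (k < 2L) return(NA_real_)
  sub <- dm[idx, idx, drop = FALSE]
  if (statistic == "mpd") {
    sum(sub[upper.tri(sub)]) / (k * (k - 1) / 2)
  } else {
    diag(sub) <- Inf
    mean(apply(sub, 1L, min))
  }
}

#' Standardized effect sizes of MPD/MNTD (NRI/NTI)
#'
#' For every sample, compares the observed statistic to a null distribution
#' obtained by shuffling taxon labels across the distance matrix
#' ("taxa.labels" null): each null replicate assigns the community's taxa
#' to a uniformly random subset of tip positions, the same relabelling
#' being applied to all samples. SES = (observed - null mean)/null sd;
#' NRI (for MPD) and NTI (for MNTD) are -SES, so positive values indicate
#' phylogenetic clustering. Where the null distribution is degenerate
#' (null sd = 0, e.g. a star tree) SES and the index are `NA` and the
#' sample is flagged.
#'
#' @param t A `feature_table`; values > 0 mark presence.
#' @param d A `distance_matrix` covering all features of `t`.
#' @param statistic `"mpd"` or `"mntd"`.
#' @param n_null Number of null relabellings (default 999).
#' @param seed Integer seed; results are bit-reproducible for a fixed seed.
#' @return A data frame of class `ses_result`: per sample the observed
#'   value, null mean/sd, `ses`, `index` (NRI or NTI), `rank_p`
#'   (= (#\{null <= observed\}+1)/(n_null+1)), `n_taxa` and a `degenerate`
#'   flag; `statistic`, `n_null` and `seed` are attached as attributes.
#' @export
ses_phylo <- function(t, d, statistic = c("mpd", "mntd"), n_null = 999,
                      seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(t, "feature_table"))
  if (n_null < 1) stopf("n_null must be >= 1")
  taxa <- feature_ids(t)
  missing_ids <- setdiff(taxa, rownames(d))
  if (length(missing_ids) > 0L) {
    stopf("feature ids absent from distance matrix: %s",
          paste(missing_ids, collapse = ", "))
  }
  dm <- dm_values(d)
  pool <- match(taxa, rownames(d))
  pres <- t$values > 0
  n_pool <- length(pool)

  obs <- vapply(seq_len(nrow(pres)), function(i) {
    phylo_stat_idx(dm, pool[pres[i, ]], statistic)
  }, numeric(1))

  null_mat <- with_seed(seed, {
    vapply(seq_len(n_null), function(rep) {
      relabel <- pool[sample.int(n_pool)]
      vapply(seq_len(nrow(pres)), function(i) {
        phylo_stat_idx(dm, relabel[pres[i, ]], statistic)
      }, numeric(1))
    }, numeric(nrow(pres)))
  })
  null_mat <- matrix(null_mat, nrow = nrow(pres))

  null_mean <- rowMeans(null_mat)
  null_sd <- apply(null_mat, 1L, stats::sd)
  ses <- ifelse(null_sd > 0, (obs - null_mean) / null_sd, NA_real_)
  rank_p <- vapply(seq_along(obs), function(i) {
    if (is.na(obs[i])) return(NA_real_)
    (sum(null_mat[i, ] <= obs[i]) + 1) / (n_null + 1)
  }, numeric(1))

  out <- data.frame(
    sample_id = sample_ids(t),
    statistic = statistic,
    n_taxa = rowSums(pres),
    observed = obs,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = ses,
    index = -ses,
    rank_p = rank_p,
    degenerate = !is.na(obs) & null_sd == 0,
    stringsAsFactors = FALSE
  )
  attr(out, "index_name") <- if (statistic == "mpd") "NRI" else "NTI"
  attr(out, "n_null") <- n_null
  attr(out, "seed") <- seed
  class(out) <- c("ses_result", "data.frame")
  out
}
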