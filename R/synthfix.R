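# Seeded generators with planted, known structure. Their defaults define
# the validation study conditions used throughout the test-suite and the
# acceptance script; every generator is bit-reproducible for a fixed seed.

#' Simulate an overdispersed case-control community count table
#'
#' Counts follow a gamma-mixed Poisson (negative-binomial-like) model:
#' each taxon has a log-normal baseline abundance (meanlog `log(20)`,
#' sdlog 1), samples are split into balanced groups, and the first
#' `n_affected` taxa receive a log-scale offset of size `effect` in every
#' non-reference group (alternating sign across affected taxa, so planted
#' changes go both up and down). The multiplicative gamma noise has mean 1
#' and variance `dispersion`.
#'
#' @param n_samples,n_taxa Table dimensions.
#' @param n_groups Number of balanced groups (default 2).
#' @param n_affected Number of truly differential taxa.
#' @param effect Log-scale group offset on affected taxa.
#' @param dispersion Variance of the multiplicative gamma noise
#'   (default 0.5).
#' @param seed Integer seed.
#' @return A list: `table` (raw `feature_table`), `metadata`
#'   (`sample_metadata` with a `group` factor) and `truth` (group
#'   assignment, affected taxa, per-taxon log-offsets, seed).
#' @export
simulate_community <- function(n_samples = 60, n_taxa = 200, n_groups = 2,
                               n_affected = 5, effect = 2, dispersion = 0.5,
                               seed = 1) {
  if (n_affected > n_taxa) stopf("n_affected must be <= n_taxa")
  if (n_samples < 2L * n_groups) stopf("need at least 2 samples per group")
  if (dispersion <= 0 || effect < 0) stopf("invalid effect/dispersion")
  with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    taxa <- sprintf("T%03d", seq_len(n_taxa))
    group <- factor(rep_len(paste0("G", seq_len(n_groups)), n_samples))
    base_log <- stats::rnorm(n_taxa, mean = log(20), sd = 1)
    offsets <- matrix(0, n_groups, n_taxa)
    if (n_affected > 0 && effect > 0) {
      sign_alt <- rep_len(c(1, -1), n_affected)
      for (g in seq_len(n_groups)[-1L]) {
        offsets[g, seq_len(n_affected)] <- effect * sign_alt
      }
    }
    lambda <- exp(sweep(offsets[as.integer(group), , drop = FALSE], 2L,
                        base_log, "+"))
    shape <- 1 / dispersion
    noise <- matrix(stats::rgamma(n_samples * n_taxa, shape = shape,
                                  rate = shape), n_samples, n_taxa)
    counts <- matrix(stats::rpois(n_samples * n_taxa, lambda * noise),
                     n_samples, n_taxa, dimnames = list(samples, taxa))
    meta <- data.frame(group = group, row.names = samples)
    class(meta) <- c("sample_metadata", "data.frame")
    list(
      table = feature_table(counts + 0, feature_kind = "taxon_cluster",
                            transform_tag = "raw"),
      metadata = meta,
      truth = list(seed = seed, group = stats::setNames(group, samples),
                   affected = if (effect > 0) taxa[seq_len(n_affected)] else character(),
                   log_offsets = offsets, dispersion = dispersion)
    )
  })
}

#' Simulate two paired omics blocks with planted joint and distinctive
#' structure
#'
#' \eqn{X_b = T P_b^T + D_b Q_b^T + E_b}: a shared orthonormal score
#' matrix T (joint structure across both blocks), block-specific
#' orthonormal distinctive scores D_b orthogonal to T and to each other,
#' unit-norm loadings, and Gaussian noise with standard deviation
#' `noise_sd`. Each planted component has unit energy, so a block's
#' signal-to-noise ratio is (number of planted components) /
#' (n_samples * p_b * noise_sd^2); the default `noise_sd = 0.01` puts the
#' default geometry deep in the high-SNR regime.
#'
#' @param n_samples Number of shared samples.
#' @param p1,p2 Features per block.
#' @param joint_rank Planted joint rank (may be 0).
#' @param distinct_ranks Integer pair of planted distinctive ranks.
#' @param noise_sd Standard deviation of the entrywise Gaussian noise.
#' @param seed Integer seed.
#' @return A list: `blocks` (two centered `feature_table`s), `truth`
#'   (joint scores `t`, joint loadings `p1`/`p2`, distinctive scores and
#'   loadings, seed).
#' @export
simulate_paired_blocks <- function(n_samples = 40, p1 = 30, p2 = 25,
                                   joint_rank = 1, distinct_ranks = c(1, 1),
                                   noise_sd = 0.01, seed = 1) {
  r_all <- joint_rank + sum(distinct_ranks)
  if (r_all >= n_samples) stopf("ranks infeasible for n_samples")
  if (joint_rank > min(p1, p2) || any(distinct_ranks > c(p1, p2))) {
    stopf("ranks infeasible for block widths")
  }
  with_seed(seed, {
    samples <- sprintf("S%03d", seq_len(n_samples))
    # plant scores inside the sample-centered subspace so the structure
    # is untouched by column-centering and stays exactly orthonormal
    raw_basis <- scale(matrix(stats::rnorm(n_samples * max(r_all, 1)),
                              n_samples), scale = FALSE)
    basis <- qr.Q(qr(raw_basis))
    tj <- basis[, seq_len(joint_rank), drop = FALSE]
    d1 <- basis[, joint_rank + seq_len(distinct_ranks[1L]), drop = FALSE]
    d2 <- basis[, joint_rank + distinct_ranks[1L] + seq_len(distinct_ranks[2L]),
                drop = FALSE]
    unit_cols <- function(p, r) {
      m <- matrix(stats::rnorm(p * r), p, r)
      if (r > 0) sweep(m, 2L, sqrt(colSums(m^2)), "/") else m
    }
    pj1 <- unit_cols(p1, joint_rank)
    pj2 <- unit_cols(p2, joint_rank)
    q1 <- unit_cols(p1, distinct_ranks[1L])
    q2 <- unit_cols(p2, distinct_ranks[2L])
    x1 <- tj %*% t(pj1) + d1 %*% t(q1) +
      matrix(stats::rnorm(n_samples * p1, sd = noise_sd), n_samples, p1)
    x2 <- tj %*% t(pj2) + d2 %*% t(q2) +
      matrix(stats::rnorm(n_samples * p2, sd = noise_sd), n_samples, p2)
    dimnames(x1) <- list(samples, sprintf("A%03d", seq_len(p1)))
    dimnames(x2) <- list(samples, sprintf("B%03d", seq_len(p2)))
    x1 <- scale(x1, scale = FALSE)
    x2 <- scale(x2, scale = FALSE)
    attr(x1, "scaled:center") <- attr(x2, "scaled:center") <- NULL
    list(
      blocks = list(
        block1 = feature_table(x1, transform_tag = "centered"),
        block2 = feature_table(x2, transform_tag = "centered")
      ),
      truth = list(seed = seed, t = tj, p1 = pj1, p2 = pj2,
                   d1 = d1, d2 = d2, q1 = q1, q2 = q2,
                   noise_sd = noise_sd)
    )
  })
}

#' Simulate a pure-birth (Yule) tree
#'
#' Constant-rate birth process via [ape::rphylo()] (birth 1, death 0),
#' giving a Yule topology with exponentially distributed waiting times;
#' tips are relabelled `T1..Tn`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param model Only `"yule"` is implemented.
#' @param seed Integer seed.
#' @return A `phylo` tree.
#' @export
simulate_tree <- function(n_tips, model = "yule", seed = 1) {
  if (!identical(model, "yule")) stopf("unknown tree model '%s'", model)
  if (n_tips < 2L) stopf("a tree needs at least 2 tips")
  with_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$tip.label <- paste0("T", seq_len(n_tips))
    validate_tree(tree)
  })
}
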