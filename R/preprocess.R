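#' Convert counts to relative abundances
#'
#' Divides each sample row by its total so rows sum to one. Within-sample
#' rank order of features is preserved.
#'
#' @param t A raw `feature_table` with positive row sums.
#' @return A `feature_table` with `transform_tag = "relative"`.
#' @export
relative_abundance <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (t$transform_tag != "raw") stopf("relative_abundance expects raw counts")
  rs <- rowSums(t$values)
  if (any(rs <= 0)) {
    stopf("sample(s) with zero total abundance: %s",
          paste(sample_ids(t)[rs <= 0], collapse = ", "))
  }
  feature_table(t$values / rs, feature_kind = t$feature_kind,
                transform_tag = "relative")
}

#' Natural-log transform with pseudocount
#'
#' Computes `ln(x + eps)`. By default `eps` is half the smallest non-zero
#' entry of the whole table (a global pseudocount, so zeros map to a single
#' well-defined floor); alternatively a fixed positive value.
#'
#' @param t A `feature_table` with non-negative values.
#' @param pseudocount_mode `"half_min_nonzero"` (default) or `"fixed"`.
#' @param fixed_value Pseudocount used when `pseudocount_mode = "fixed"`.
#' @return A `feature_table`; tag becomes `"log_relative"` when the input
#'   was relative, `"centered"`-compatible generic otherwise.
#' @export
log_transform <- function(t,
                          pseudocount_mode = c("half_min_nonzero", "fixed"),
                          fixed_value = NULL) {
  stopifnot(inherits(t, "feature_table"))
  pseudocount_mode <- match.arg(pseudocount_mode)
  if (any(t$values < 0)) stopf("log_transform needs non-negative values")
  if (pseudocount_mode == "fixed") {
    if (is.null(fixed_value) || !is.numeric(fixed_value) || fixed_value <= 0) {
      stopf("fixed pseudocount must be a positive number")
    }
    eps <- fixed_value
  } else {
    nz <- t$values[t$values > 0]
    if (length(nz) == 0L) stopf("table is all zero; no pseudocount defined")
    eps <- min(nz) / 2
  }
  # a log table is no longer on the raw scale, whatever it started as
  tag <- if (t$transform_tag == "relative") "log_relative" else "centered"
  out <- feature_table(log(t$values + eps), feature_kind = t$feature_kind,
                       transform_tag = tag)
  attr(out, "pseudocount") <- eps
  out
}

#' Pareto scaling
#'
#' The metabolomics convention: per feature, subtract the mean and divide
#' by the square root of the sample (n-1) standard deviation. Features with
#' zero variance are set to all-zero and listed in the attached report.
#'
#' @param t A `feature_table` with at least two samples.
#' @return A `feature_table` with `transform_tag = "pareto"` and a
#'   `"constant_features"` attribute naming degenerate features.
#' @export
pareto_scale <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (nrow(t$values) < 2L) stopf("pareto scaling needs at least 2 samples")
  mu <- colMeans(t$values)
  sd_ <- apply(t$values, 2L, stats::sd)
  out <- sweep(t$values, 2L, mu, "-")
  ok <- sd_ > 0
  out[, ok] <- sweep(out[, ok, drop = FALSE], 2L, sqrt(sd_[ok]), "/")
  out[, !ok] <- 0
  res <- feature_table(out, feature_kind = t$feature_kind,
                       transform_tag = "pareto")
  attr(res, "constant_features") <- feature_ids(t)[!ok]
  res
}

#' Aggregate contig coverages into cluster abundances
#'
#' Collapses a contig coverage table into genome-cluster abundances using a
#' contig-to-cluster assignment (CONCOCT-style). Contigs absent from the
#' assignment are dropped and reported.
#'
#' @param coverage A `feature_table` whose features are contigs.
#' @param assignment A `mapping_table` with role `contig_to_cluster`.
#' @param stat `"mean"` (default, cluster abundance = average member
#'   coverage) or `"sum"`.
#' @return A `feature_table` with `feature_kind = "taxon_cluster"` and a
#'   `"dropped_contigs"` attribute.
#' @export
aggregate_by_group <- function(coverage, assignment, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  stopifnot(inherits(coverage, "feature_table"),
            inherits(assignment, "mapping_table"))
  if (!identical(attr(assignment, "role"), "contig_to_cluster")) {
    stopf("assignment must have role contig_to_cluster")
  }
  contigs <- feature_ids(coverage)
  keep <- contigs %in% assignment$element_id
  if (!any(keep)) stopf("no contig in the coverage table matches the assignment")
  cl <- assignment$group_id[match(contigs[keep], assignment$element_id)]
  vals <- coverage$values[, keep, drop = FALSE]
  clusters <- lex_sort(unique(cl))
  agg <- vapply(clusters, function(g) {
    m <- vals[, cl == g, drop = FALSE]
    if (stat == "mean") rowMeans(m) else rowSums(m)
  }, numeric(nrow(vals)))
  agg <- matrix(agg, nrow = nrow(vals),
                dimnames = list(sample_ids(coverage), clusters))
  res <- feature_table(agg, feature_kind = "taxon_cluster",
                       transform_tag = coverage$transform_tag)
  attr(res, "dropped_contigs") <- contigs[!keep]
  res
}

#' Center and Frobenius-scale a block for multi-block analysis
#'
#' Column-centers the matrix, then divides the whole block by its Frobenius
#' norm so every block enters a joint decomposition with equal total sum of
#' squares (1). The returned scaling record allows exact inversion back to
#' the centered block.
#'
#' @param t A `feature_table` with at least 2 samples.
#' @return A list with `table` (tagged `"centered"`) and `scaling`
#'   (class `block_scaling`: per-feature centers, global `block_norm`,
#'   `block_weight`).
#' @export
block_scale <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (nrow(t$values) < 2L) stopf("block scaling needs at least 2 samples")
  centers <- colMeans(t$values)
  centered <- sweep(t$values, 2L, centers, "-")
  nrm <- sqrt(fnorm2(centered))
  if (nrm == 0) stopf("block is constant; cannot scale")
  scaled <- centered / nrm
  scaling <- structure(
    list(centers = centers, block_norm = nrm, block_weight = 1),
    class = "block_scaling"
  )
  list(
    table = feature_table(scaled, feature_kind = t$feature_kind,
                          transform_tag = "centered"),
    scaling = scaling
  )
}

#' Invert block scaling
#'
#' @param t The scaled `feature_table` returned by [block_scale()].
#' @param scaling The matching `block_scaling` record.
#' @param recenter Add the feature means back? Default `FALSE` returns the
#'   centered block.
#' @return A `feature_table`.
#' @export
block_unscale <- function(t, scaling, recenter = FALSE) {
  stopifnot(inherits(t, "feature_table"), inherits(scaling, "block_scaling"))
  vals <- t$values * scaling$block_norm
  if (recenter) vals <- sweep(vals, 2L, scaling$centers, "+")
  feature_table(vals, feature_kind = t$feature_kind,
                transform_tag = "centered")
}
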