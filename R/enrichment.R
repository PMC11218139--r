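# KEGG-ortholog pathway over-representation. The counting unit is the KO:
# a feature contributes the union of its KOs, and pathway membership is a
# pure set computation, so results are invariant to KO renaming.

#' Build pathway KO-sets from mapping tables
#'
#' Combines feature-to-KO annotations with KO-to-pathway membership into
#' deduplicated pathway sets. The default background universe contains the
#' KOs that appear in at least one pathway; KOs with no pathway are
#' reported separately.
#'
#' @param feature_to_ko A `mapping_table` with role `feature_to_ko`.
#' @param ko_to_pathway A `mapping_table` with role `ko_to_pathway`.
#' @param universe `"annotated-only"` (default: KOs in >= 1 pathway) or
#'   `"all-annotated"` (every KO seen in the feature annotation).
#' @return A list: `pathway_sets` (named list of KO character vectors),
#'   `feature_index` (named list feature -> KOs), `universe` (character),
#'   `unmapped_kos`.
#' @export
build_pathway_sets <- function(feature_to_ko, ko_to_pathway,
                               universe = c("annotated-only", "all-annotated")) {
  universe <- match.arg(universe)
  stopifnot(inherits(feature_to_ko, "mapping_table"),
            inherits(ko_to_pathway, "mapping_table"))
  feature_index <- split(feature_to_ko$group_id, feature_to_ko$element_id)
  feature_index <- lapply(feature_index, unique)
  pathway_sets <- split(ko_to_pathway$element_id, ko_to_pathway$group_id)
  pathway_sets <- lapply(pathway_sets, unique)
  all_kos <- unique(feature_to_ko$group_id)
  in_pathway <- unique(unlist(pathway_sets, use.names = FALSE))
  unmapped <- setdiff(all_kos, in_pathway)
  uni <- if (universe == "annotated-only") intersect(all_kos, in_pathway) else all_kos
  if (length(uni) == 0L) stopf("empty KO universe after filtering")
  list(pathway_sets = pathway_sets, feature_index = feature_index,
       universe = lex_sort(uni), unmapped_kos = lex_sort(unmapped))
}

#' Pathway over-representation test
#'
#' One-sided hypergeometric upper-tail test per pathway: with `N` the
#' universe size, `K` the pathway's universe members, `n` the selection
#' size and `k` the selected pathway members,
#' \eqn{p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}}.
#' BH adjustment across the tested pathways; rows sorted by p, ties by
#' pathway id.
#'
#' @param selected_kos Character vector of selected KOs (subset of the
#'   universe).
#' @param universe Character vector of background KOs.
#' @param pathway_sets Named list of pathway KO-sets (only members inside
#'   the universe are counted; pathways with none are skipped).
#' @return Data frame with `pathway_id`, `k`, `K`, `n`, `N`, `p`, `padj`.
#' @export
pathway_enrichment <- function(selected_kos, universe, pathway_sets) {
  selected_kos <- unique(as.character(selected_kos))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stopf("empty universe")
  outside <- setdiff(selected_kos, universe)
  if (length(outside) > 0L) {
    stopf("selected KOs outside the universe: %s", paste(outside, collapse = ", "))
  }
  n <- length(selected_kos)
  N <- length(universe)
  rows <- lapply(names(pathway_sets), function(pid) {
    members <- intersect(pathway_sets[[pid]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(selected_kos, members))
    # upper tail including k itself
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stopf("no pathway overlaps the universe")
  out <- do.call(rbind, rows)
  out$padj <- adjust_pvalues(out$p, "bh")
  out <- out[order(out$p, out$pathway_id, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' KOs of a feature selection
#'
#' Convenience handoff from a differential-abundance result: maps selected
#' feature ids to the union of their KOs via the feature index from
#' [build_pathway_sets()].
#'
#' @param features Character vector of feature ids.
#' @param feature_index Named list feature -> KOs.
#' @return Character vector of KOs.
#' @export
features_to_kos <- function(features, feature_index) {
  lex_sort(unique(unlist(feature_index[intersect(features, names(feature_index))],
                         use.names = FALSE)))
}
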