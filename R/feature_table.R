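#' Construct a feature table
#'
#' The central data container: a samples-by-features numeric matrix with a
#' feature kind (taxon cluster, metabolite, gene function) and a tag
#' recording which transformation the values are on. All downstream
#' operations assume the canonical samples-in-rows layout enforced here.
#'
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   unique row and column names.
#' @param feature_kind One of `"taxon_cluster"`, `"metabolite"`,
#'   `"gene_function"`, `"generic"`.
#' @param transform_tag One of `"raw"`, `"relative"`, `"log_relative"`,
#'   `"pareto"`, `"centered"`. Raw values must be non-negative.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values,
                          feature_kind = c("generic", "taxon_cluster",
                                           "metabolite", "gene_function"),
                          transform_tag = c("raw", "relative", "log_relative",
                                            "pareto", "centered")) {
  feature_kind <- match.arg(feature_kind)
  transform_tag <- match.arg(transform_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("feature table values must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) {
    stopf("feature table is empty")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("feature table needs sample (row) and feature (column) names")
  }
  if (anyDuplicated(rownames(values))) {
    stopf("duplicated sample ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicated feature ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  }
  if (any(!is.finite(values))) {
    stopf("feature table contains NA/NaN/Inf values")
  }
  if (transform_tag == "raw" && any(values < 0)) {
    stopf("raw feature table contains negative values")
  }
  structure(
    list(values = values, feature_kind = feature_kind,
         transform_tag = transform_tag),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$feature_kind, x$transform_tag))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Sample identifiers of a feature table
#' @param t A `feature_table`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(t) rownames(t$values)

#' Feature identifiers of a feature table
#' @param t A `feature_table`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(t) colnames(t$values)

#' Construct a pairwise sample distance matrix
#'
#' Validates symmetry, a zero diagonal and non-negative entries.
#'
#' @param d Square numeric matrix with identical, unique row/column names.
#' @param method Optional label recording how the distances were computed.
#' @return An object of class `distance_matrix` (a named square matrix).
#' @export
distance_matrix <- function(d, method = "unknown") {
  if (!is.matrix(d) || !is.numeric(d)) stopf("distances must be a numeric matrix")
  if (nrow(d) != ncol(d)) stopf("distance matrix must be square")
  if (is.null(rownames(d)) || is.null(colnames(d))) {
    stopf("distance matrix needs row and column names")
  }
  if (!identical(rownames(d), colnames(d))) {
    stopf("distance matrix row and column names differ")
  }
  if (anyDuplicated(rownames(d))) stopf("duplicated ids in distance matrix")
  if (any(!is.finite(d))) stopf("distance matrix contains non-finite entries")
  if (max(abs(d - t(d))) > 1e-12) stopf("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 0)) stopf("distance matrix diagonal must be exactly 0")
  if (any(d < 0)) stopf("distance matrix has negative entries")
  structure(d, class = c("distance_matrix", "matrix"), method = method)
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d samples, method = %s\n",
              nrow(x), attr(x, "method") %||% "unknown"))
  invisible(x)
}

# strip the class so plain matrix algebra applies
dm_values <- function(d) {
  m <- unclass(d)
  attr(m, "method") <- NULL
  m
}
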