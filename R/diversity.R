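#' Alpha diversity per sample
#'
#' With \eqn{p_i} the within-sample proportions over non-zero features:
#' Shannon entropy \eqn{H = -\sum p_i \ln p_i} (natural log), the
#' Gini-Simpson index \eqn{D = 1 - \sum p_i^2} (larger = more diverse), and
#' Pielou's evenness \eqn{J = H / \ln S} with \eqn{S} the number of non-zero
#' features. \eqn{J} is undefined (`NA`) for single-feature samples. All
#' three are invariant to rescaling a sample's counts.
#'
#' @param t A `feature_table` with non-negative values and positive row sums.
#' @param index `"shannon"`, `"simpson"` or `"pielou"`.
#' @return A data frame with columns `sample_id`, `index`, `value`.
#' @export
alpha_diversity <- function(t, index = c("shannon", "simpson", "pielou")) {
  index <- match.arg(index)
  stopifnot(inherits(t, "feature_table"))
  if (any(t$values < 0)) stopf("alpha diversity needs non-negative abundances")
  rs <- rowSums(t$values)
  if (any(rs <= 0)) {
    stopf("sample(s) with zero total abundance: %s",
          paste(sample_ids(t)[rs <= 0], collapse = ", "))
  }
  vals <- apply(t$values, 1L, function(x) {
    p <- x[x > 0]
    p <- p / sum(p)
    switch(index,
           shannon = -sum(p * log(p)),
           simpson = 1 - sum(p^2),
           pielou = if (length(p) < 2L) NA_real_ else -sum(p * log(p)) / log(length(p)))
  })
  data.frame(sample_id = sample_ids(t), index = index, value = unname(vals),
             stringsAsFactors = FALSE)
}
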