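# Small fixtures built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

make_ft <- function(values, samples = NULL, features = NULL, ...) {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(samples))
  rownames(values) <- samples %||% sprintf("S%02d", seq_len(nrow(values)))
  colnames(values) <- features %||% sprintf("F%02d", seq_len(ncol(values)))
  args <- list(...)
  if (is.null(args$transform_tag) && any(values < 0)) {
    args$transform_tag <- "centered"
  }
  do.call(feature_table, c(list(values), args))
}

# population (divide-by-n) standard deviation for exhaustive-null oracles
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Monte-Carlo standard error of the sample sd of n draws from the discrete
# distribution x (kurtosis-aware; the normal-theory sd/sqrt(2n) understates
# it for two-point nulls)
se_of_sd <- function(x, n) {
  s2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  sqrt(max(m4 - s2^2, 0) / (4 * s2 * n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tmp <- function(lines, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  writeLines(lines, path)
  path
}

tree_text <- function(txt) ape::read.tree(text = txt)

# random raw count table
random_counts <- function(n, p, seed = 1) {
  with_seed(seed, make_ft(matrix(rpois(n * p, 10) + 0, n, p)))
}
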