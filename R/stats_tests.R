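# Nonparametric group comparison and correlation. Omnibus tests delegate
# to the base-R implementations (kruskal.test, friedman.test, cor.test,
# p.adjust); the Dunn post hoc is computed here since base R has none.

#' Kruskal-Wallis rank-sum test
#'
#' Mid-ranks for ties and the tie-corrected H statistic, with p from the
#' chi-square distribution on (number of groups - 1) degrees of freedom.
#' All-identical values give H = 0, p = 1 (no variation, not an error).
#'
#' @param values Numeric vector.
#' @param groups Factor/character of the same length, at least 2 levels.
#' @return A list with `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stopf("Kruskal-Wallis needs at least 2 groups")
  if (length(values) < 3L) stopf("Kruskal-Wallis needs at least 3 observations")
  if (max(values) == min(values)) {
    return(list(statistic = 0, df = nlevels(groups) - 1L, p = 1))
  }
  ht <- stats::kruskal.test(values, groups)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Friedman test for repeated measures
#'
#' Within-block mid-ranks with tie correction; blocks with any missing
#' cell are dropped and reported. Identical treatment columns give
#' chi-squared = 0, p = 1.
#'
#' @param block_matrix Numeric matrix, blocks (subjects) in rows,
#'   treatments in columns.
#' @return A list with `statistic`, `df`, `p`, `n_blocks`,
#'   `dropped_blocks`.
#' @export
friedman <- function(block_matrix) {
  if (!is.matrix(block_matrix)) block_matrix <- as.matrix(block_matrix)
  if (ncol(block_matrix) < 2L) stopf("Friedman test needs >= 2 treatments")
  complete <- stats::complete.cases(block_matrix)
  dropped <- rownames(block_matrix)[!complete] %||% which(!complete)
  m <- block_matrix[complete, , drop = FALSE]
  if (nrow(m) < 2L) stopf("Friedman test needs >= 2 complete blocks")
  ranks <- t(apply(m, 1L, rank))
  if (all(abs(ranks - ranks[, 1L]) < .Machine$double.eps^0.5)) {
    return(list(statistic = 0, df = ncol(m) - 1L, p = 1,
                n_blocks = nrow(m), dropped_blocks = dropped))
  }
  ht <- stats::friedman.test(m)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), n_blocks = nrow(m), dropped_blocks = dropped)
}

#' Dunn's post hoc pairwise comparisons
#'
#' For every unordered pair of groups,
#' \eqn{z_{ab} = (\bar R_a - \bar R_b) / \sqrt{\left[\frac{N(N+1)}{12} -
#' \frac{\sum (t^3 - t)}{12(N-1)}\right]\left(\frac{1}{n_a} +
#' \frac{1}{n_b}\right)}} on the global mid-ranks, with a two-sided normal
#' p-value and multiplicity adjustment across the pairs.
#'
#' @param values Numeric vector.
#' @param groups Factor/character of the same length.
#' @param adjust `"bh"` (default), `"bonferroni"` or `"none"`.
#' @return Data frame with `group_a`, `group_b`, `z`, `p`, `padj`.
#' @export
dunn_posthoc <- function(values, groups, adjust = c("bh", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L) stopf("Dunn post hoc needs at least 2 groups")
  if (any(table(groups) < 1L)) stopf("empty group")
  n <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab)
  var_core <- n * (n + 1) / 12 - tie_term / (12 * (n - 1))
  mean_ranks <- tapply(r, groups, mean)
  sizes <- table(groups)
  levs <- levels(groups)
  pairs <- utils::combn(levs, 2L)
  z <- apply(pairs, 2L, function(pr) {
    (mean_ranks[[pr[1L]]] - mean_ranks[[pr[2L]]]) /
      sqrt(var_core * (1 / sizes[[pr[1L]]] + 1 / sizes[[pr[2L]]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  padj <- adjust_pvalues(p, method = if (adjust == "none") NULL else adjust)
  data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
             z = z, p = p, padj = padj, stringsAsFactors = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up or Bonferroni, via [stats::p.adjust()].
#'
#' @param p Numeric vector in \[0, 1\].
#' @param method `"bh"` (default) or `"bonferroni"`; `NULL` returns `p`
#'   unchanged.
#' @return Adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  if (is.null(method)) return(p)
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni")[[method]])
}

#' Correlation between two paired variables
#'
#' Pearson product-moment, Spearman (Pearson on mid-ranks, t
#' approximation) or Kendall tau-b with tie correction (normal
#' approximation); two-sided p-values. Incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return A list of class `correlation_result`: `method`, `r`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) stopf("correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero variance in x or y; correlation undefined")
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  structure(list(method = method, r = unname(ht$estimate),
                 p = unname(ht$p.value), n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f, p = %.4g, n = %d\n",
              x$method, x$r, x$p, x$n))
  invisible(x)
}

#' Per-feature differential abundance table
#'
#' Runs the omnibus test on every feature of a harmonized table
#' (Kruskal-Wallis for independent groups, Friedman for a repeated /
#' blocked design), adjusts the omnibus p-values across features by
#' Benjamini-Hochberg, and for the independent design computes Dunn's
#' pairwise post hoc (BH across pairs within each feature) for features
#' with `padj <= alpha`. Constant or otherwise degenerate features are
#' flagged rather than aborting the run.
#'
#' @param t A `feature_table` (values on the analysis scale; group means
#'   are reported on that scale).
#' @param groups Grouping variable, named by sample id or aligned to rows.
#' @param design `"independent"` (Kruskal-Wallis, default) or `"repeated"`
#'   (Friedman; requires `blocks`).
#' @param blocks Subject/block identifiers for the repeated design.
#' @param alpha Post hoc gate on the BH-adjusted omnibus p (default 0.05).
#' @return A list of class `differential_result`: `features` (one row per
#'   feature: statistic, df, p, padj, group means, flag) and `pairwise`
#'   (long Dunn table with feature_id).
#' @export
differential_table <- function(t, groups, design = c("independent", "repeated"),
                               blocks = NULL, alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(inherits(t, "feature_table"))
  groups <- align_variable(groups, sample_ids(t))
  keep <- !is.na(groups)
  vals <- t$values[keep, , drop = FALSE]
  gf <- factor(groups[keep])
  if (design == "repeated") {
    if (is.null(blocks)) stopf("repeated design needs `blocks` (subject ids)")
    blocks <- align_variable(blocks, sample_ids(t))[keep]
  }
  feats <- feature_ids(t)
  rows <- lapply(seq_along(feats), function(j) {
    v <- vals[, j]
    gm <- tapply(v, gf, mean)
    res <- tryCatch({
      if (design == "independent") {
        if (max(v) == min(v)) stop("constant feature")
        kruskal_wallis(v, gf)
      } else {
        bm <- tapply(v, list(blocks, gf), mean)
        fr <- friedman(bm)
        list(statistic = fr$statistic, df = fr$df, p = fr$p)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      data.frame(feature_id = feats[j], statistic = NA_real_, df = NA_integer_,
                 p = NA_real_, t(gm), flag = "degenerate",
                 stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      data.frame(feature_id = feats[j], statistic = res$statistic,
                 df = res$df, p = res$p, t(gm), flag = "",
                 stringsAsFactors = FALSE, check.names = FALSE)
    }
  })
  features <- do.call(rbind, rows)
  names(features)[5:(4 + nlevels(gf))] <- paste0("mean_", levels(gf))
  features$padj <- NA_real_
  tested <- !is.na(features$p)
  features$padj[tested] <- adjust_pvalues(features$p[tested], "bh")

  pairwise <- NULL
  if (design == "independent") {
    hits <- which(tested & features$padj <= alpha)
    pw <- lapply(hits, function(j) {
      out <- dunn_posthoc(vals[, j], gf, adjust = "bh")
      cbind(feature_id = feats[j], out, stringsAsFactors = FALSE)
    })
    pairwise <- if (length(pw) > 0L) do.call(rbind, pw) else
      data.frame(feature_id = character(), group_a = character(),
                 group_b = character(), z = numeric(), p = numeric(),
                 padj = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(features = features, pairwise = pairwise,
                 design = design, alpha = alpha),
            class = "differential_result")
}

#' @export
print.differential_result <- function(x, ...) {
  n_sig <- sum(x$features$padj <= x$alpha, na.rm = TRUE)
  cat(sprintf("<differential_result> %s design: %d features, %d at padj <= %g\n",
              x$design, nrow(x$features), n_sig, x$alpha))
  invisible(x)
}
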