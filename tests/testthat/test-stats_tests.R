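test_that("Kruskal-Wallis matches hand-ranked examples", {
  res <- kruskal_wallis(1:9, rep(c("a", "b", "c"), each = 3))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2L)

  flat <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  # two-group H equals the squared standardized Wilcoxon rank-sum statistic
  with_seed(19, {
    x <- sample(seq(0.01, 1, by = 0.01), 14)  # tie-free
    g <- rep(c("a", "b"), c(6, 8))
    r <- rank(x)
    w <- sum(r[g == "a"])
    n1 <- 6; n2 <- 8; n <- 14
    z <- (w - n1 * (n + 1) / 2) / sqrt(n1 * n2 * (n + 1) / 12)
    expect_equal(kruskal_wallis(x, g)$statistic, z^2, tolerance = 1e-10)
  })
})

test_that("Friedman test matches hand examples and label symmetry", {
  same_order <- matrix(rep(c(10, 20, 30), 3), 3, byrow = TRUE)
  res <- friedman(same_order)
  expect_equal(res$statistic, 6, tolerance = 1e-12)
  expect_equal(res$df, 2L)

  no_effect <- matrix(rep(c(1, 1, 1), 4), 4, byrow = TRUE)
  flat <- friedman(no_effect)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  m <- with_seed(2, matrix(rnorm(15), 5, 3))
  expect_equal(friedman(m[, c(3, 1, 2)])$statistic, friedman(m)$statistic,
               tolerance = 1e-12)

  # incomplete blocks are dropped, too few blocks error
  m_na <- m
  m_na[1, 2] <- NA
  expect_equal(friedman(m_na)$n_blocks, 4L)
  expect_error(friedman(matrix(c(1, NA, NA, 3, 5, NA), 3, 2)), "complete blocks")
})

test_that("Dunn z statistics follow the tie-corrected formula", {
  v <- c(1, 2, 3, 4, 10, 11, 12, 13)
  g <- rep(c("lo", "hi"), each = 4)
  dn <- dunn_posthoc(v, g, adjust = "none")
  # two-group z^2 equals the Kruskal-Wallis H (tie-free)
  expect_equal(dn$z^2, kruskal_wallis(v, g)$statistic, tolerance = 1e-10)

  ident <- dunn_posthoc(rep(c(5, 6), 4), rep(c("a", "b"), each = 4))
  expect_equal(ident$z, 0)
  expect_equal(ident$p, 1)

  v3 <- c(1, 2, 3, 11, 12, 13, 21, 22, 23)
  g3 <- rep(c("a", "b", "c"), each = 3)
  dn3 <- dunn_posthoc(v3, g3)
  extreme <- dn3[dn3$group_a == "a" & dn3$group_b == "c", ]
  expect_equal(max(abs(dn3$z)), abs(extreme$z))
  expect_equal(nrow(dn3), 3L)  # all unordered pairs
  expect_true(all(dn3$padj >= dn3$p))
})

test_that("p-value adjustment reproduces the BH step-up by hand", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.04, "bh"), 0.04)
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  with_seed(5, {
    p <- runif(20)
    q <- adjust_pvalues(p, "bh")
    expect_true(all(q >= p))
    expect_identical(order(q[order(p)]), 1:20)  # no rank reordering
  })
  expect_error(adjust_pvalues(c(0.1, 1.2), "bh"), "0, 1")
})

test_that("rank statistics are invariant under monotone transforms", {
  with_seed(23, {
    x <- rlnorm(18)
    g <- rep(c("a", "b", "c"), 6)
    for (f in list(function(z) z, log, function(z) z^3, function(z) rank(z))) {
      expect_equal(kruskal_wallis(f(x), g)$statistic,
                   kruskal_wallis(x, g)$statistic, tolerance = 1e-12)
      expect_equal(dunn_posthoc(f(x), g)$z, dunn_posthoc(x, g)$z,
                   tolerance = 1e-12)
    }
  })
})

test_that("correlations cover linear, monotone and tied cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$r, 1, tolerance = 1e-12)

  y3 <- x^3
  expect_equal(correlate(x, y3, "spearman")$r, 1, tolerance = 1e-12)
  expect_lt(correlate(x, y3, "pearson")$r, 1)

  k <- correlate(c(1, 2, 3), c(2, 1, 3), "kendall")
  expect_equal(k$r, 1 / 3, tolerance = 1e-12)

  # incomplete pairs are dropped
  r <- correlate(c(x, NA), c(2 * x, 7), "pearson")
  expect_equal(r$n, 5L)
  expect_error(correlate(c(1, 1, 1), x[1:3]), "variance")
})

test_that("differential tables rank a planted feature first and flag degenerates", {
  sim <- simulate_community(n_samples = 40, n_taxa = 30, n_affected = 2,
                            effect = 2.5, seed = 91)
  vals <- sim$table$values
  vals[, 30] <- 5  # constant feature
  ft <- feature_table(vals, transform_tag = "raw")
  res <- differential_table(ft, sim$truth$group)
  expect_s3_class(res, "differential_result")
  expect_identical(res$features$flag[30], "degenerate")
  expect_true(is.na(res$features$padj[30]))
  top <- res$features$feature_id[which.min(res$features$padj)]
  expect_true(top %in% sim$truth$affected)
  # post hoc rows exist only for features passing the gate
  expect_true(all(res$pairwise$feature_id %in%
                    res$features$feature_id[!is.na(res$features$padj) &
                                              res$features$padj <= 0.05]))
  expect_true(all(c("mean_G1", "mean_G2") %in% names(res$features)))
})

test_that("repeated-measures design routes features through Friedman", {
  with_seed(33, {
    subj <- rep(sprintf("P%02d", 1:8), each = 3)
    time <- rep(c("t1", "t2", "t3"), 8)
    base <- rnorm(8)[rep(1:8, each = 3)]
    shift <- c(t1 = 0, t2 = 1.5, t3 = 3)[time]
    m <- cbind(f_signal = base + shift + rnorm(24, sd = 0.1),
               f_null = rnorm(24))
    rownames(m) <- sprintf("s%02d", 1:24)
    ft <- feature_table(m, transform_tag = "centered")
    res <- differential_table(ft, setNames(time, rownames(m)),
                              design = "repeated",
                              blocks = setNames(subj, rownames(m)))
    expect_lt(res$features$p[1], 0.01)
    expect_gt(res$features$p[2], 0.05)
    expect_error(differential_table(ft, setNames(time, rownames(m)),
                                    design = "repeated"), "blocks")
  })
})
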