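scaled_blocks <- function(sim) lapply(sim$blocks, function(t) block_scale(t)$table)

best_cor <- function(a, b) abs(cor(a, b))

test_that("DISCO-SCA with no distinctive ranks reduces to plain SCA", {
  sim <- simulate_paired_blocks(30, 12, 9, joint_rank = 1,
                                distinct_ranks = c(0, 0), noise_sd = 0.05,
                                seed = 71)
  b <- scaled_blocks(sim)
  m <- disco_sca(b, n_common = 1, n_distinct = c(0, 0), seed = 1)
  x <- cbind(b$block1$values, b$block2$values)
  sv <- svd(x)
  expect_lt(min(
    max(abs(m$common_scores[, 1] - sv$u[, 1])),
    max(abs(m$common_scores[, 1] + sv$u[, 1]))
  ), 1e-8)
})

test_that("DISCO-SCA recovers planted joint and distinctive structure exactly without noise", {
  sim <- simulate_paired_blocks(40, 30, 25, joint_rank = 1,
                                distinct_ranks = c(1, 1), noise_sd = 0,
                                seed = 5)
  b <- scaled_blocks(sim)
  m <- disco_sca(b, n_common = 1, n_distinct = c(1, 1), seed = 1)

  expect_gte(best_cor(m$joint_loadings$block1[, 1], sim$truth$p1[, 1]), 0.999)
  expect_gte(best_cor(m$joint_loadings$block2[, 1], sim$truth$p2[, 1]), 0.999)
  expect_gte(best_cor(m$common_scores[, 1], sim$truth$t[, 1]), 0.999)

  # distinctive components carry no energy in the other block
  for (bl in names(m$cross_energy)) {
    total <- sum(m$distinct_loadings[[bl]]^2) + m$cross_energy[[bl]]
    expect_lte(m$cross_energy[[bl]] / total, 1e-6)
  }

  # rotation stays inside the SCA subspace: same fit as unrotated SCA
  x <- cbind(b$block1$values, b$block2$values)
  sca_resid <- fnorm2(x - mgtools:::svd_trunc(x, 3))
  rot_resid <- fnorm2(x - m$scores %*% t(m$loadings))
  expect_equal(rot_resid, sca_resid, tolerance = 1e-10)
})

test_that("JIVE reduces to SCA at zero individual ranks and finds planted spaces", {
  sim <- simulate_paired_blocks(30, 20, 15, joint_rank = 2,
                                distinct_ranks = c(0, 0), noise_sd = 0.05,
                                seed = 3)
  b <- scaled_blocks(sim)
  j0 <- jive(b, joint_rank = 2, individual_ranks = c(0, 0))
  x <- cbind(b$block1$values, b$block2$values)
  expect_lt(max(abs(cbind(j0$joint$block1, j0$joint$block2) -
                      mgtools:::svd_trunc(x, 2))), 1e-7)

  sim2 <- simulate_paired_blocks(40, 25, 20, joint_rank = 1,
                                 distinct_ranks = c(1, 0), noise_sd = 0,
                                 seed = 9)
  b2 <- scaled_blocks(sim2)
  j <- jive(b2, joint_rank = 1, individual_ranks = c(1, 0))
  # principal angle between estimated and true joint sample space
  ct <- abs(crossprod(j$common_scores[, 1] / sqrt(sum(j$common_scores[, 1]^2)),
                      sim2$truth$t[, 1]))
  expect_lte(acos(min(ct, 1)), 1e-3)
  # joint and individual sample spaces orthogonal
  expect_lt(max(abs(crossprod(j$common_scores, j$distinct_scores$block1))), 1e-6)

  z <- matrix(0, 6, 4, dimnames = list(paste0("s", 1:6), paste0("f", 1:4)))
  jz <- jive(list(a = z, b = z), 1, c(1, 1))
  expect_true(jz$convergence$converged)
  expect_equal(jz$convergence$iterations, 1L)
  expect_true(all(jz$variance[, 2:4] == 0))

  j_stub <- jive(b2, 1, c(1, 0), max_iter = 1, tol = 0)
  expect_false(j_stub$convergence$converged)
})

test_that("O2PLS matches PCA when Y = X and its orthogonal filter cleans loadings", {
  x <- with_seed(3, scale(matrix(rnorm(200), 20, 10), scale = FALSE))
  dimnames(x) <- list(paste0("s", 1:20), paste0("f", 1:10))
  oo <- o2pls(x, x, n_joint = 2)
  pcs <- prcomp(x)$rotation[, 1:2]
  for (j in 1:2) {
    expect_lt(abs(abs(sum(oo$weights$x[, j] * pcs[, j])) - 1), 1e-8)
  }
  expect_error(o2pls(x, x, n_joint = 11), "rank")

  # planted rank-1 cross-covariance plus a strong X-specific component that
  # overlaps the joint loading direction: filtering must help
  with_seed(41, {
    n <- 60; p <- 20; q <- 15
    tt <- scale(rnorm(n), scale = FALSE)[, 1]
    t_orth <- residuals(lm(rnorm(n) ~ tt))
    p_x <- rnorm(p); p_x <- p_x / sqrt(sum(p_x^2))
    p_o <- p_x + 0.7 * rnorm(p); p_o <- p_o / sqrt(sum(p_o^2))
    p_y <- rnorm(q); p_y <- p_y / sqrt(sum(p_y^2))
    X <- tt %*% t(p_x) + 2.5 * t_orth %*% t(p_o) +
      matrix(rnorm(n * p, sd = 0.05), n, p)
    Y <- tt %*% t(p_y) + matrix(rnorm(n * q, sd = 0.05), n, q)
    dimnames(X) <- list(paste0("s", 1:n), paste0("a", 1:p))
    dimnames(Y) <- list(paste0("s", 1:n), paste0("b", 1:q))
    X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)

    with_filter <- o2pls(X, Y, n_joint = 1, n_orth_x = 1)
    without <- o2pls(X, Y, n_joint = 1, n_orth_x = 0)
    cor_with <- best_cor(with_filter$joint_loadings$x[, 1], p_x)
    cor_without <- best_cor(without$joint_loadings$x[, 1], p_x)
    expect_gte(cor_with, 0.99)
    expect_lt(cor_without, cor_with)
  })
})

test_that("variance decompositions are exact and orders permute consistently", {
  sim <- simulate_paired_blocks(30, 15, 12, joint_rank = 1,
                                distinct_ranks = c(1, 1), noise_sd = 0.1,
                                seed = 13)
  b <- scaled_blocks(sim)
  models <- list(
    disco = disco_sca(b, 1, c(1, 1), seed = 2),
    jive = jive(b, 1, c(1, 1)),
    o2pls = o2pls(b$block1, b$block2, 1, 1, 1)
  )
  for (m in models) {
    sums <- rowSums(m$variance[, c("joint", "distinctive", "residual")])
    expect_lt(max(abs(sums - 1)), 1e-6)
    expect_true(all(as.matrix(m$variance[, 2:4]) >= -1e-12))
  }
  # common scores orthonormal
  for (m in models) {
    cp <- crossprod(m$common_scores)
    expect_lt(max(abs(cp - diag(nrow(cp)))), 1e-6)
  }

  # permuting samples in both blocks permutes scores, loadings unchanged
  perm <- with_seed(99, sample.int(30))
  bp <- lapply(b, function(t) {
    feature_table(t$values[perm, , drop = FALSE], transform_tag = "centered")
  })
  m1 <- disco_sca(b, 1, c(1, 1), seed = 2)
  m2 <- disco_sca(bp, 1, c(1, 1), seed = 2)
  expect_lt(max(abs(m2$common_scores[, 1] - m1$common_scores[perm, 1])), 1e-8)
  expect_lt(max(abs(m2$joint_loadings$block1 - m1$joint_loadings$block1)), 1e-8)
})

test_that("ranked loadings sort by absolute value with stable ties", {
  lo <- matrix(c(0.1, -0.5, 0.3), 3, 1,
               dimnames = list(c("fa", "fb", "fc"), "C1"))
  model <- structure(list(method = "stub",
                          common_scores = matrix(0, 2, 1),
                          joint_loadings = list(blk = lo)),
                     class = "joint_model")
  r <- ranked_loadings(model, "blk", 1, top_k = 30)
  expect_identical(r$feature_id, c("fb", "fc", "fa"))
  expect_equal(r$loading, c(-0.5, 0.3, 0.1))
  expect_equal(nrow(ranked_loadings(model, "blk", 1, top_k = 2)), 2L)

  zero <- model
  zero$joint_loadings$blk[, 1] <- 0
  rz <- ranked_loadings(zero, "blk", 1)
  expect_identical(rz$feature_id, c("fa", "fb", "fc"))
  expect_error(ranked_loadings(model, "nope", 1), "unknown block")
  expect_error(ranked_loadings(model, "blk", 5), "component")
})
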