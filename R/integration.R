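# Two-block joint decomposition of paired omics matrices. Blocks are
# expected column-centered and Frobenius-scaled (see block_scale) so each
# contributes equal total sum of squares. All methods return a joint_model
# with common scores, per-block loadings and an exact per-block variance
# decomposition (joint + distinctive + residual = 1 of the block's sum of
# squares, up to float).

as_block_matrix <- function(b) {
  m <- if (inherits(b, "feature_table")) b$values else as.matrix(b)
  if (is.null(rownames(m))) stopf("block needs sample (row) names")
  m
}

check_paired <- function(blocks) {
  mats <- lapply(blocks, as_block_matrix)
  ids <- rownames(mats[[1L]])
  for (m in mats[-1L]) {
    if (!identical(rownames(m), ids)) {
      stopf("blocks must share the same samples in the same order")
    }
  }
  mats
}

joint_model <- function(method, common_scores, joint_loadings,
                        distinct_scores, distinct_loadings, variance,
                        convergence = NULL, extra = list()) {
  structure(
    c(list(method = method, common_scores = common_scores,
           joint_loadings = joint_loadings,
           distinct_scores = distinct_scores,
           distinct_loadings = distinct_loadings,
           variance = variance, convergence = convergence), extra),
    class = "joint_model"
  )
}

#' @export
print.joint_model <- function(x, ...) {
  cat(sprintf("<joint_model> %s: %d common component(s)\n",
              x$method, ncol(x$common_scores)))
  v <- x$variance
  v[-1] <- round(v[-1], 4)
  print(v)
  invisible(x)
}

# variance fractions of a list of additive, mutually orthogonal parts
variance_rows <- function(block_names, joint, distinct, resid, totals) {
  out <- do.call(rbind, lapply(seq_along(block_names), function(b) {
    data.frame(block = block_names[b],
               joint = joint[b] / totals[b],
               distinctive = distinct[b] / totals[b],
               residual = resid[b] / totals[b])
  }))
  rownames(out) <- NULL
  out
}

#' DISCO-SCA: simultaneous component analysis with distinctive/common
#' rotation
#'
#' Fits a rank-R simultaneous component model (R = n_common + both
#' distinctive ranks) to the column-wise concatenation of two paired
#' blocks by truncated SVD, then rotates the solution by an orthogonal
#' matrix chosen to minimize the squared loadings on positions constrained
#' to zero: a distinctive component of one block must have (near-)zero
#' loadings on the other block, common components are unconstrained. The
#' rotation is found by iterative majorization (orthogonal Procrustes
#' steps) from the identity plus seeded random starts, keeping the best.
#' Rotation happens inside the fitted subspace, so the SCA fit is
#' unchanged.
#'
#' @param blocks List of two paired blocks (`feature_table` or matrix),
#'   column-centered and block-scaled.
#' @param n_common Number of common components.
#' @param n_distinct Integer pair: distinctive rank of block 1 and 2.
#' @param tol Convergence tolerance on the rotation criterion (default 1e-8).
#' @param max_iter Maximum majorization iterations per start (default 1000).
#' @param n_starts Random rotation starts in addition to the identity
#'   (default 10).
#' @param seed Seed for the random starts.
#' @return A `joint_model`; `extra` fields: `component_roles`, per-block
#'   `cross_energy` of distinctive components, `sca_singular_values` (scree
#'   for rank choice).
#' @export
disco_sca <- function(blocks, n_common, n_distinct = c(0L, 0L), tol = 1e-8,
                      max_iter = 1000, n_starts = 10, seed = 1) {
  if (length(blocks) != 2L) stopf("DISCO-SCA is implemented for exactly 2 blocks")
  mats <- check_paired(blocks)
  block_names <- names(blocks) %||% paste0("block", 1:2)
  p <- vapply(mats, ncol, integer(1))
  n <- nrow(mats[[1L]])
  r_total <- n_common + sum(n_distinct)
  if (n_common < 1L) stopf("need at least one common component")
  if (r_total > min(n - 1L, sum(p))) stopf("total rank %d too large", r_total)
  x <- do.call(cbind, mats)
  sv <- svd(x)
  if (sv$d[r_total] < max(sv$d) * 1e-12) stopf("total rank %d too large for the data", r_total)
  scores <- sv$u[, seq_len(r_total), drop = FALSE]
  loadings <- sv$v[, seq_len(r_total), drop = FALSE] %*%
    diag(sv$d[seq_len(r_total)], r_total, r_total)

  # component order: common first, then distinctive of block 1, block 2
  roles <- c(rep("common", n_common),
             rep(block_names[1L], n_distinct[1L]),
             rep(block_names[2L], n_distinct[2L]))
  block_of_row <- rep(block_names, p)
  # mask[j, c] = 1 where loading row j is constrained to zero for component c
  mask <- matrix(0, sum(p), r_total)
  for (cc in seq_len(r_total)) {
    if (roles[cc] != "common") mask[block_of_row != roles[cc], cc] <- 1
  }

  rotate_from <- function(v0) {
    v <- v0
    crit_old <- fnorm2(mask * (loadings %*% v))
    crit <- crit_old
    for (it in seq_len(max_iter)) {
      pv <- loadings %*% v
      z <- (1 - mask) * pv
      s <- svd(crossprod(loadings, z))
      v <- s$u %*% t(s$v)
      crit <- fnorm2(mask * (loadings %*% v))
      # relative decrease criterion so near-zero optima are polished
      if (crit_old - crit < tol * max(crit, 1e-12)) break
      crit_old <- crit
    }
    list(v = v, crit = crit, iter = it)
  }

  starts <- c(list(diag(r_total)), with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      qr.Q(qr(matrix(stats::rnorm(r_total^2), r_total)))
    })
  }))
  fits <- lapply(starts, rotate_from)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "crit"))]]

  t_rot <- scores %*% best$v
  p_rot <- loadings %*% best$v
  # sign convention per component: largest-|loading| entry positive
  sg <- axis_signs(p_rot)
  t_rot <- sweep(t_rot, 2L, sg, "*")
  p_rot <- sweep(p_rot, 2L, sg, "*")
  rownames(t_rot) <- rownames(x)
  colnames(t_rot) <- colnames(p_rot) <- paste0("C", seq_len(r_total))
  rownames(p_rot) <- colnames(x)

  row_split <- split(seq_len(sum(p)), rep(seq_along(mats), p))
  is_common <- roles == "common"
  totals <- vapply(mats, fnorm2, numeric(1))
  joint_e <- distinct_e <- resid_e <- cross_e <- numeric(2)
  joint_loadings <- distinct_loadings <- vector("list", 2L)
  distinct_scores <- vector("list", 2L)
  for (b in 1:2) {
    pb <- p_rot[row_split[[b]], , drop = FALSE]
    own <- roles == block_names[b]
    other <- !is_common & !own
    # scores are orthonormal, so component energies in a block add up
    joint_e[b] <- fnorm2(pb[, is_common, drop = FALSE])
    distinct_e[b] <- fnorm2(pb[, own | other, drop = FALSE])
    cross_e[b] <- fnorm2(pb[, other, drop = FALSE])
    resid_e[b] <- fnorm2(mats[[b]] - t_rot %*% t(pb))
    joint_loadings[[b]] <- pb[, is_common, drop = FALSE]
    distinct_loadings[[b]] <- pb[, own, drop = FALSE]
    distinct_scores[[b]] <- t_rot[, own, drop = FALSE]
  }
  names(joint_loadings) <- names(distinct_loadings) <-
    names(distinct_scores) <- block_names

  joint_model(
    method = "disco_sca",
    common_scores = t_rot[, is_common, drop = FALSE],
    joint_loadings = joint_loadings,
    distinct_scores = distinct_scores,
    distinct_loadings = distinct_loadings,
    variance = variance_rows(block_names, joint_e, distinct_e, resid_e, totals),
    convergence = list(iterations = best$iter, criterion = best$crit,
                       n_starts = length(starts)),
    extra = list(component_roles = roles,
                 scores = t_rot, loadings = p_rot,
                 cross_energy = stats::setNames(cross_e, block_names),
                 sca_singular_values = sv$d, seed = seed)
  )
}

#' JIVE: joint and individual variation explained
#'
#' Alternating estimation: the joint structure J is the best rank-r
#' approximation of the concatenated blocks minus their individual
#' structure; each block's individual structure is the best rank-r_b
#' approximation of the block minus its joint slice, projected onto the
#' orthogonal complement of J's sample-space basis. Iterates until the
#' summed Frobenius change of all structures falls below `tol`, giving
#' joint and individual matrices with orthogonal sample spaces.
#'
#' @param blocks List of >= 2 paired blocks.
#' @param joint_rank Rank of the joint structure.
#' @param individual_ranks Integer vector of per-block individual ranks.
#' @param tol Convergence tolerance (default 1e-7).
#' @param max_iter Maximum iterations (default 500).
#' @return A `joint_model`; `extra` has the fitted `joint` and
#'   `individual` matrices per block; `convergence$converged` is `FALSE`
#'   when `max_iter` was hit.
#' @export
jive <- function(blocks, joint_rank, individual_ranks, tol = 1e-7,
                 max_iter = 500) {
  if (length(blocks) < 2L) stopf("JIVE needs at least 2 blocks")
  mats <- check_paired(blocks)
  block_names <- names(blocks) %||% paste0("block", seq_along(mats))
  if (length(individual_ranks) != length(mats)) {
    stopf("need one individual rank per block")
  }
  p <- vapply(mats, ncol, integer(1))
  n <- nrow(mats[[1L]])
  if (joint_rank + max(individual_ranks) > min(n, min(p))) {
    stopf("ranks are infeasible for the block dimensions")
  }
  col_split <- split(seq_len(sum(p)), rep(seq_along(mats), p))
  x <- do.call(cbind, mats)
  a <- lapply(mats, function(m) matrix(0, n, ncol(m)))
  j <- matrix(0, n, sum(p))
  if (fnorm2(x) == 0) {
    # all-zero input: everything is zero, converged immediately
    conv <- list(iterations = 1L, converged = TRUE, delta = 0)
  } else {
    conv <- NULL
    for (it in seq_len(max_iter)) {
      j_old <- j
      a_old <- a
      resid_a <- x - do.call(cbind, a)
      j <- svd_trunc(resid_a, joint_rank)
      u_j <- if (joint_rank > 0) svd(j, nu = joint_rank, nv = 0)$u else
        matrix(0, n, 0)
      for (b in seq_along(mats)) {
        r_b <- mats[[b]] - j[, col_split[[b]], drop = FALSE]
        if (ncol(u_j) > 0) r_b <- r_b - u_j %*% crossprod(u_j, r_b)
        a[[b]] <- svd_trunc(r_b, individual_ranks[b])
      }
      delta <- sqrt(fnorm2(j - j_old)) +
        sum(vapply(seq_along(a), function(b) sqrt(fnorm2(a[[b]] - a_old[[b]])),
                   numeric(1)))
      if (delta < tol) {
        conv <- list(iterations = it, converged = TRUE, delta = delta)
        break
      }
    }
    if (is.null(conv)) {
      conv <- list(iterations = max_iter, converged = FALSE, delta = delta)
    }
  }

  joint_blocks <- lapply(seq_along(mats), function(b) {
    out <- j[, col_split[[b]], drop = FALSE]
    dimnames(out) <- dimnames(mats[[b]])
    out
  })
  totals <- vapply(mats, fnorm2, numeric(1))
  joint_e <- vapply(joint_blocks, fnorm2, numeric(1))
  indiv_e <- vapply(a, fnorm2, numeric(1))
  resid_e <- vapply(seq_along(mats), function(b) {
    fnorm2(mats[[b]] - joint_blocks[[b]] - a[[b]])
  }, numeric(1))
  totals[totals == 0] <- 1  # zero blocks: report zero fractions

  sj <- svd(j)
  r_eff <- min(joint_rank, sum(sj$d > max(sj$d, 0) * 1e-12))
  common_scores <- sj$u[, seq_len(r_eff), drop = FALSE]
  joint_loadings <- lapply(seq_along(mats), function(b) {
    lo <- crossprod(joint_blocks[[b]], common_scores)
    if (r_eff > 0) colnames(lo) <- paste0("J", seq_len(r_eff))
    lo
  })
  # common sign convention driven by the concatenated loadings
  if (r_eff > 0) {
    all_lo <- do.call(rbind, joint_loadings)
    sg <- axis_signs(all_lo)
    common_scores <- sweep(common_scores, 2L, sg, "*")
    joint_loadings <- lapply(joint_loadings, function(lo) sweep(lo, 2L, sg, "*"))
  }
  rownames(common_scores) <- rownames(mats[[1L]])
  names(joint_loadings) <- block_names
  indiv_named <- stats::setNames(a, block_names)

  joint_model(
    method = "jive",
    common_scores = common_scores,
    joint_loadings = joint_loadings,
    distinct_scores = lapply(indiv_named, function(m) {
      s <- svd(m)
      k <- sum(s$d > max(s$d, 0) * 1e-12)
      s$u[, seq_len(k), drop = FALSE]
    }),
    distinct_loadings = indiv_named,
    variance = variance_rows(block_names, joint_e, indiv_e, resid_e, totals),
    convergence = conv,
    extra = list(joint = stats::setNames(joint_blocks, block_names),
                 individual = indiv_named)
  )
}

#' O2PLS: two-way orthogonal projections to latent structures
#'
#' Joint weights come from the leading singular triplets of the
#' cross-block covariance \eqn{Y^T X}. Structured noise unique to each
#' block (variation orthogonal to the joint scores) is estimated from the
#' residual of the joint model part and deflated, one component at a time;
#' the joint weights are then re-estimated on the filtered matrices.
#'
#' @param x,y Paired blocks (`feature_table` or matrix), column-centered.
#' @param n_joint Number of joint components.
#' @param n_orth_x,n_orth_y Numbers of block-specific orthogonal
#'   components (default 0).
#' @return A `joint_model`; `extra` has per-block joint weights/scores/
#'   loadings and orthogonal scores/loadings.
#' @export
o2pls <- function(x, y, n_joint, n_orth_x = 0, n_orth_y = 0) {
  mats <- check_paired(list(x, y))
  xm <- mats[[1L]]
  ym <- mats[[2L]]
  x0 <- xm
  y0 <- ym
  cov_xy <- crossprod(ym, xm)  # q x p
  rk <- sum(svd(cov_xy)$d > max(svd(cov_xy)$d) * 1e-12)
  if (n_joint < 1L) stopf("need at least one joint component")
  if (n_joint > rk) stopf("n_joint (%d) exceeds the rank of t(Y) %%*%% X (%d)",
                          n_joint, rk)

  joint_weights <- function(xm, ym) {
    s <- svd(crossprod(ym, xm), nu = n_joint, nv = n_joint)
    list(w = s$v[, seq_len(n_joint), drop = FALSE],
         c = s$u[, seq_len(n_joint), drop = FALSE])
  }
  wc <- joint_weights(xm, ym)

  # Trygg-style orthogonal filter: the residual X - T W^T (weights, not
  # regression loadings) exposes structured variation whose scores are
  # then made orthogonal to the joint scores and deflated
  deflate_orth <- function(m, w, n_orth) {
    t_o <- matrix(0, nrow(m), 0)
    p_o <- matrix(0, ncol(m), 0)
    for (i in seq_len(n_orth)) {
      scores <- m %*% w
      e <- m - scores %*% t(w)
      w_o <- svd(crossprod(e, scores), nu = 1L, nv = 0L)$u
      t_i <- m %*% w_o
      p_i <- crossprod(m, t_i) / drop(crossprod(t_i))
      m <- m - t_i %*% t(p_i)
      t_o <- cbind(t_o, t_i)
      p_o <- cbind(p_o, p_i)
    }
    list(m = m, scores = t_o, loadings = p_o)
  }

  # estimate joint weights, strip block-specific orthogonal variation,
  # then refresh the joint weights on the filtered matrices
  ox <- deflate_orth(xm, wc$w, n_orth_x)
  oy <- deflate_orth(ym, wc$c, n_orth_y)
  xm <- ox$m
  ym <- oy$m
  if (n_orth_x > 0 || n_orth_y > 0) wc <- joint_weights(xm, ym)

  tt <- xm %*% wc$w
  uu <- ym %*% wc$c
  p_x <- crossprod(xm, tt) %*% solve(crossprod(tt))
  p_y <- crossprod(ym, uu) %*% solve(crossprod(uu))
  # sign convention from the X-block loadings
  sg <- axis_signs(p_x)
  wc$w <- sweep(wc$w, 2L, sg, "*"); tt <- sweep(tt, 2L, sg, "*")
  wc$c <- sweep(wc$c, 2L, sg, "*"); uu <- sweep(uu, 2L, sg, "*")
  p_x <- sweep(p_x, 2L, sg, "*"); p_y <- sweep(p_y, 2L, sg, "*")

  block_names <- c("x", "y")
  totals <- c(fnorm2(x0), fnorm2(y0))
  joint_e <- c(fnorm2(tt %*% t(p_x)), fnorm2(uu %*% t(p_y)))
  orth_e <- c(fnorm2(ox$scores %*% t(ox$loadings)),
              fnorm2(oy$scores %*% t(oy$loadings)))
  resid_e <- c(fnorm2(x0 - tt %*% t(p_x) - ox$scores %*% t(ox$loadings)),
               fnorm2(y0 - uu %*% t(p_y) - oy$scores %*% t(oy$loadings)))

  qr_t <- qr(tt)
  common_scores <- qr.Q(qr_t)[, seq_len(n_joint), drop = FALSE]
  rownames(common_scores) <- rownames(x0)

  joint_model(
    method = "o2pls",
    common_scores = common_scores,
    joint_loadings = list(x = p_x, y = p_y),
    distinct_scores = list(x = ox$scores, y = oy$scores),
    distinct_loadings = list(x = ox$loadings, y = oy$loadings),
    variance = variance_rows(block_names, joint_e, orth_e, resid_e, totals),
    convergence = NULL,
    extra = list(weights = list(x = wc$w, y = wc$c),
                 joint_scores = list(x = tt, y = uu))
  )
}

#' Ranked loadings of one component
#'
#' Returns the `top_k` features of a block sorted by decreasing absolute
#' loading on the chosen component (ties broken by feature id), keeping
#' the signed loading.
#'
#' @param model A `joint_model`.
#' @param block Block label (name used when fitting).
#' @param component Component index (within the joint loadings).
#' @param top_k Number of rows (default 30, clamped to the feature count).
#' @return Data frame with `feature_id` and `loading`.
#' @export
ranked_loadings <- function(model, block, component = 1, top_k = 30) {
  stopifnot(inherits(model, "joint_model"))
  if (!block %in% names(model$joint_loadings)) {
    stopf("unknown block '%s'; available: %s", block,
          paste(names(model$joint_loadings), collapse = ", "))
  }
  lo <- model$joint_loadings[[block]]
  if (component < 1 || component > ncol(lo)) {
    stopf("component %d not available (block has %d)", component, ncol(lo))
  }
  v <- lo[, component]
  ids <- rownames(lo) %||% paste0("f", seq_along(v))
  ord <- order(-abs(v), ids, method = "radix")
  k <- min(top_k, length(v))
  data.frame(feature_id = ids[ord][seq_len(k)],
             loading = unname(v[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
}
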