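#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package operations never disturb the global
#' random-number stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# stable lexicographic order, independent of the user's locale
lex_sort <- function(x) {
  x[order(x, method = "radix")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# squared Frobenius norm
fnorm2 <- function(m) sum(m * m)

# best rank-r approximation by truncated SVD; r = 0 gives the zero matrix
svd_trunc <- function(m, r) {
  if (r <= 0) {
    return(matrix(0, nrow(m), ncol(m), dimnames = dimnames(m)))
  }
  s <- svd(m, nu = r, nv = r)
  u <- s$u[, seq_len(r), drop = FALSE]
  v <- s$v[, seq_len(r), drop = FALSE]
  out <- u %*% (diag(s$d[seq_len(r)], r, r) %*% t(v))
  dimnames(out) <- dimnames(m)
  out
}

# flip component signs so the largest-|loading| entry on each axis is
# positive; returns the vector of signs applied
axis_signs <- function(loadings) {
  apply(loadings, 2L, function(v) {
    i <- which.max(abs(v))
    if (length(i) == 0L || v[i] == 0) 1 else sign(v[i])
  })
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
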