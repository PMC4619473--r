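# internal helpers shared across the package

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# log(sum(exp(x))) without overflow; x may contain -Inf
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# symmetrize and check positive definiteness with a trace-relative tolerance
sym <- function(S) (S + t(S)) / 2

is_pd <- function(S, tol = 1e-10) {
  S <- sym(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > tol * max(sum(abs(diag(S))), .Machine$double.eps)
}

assert_pd <- function(S, name = "S") {
  if (!is_pd(S)) {
    stop(sprintf("`%s` must be symmetric positive definite", name), call. = FALSE)
  }
  invisible(S)
}

# Mahalanobis-type quadratic forms q_r = (x_r - m)' A^{-1} (x_r - m) for all
# rows of X at once, via the Cholesky factor of A.
quad_forms <- function(X, m, A) {
  R <- chol(sym(A))
  Z <- backsolve(R, t(X) - m, transpose = TRUE)
  colSums(Z^2)
}

# count classes / validate 0-based contiguous labels
check_labels <- function(y, M = NULL) {
  if (any(y != floor(y)) || any(y < 0)) {
    stop("labels must be nonnegative integers 0..M-1", call. = FALSE)
  }
  M <- M %||% (max(y) + 1L)
  as.integer(M)
}

# deterministic per-component seed stream derived from one master seed,
# kept below 2^31 for 32-bit R integers
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
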