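#' Dirichlet posterior for discrete (histogram) class-conditional models
#'
#' The feature space is the finite set of bins `1..b`; the class-`y`
#' conditional distribution is the bin-probability vector `p^y` with a
#' Dirichlet prior `alpha^y`. Observed bin counts `U^y` update the prior
#' conjugately to `alpha^y + U^y`. Hyperparameters may be improper as long
#' as every posterior entry is positive.
#'
#' @param alpha `b x M` matrix of prior hyperparameters (column = class).
#' @return An object of class `"discrete_posterior"` with fields `alpha`
#'   (`b x M`), `counts` (`b x M`), `b`, `M`, `n_y`.
#' @export
discrete_prior <- function(alpha) {
  alpha <- as.matrix(alpha)
  if (nrow(alpha) < 2L || ncol(alpha) < 2L) {
    stop("need b >= 2 bins and M >= 2 classes", call. = FALSE)
  }
  structure(
    list(alpha = alpha, counts = matrix(0L, nrow(alpha), ncol(alpha)),
         b = nrow(alpha), M = ncol(alpha), n_y = integer(ncol(alpha))),
    class = "discrete_posterior"
  )
}

#' Conjugate update of a discrete model with observed bin counts
#'
#' @param prior A [discrete_prior()] object (or an already-updated
#'   posterior; updates compose).
#' @param counts `b x M` matrix of nonnegative integer bin counts per class.
#' @return Updated `"discrete_posterior"`. Errors if any posterior
#'   hyperparameter is `<= 0` (improper posterior).
#' @export
update_discrete <- function(prior, counts) {
  stopifnot(inherits(prior, "discrete_posterior"))
  counts <- as.matrix(counts)
  if (!all(dim(counts) == dim(prior$alpha))) {
    stop("`counts` must be b x M", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("`counts` must be nonnegative integers", call. = FALSE)
  }
  astar <- prior$alpha + counts
  if (any(astar <= 0)) {
    stop("improper posterior: all updated alpha must be positive", call. = FALSE)
  }
  structure(
    list(alpha = astar, counts = prior$counts + counts,
         b = prior$b, M = prior$M, n_y = prior$n_y + colSums(counts)),
    class = "discrete_posterior"
  )
}

#' Tabulate labeled discrete observations into per-class bin counts
#'
#' @param x Bin indices in `1..b`.
#' @param y Labels `0..M-1`.
#' @param b,M Number of bins and classes.
#' @return `b x M` integer count matrix.
#' @export
discrete_counts <- function(x, y, b, M) {
  if (any(x < 1 | x > b | x != floor(x))) stop("bins must be integers in 1..b", call. = FALSE)
  counts <- matrix(0L, b, M)
  for (cls in 0:(M - 1L)) {
    counts[, cls + 1L] <- tabulate(x[y == cls], nbins = b)
  }
  counts
}
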