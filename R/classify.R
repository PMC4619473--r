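#' Binary linear classifier
#'
#' Predicts class 0 when `g(x) = a'x + b <= 0` and class 1 otherwise. The
#' closed-form risk and MSE expressions for Gaussian models apply to
#' classifiers of this form.
#'
#' @param a Weight vector (length `D`, not all zero).
#' @param b Scalar offset.
#' @return An object of class `"linear_classifier"`.
#' @export
linear_classifier <- function(a, b) {
  a <- as.numeric(a)
  if (all(a == 0)) stop("`a` must not be all-zero", call. = FALSE)
  stopifnot_finite_scalar(b)
  structure(list(a = a, b = b, M = 2L), class = "linear_classifier")
}

#' @export
predict.linear_classifier <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else matrix(newdata, ncol = length(object$a))
  as.integer(drop(X %*% object$a) + object$b > 0)
}

# shared prediction engine: N x M matrix of log "density * weight" scores ->
# label minimizing sum_y lambda(i, y) w_y f_y(x), ties to the lowest index.
# Works on log scores to survive underflow at D = 20: the per-point maximum
# is subtracted before exponentiating, a monotone rescaling of all i.
risk_argmin <- function(logF, w, loss) {
  lw <- log(w)
  scores <- sweep(logF, 2L, lw, `+`)
  mx <- apply(scores, 1L, max)
  bad <- !is.finite(mx)
  mx[bad] <- 0
  E <- exp(scores - mx)            # N x M, rowwise rescaled
  Dm <- E %*% t(unclass(loss))     # N x M, column i = sum_y lambda(i,y) w_y f_y
  pred <- max.col(-Dm, ties.method = "first") - 1L
  if (any(bad)) {
    # every weighted density underflowed: fall back to the dominant class on
    # the raw log scale and pick the prediction cheapest against it
    ymax <- max.col(logF[bad, , drop = FALSE], ties.method = "first")
    pred[bad] <- vapply(ymax, function(j) which.min(unclass(loss)[, j]) - 1L, integer(1L))
  }
  pred
}

# N x M matrix of class-conditional log densities under a parameter set
theta_log_densities <- function(theta, X) {
  if (theta$type == "gaussian") {
    X <- if (is.matrix(X)) X else matrix(X, ncol = nrow(theta$mu))
    M <- ncol(theta$mu)
    out <- matrix(0, nrow(X), M)
    for (j in seq_len(M)) {
      out[, j] <- log_density(eff_gaussian(theta$mu[, j], theta$Sigma[[j]]), X)
    }
    out
  } else if (theta$type == "discrete") {
    bins <- as.integer(X)
    matrix(log(theta$p[bins, , drop = FALSE]), length(bins), ncol(theta$p))
  } else stop("unknown parameter type", call. = FALSE)
}

#' Bayes decision rule with known parameters
#'
#' The pointwise-optimal classifier when the feature-label distribution is
#' known: predict `argmin_i sum_y lambda(i, y) c_y f(x | y, theta_y)`, ties
#' broken to the lowest index.
#'
#' @param c Class-probability vector.
#' @param theta Parameter set: `list(type = "gaussian", mu = D x M matrix,
#'   Sigma = list of M covariance matrices)` or `list(type = "discrete",
#'   p = b x M bin-probability matrix)`.
#' @param loss Loss matrix (default zero-one).
#' @return A `"bdr_classifier"` (also a `"risk_classifier"`); use
#'   `predict(obj, X)` for labels.
#' @export
bdr_classifier <- function(c, theta, loss = NULL) {
  M <- length(c)
  loss <- as_loss(loss, M)
  structure(list(c = as.numeric(c), theta = theta, loss = loss, M = M),
            class = c("bdr_classifier", "risk_classifier"))
}

#' @export
predict.bdr_classifier <- function(object, newdata, ...) {
  logF <- theta_log_densities(object$theta, newdata)
  risk_argmin(logF, object$c, object$loss)
}

#' Optimal Bayesian risk classifier
#'
#' Minimizes the Bayesian risk estimator over all classifiers; pointwise it
#' predicts `argmin_i sum_y lambda(i, y) E[C_y | S] f(x | y, S)` with the
#' effective densities in place of the unknown true densities. Has the same
#' functional form as the Bayes decision rule, but is not a plug-in rule:
#' under inverse-Wishart models the effective densities are Student-t, not
#' Gaussian.
#'
#' @param post Class-conditional posterior (`"gaussian_posterior"` or
#'   `"discrete_posterior"`).
#' @param class_post A `"class_prob_posterior"` for the label distribution.
#' @param loss Loss matrix (default zero-one).
#' @return An `"obrc_classifier"` (also a `"risk_classifier"`).
#' @export
obrc_classifier <- function(post, class_post, loss = NULL) {
  M <- post$M
  loss <- as_loss(loss, M)
  dens <- lapply(seq_len(M) - 1L, function(y) effective_density(post, y))
  structure(list(post = post, class_post = class_post, loss = loss,
                 densities = dens, w = class_prob_mean(class_post), M = M),
            class = c("obrc_classifier", "risk_classifier"))
}

# N x M log effective densities for an obrc classifier
obrc_log_densities <- function(object, X) {
  out <- sapply(object$densities, function(d) log_density(d, X))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  out
}

#' @export
predict.obrc_classifier <- function(object, newdata, ...) {
  risk_argmin(obrc_log_densities(object, newdata), object$w, object$loss)
}

#' Posterior probability of each class at a point
#'
#' `f(y | x, S)` proportional to `f(y | S) f(x | y, S)`, normalized over
#' classes. Errors if every effective density underflows to zero at `x`.
#'
#' @param x A single point (length `D`, or a bin index).
#' @param post Class-conditional posterior.
#' @param class_post Class-probability posterior.
#' @return Probability vector over the `M` classes.
#' @export
posterior_class_prob <- function(x, post, class_post) {
  w <- class_prob_mean(class_post)
  logf <- vapply(seq_len(post$M) - 1L, function(y) {
    as.numeric(log_density(effective_density(post, y),
                           if (inherits(post, "discrete_posterior")) x else matrix(x, 1L)))
  }, numeric(1L))
  s <- log(w) + logf
  if (all(!is.finite(s))) stop("all effective densities vanish at x", call. = FALSE)
  s[!is.finite(s)] <- -Inf
  p <- exp(s - logsumexp(s))
  p / sum(p)
}

#' Bayesian conditional risk estimator at a point
#'
#' The MMSE estimate of the conditional risk of predicting each class `i`
#' at point `x`: `Rhat(i, x, S) = sum_y lambda(i, y) f(y | x, S)`. Under
#' zero-one loss this is `1 - f(i | x, S)`. The OBRC label at `x` is the
#' argmin of this vector.
#'
#' @inheritParams posterior_class_prob
#' @param loss Loss matrix (default zero-one).
#' @return Length-`M` vector of estimated conditional risks.
#' @export
bcre <- function(x, post, class_post, loss = NULL) {
  loss <- as_loss(loss, post$M)
  drop(unclass(loss) %*% posterior_class_prob(x, post, class_post))
}

#' Plug-in discriminant classifiers
#'
#' Classical baselines that substitute sample estimates into the Bayes
#' decision rule under a Gaussian assumption. `plugin_qda()` uses per-class
#' sample means and covariances (each class needs `n_y >= 2` and a
#' non-singular estimate); `plugin_lda()` pools one covariance across
#' classes. Class probabilities default to the empirical frequencies
#' `n_y / n` but can be fixed (e.g. to known prevalences).
#'
#' @param X Training features (`n x D`).
#' @param y Labels `0..M-1`.
#' @param loss Loss matrix (default zero-one).
#' @param c Optional fixed class-probability vector.
#' @param M Number of classes (defaults to `max(y) + 1`).
#' @return A `"bdr_classifier"` built on the estimates. Errors on singular
#'   covariance estimates.
#' @export
plugin_qda <- function(X, y, loss = NULL, c = NULL, M = NULL) {
  est <- gaussian_estimates(X, y, pooled = FALSE, M = M)
  bdr_classifier(c %||% est$freq, est$theta, as_loss(loss, length(est$freq)))
}

#' @rdname plugin_qda
#' @export
plugin_lda <- function(X, y, loss = NULL, c = NULL, M = NULL) {
  est <- gaussian_estimates(X, y, pooled = TRUE, M = M)
  bdr_classifier(c %||% est$freq, est$theta, as_loss(loss, length(est$freq)))
}

gaussian_estimates <- function(X, y, pooled, M = NULL) {
  X <- as.matrix(X)
  M <- check_labels(y, M)
  D <- ncol(X)
  mu <- matrix(0, D, M)
  covs <- vector("list", M)
  n_y <- integer(M)
  for (cls in seq_len(M) - 1L) {
    Xy <- X[y == cls, , drop = FALSE]
    n_y[cls + 1L] <- nrow(Xy)
    if (nrow(Xy) < 1L || (!pooled && nrow(Xy) < 2L)) {
      stop("insufficient points to estimate class ", cls, call. = FALSE)
    }
    mu[, cls + 1L] <- colMeans(Xy)
    covs[[cls + 1L]] <- if (nrow(Xy) > 1L) stats::cov(Xy) else matrix(0, D, D)
  }
  if (pooled) {
    n <- sum(n_y)
    if (n < M + 1L) stop("pooled covariance needs n >= M + 1", call. = FALSE)
    pool <- Reduce(`+`, Map(function(S, ny) (ny - 1L) * S, covs, n_y)) / (n - M)
    if (!is_pd(pool)) stop("singular pooled covariance estimate", call. = FALSE)
    covs <- rep(list(pool), M)
  } else {
    ok <- vapply(covs, is_pd, logical(1L))
    if (!all(ok)) stop("singular per-class covariance estimate", call. = FALSE)
  }
  list(theta = list(type = "gaussian", mu = mu, Sigma = covs), freq = n_y / sum(n_y))
}
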