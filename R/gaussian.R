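#' Gaussian class-conditional models with conjugate priors
#'
#' Container for the hyperparameters of the Gaussian Bayesian models. Each
#' class-`y` conditional density is `N(mu_y, Sigma_y)`; the mean has a
#' normal prior `N(m_y, Sigma_y / nu_y)` given the covariance, and the
#' covariance follows one of three structures:
#' * `"known"` - `Sigma_y` fixed; only `(nu_y, m_y)` are updated;
#' * `"arbitrary"` - inverse-Wishart prior with hyperparameters
#'   `(kappa, S)`;
#' * `"scaled_identity"` - `Sigma_y = sigma^2 I_D` with an inverse-gamma
#'   prior on `sigma^2` parameterized through `(kappa, S)` so that the
#'   update equations coincide with the arbitrary model.
#'
#' Coupling is `"independent"` (per-class `kappa_y`, `S_y`, a priori
#' independent) or `"homoscedastic"` (one shared covariance parameter, one
#' `(kappa, S)` pair). Improper hyperparameters (e.g. `nu = 0`) are accepted
#' at construction; propriety is enforced whenever a posterior quantity
#' (effective density, sampler, risk estimate) is requested.
#'
#' @param D Feature-space dimension.
#' @param M Number of classes.
#' @param structure Covariance structure (see above).
#' @param coupling `"independent"` or `"homoscedastic"` (ignored for
#'   `"known"`, whose means are always a priori independent).
#' @param nu Length-`M` vector of mean-precision hyperparameters.
#' @param m `D x M` matrix of prior location vectors (or a vector recycled
#'   across classes).
#' @param kappa Covariance degrees-of-freedom hyperparameter: length `M`
#'   (independent) or scalar (homoscedastic).
#' @param S Covariance scale: a list of `M` symmetric `D x D` matrices
#'   (independent), a single matrix (homoscedastic), or a scalar taken as
#'   `scalar * I_D`.
#' @param Sigma Known covariances (structure `"known"`): list of `M`
#'   matrices or a single matrix shared by all classes.
#' @return An object of class `"gaussian_posterior"` with `n_y = 0`.
#' @export
gaussian_prior <- function(D, M, structure = c("arbitrary", "scaled_identity", "known"),
                           coupling = c("independent", "homoscedastic"),
                           nu, m, kappa = NULL, S = NULL, Sigma = NULL) {
  structure <- match.arg(structure)
  coupling <- match.arg(coupling)
  if (structure == "known") coupling <- "independent"
  D <- as.integer(D); M <- as.integer(M)
  nu <- rep_len(as.numeric(nu), M)
  m <- if (is.matrix(m)) m else matrix(rep_len(as.numeric(m), D * M), D, M)
  if (!all(dim(m) == c(D, M))) stop("`m` must be D x M", call. = FALSE)

  as_scale <- function(s) {
    if (is.matrix(s)) {
      if (!all(dim(s) == c(D, D))) stop("scale matrices must be D x D", call. = FALSE)
      sym(s)
    } else if (length(s) == 1L) diag(as.numeric(s), D) else stop("bad scale", call. = FALSE)
  }

  obj <- list(D = D, M = M, structure = structure, coupling = coupling,
              nu = nu, m = m, n_y = integer(M))
  if (structure == "known") {
    if (is.null(Sigma)) stop("known structure requires `Sigma`", call. = FALSE)
    if (!is.list(Sigma)) Sigma <- rep(list(Sigma), M)
    obj$Sigma <- lapply(Sigma, function(s) assert_pd(as_scale(s), "Sigma"))
  } else {
    if (is.null(kappa) || is.null(S)) {
      stop("arbitrary/scaled_identity structures require `kappa` and `S`", call. = FALSE)
    }
    if (coupling == "independent") {
      obj$kappa <- rep_len(as.numeric(kappa), M)
      if (!is.list(S)) S <- rep(list(S), M)
      obj$S <- lapply(S, as_scale)
    } else {
      if (length(kappa) != 1L) stop("homoscedastic coupling has one `kappa`", call. = FALSE)
      obj$kappa <- as.numeric(kappa)
      obj$S <- as_scale(if (is.list(S)) S[[1L]] else S)
    }
  }
  base::structure(obj, class = "gaussian_posterior")  # `structure` arg shadows base
}

# effective Student-t degrees of freedom for each class (vector length M);
# NULL for known covariance (Gaussian effective densities)
eff_dof <- function(post) {
  D <- post$D
  switch(post$structure,
    known = NULL,
    arbitrary = if (post$coupling == "homoscedastic") {
      rep(post$kappa - D + 1, post$M)
    } else post$kappa - D + 1,
    scaled_identity = if (post$coupling == "homoscedastic") {
      rep((post$kappa + D + 1) * D - 2, post$M)
    } else (post$kappa + D + 1) * D - 2
  )
}

# propriety of the *posterior* hyperparameters; errors rather than NaN
check_proper <- function(post) {
  if (any(post$nu <= 0)) stop("improper posterior: nu* must be > 0", call. = FALSE)
  if (post$structure == "arbitrary") {
    ks <- if (post$coupling == "homoscedastic") list(list(post$kappa, post$S)) else
      Map(list, post$kappa, post$S)
    for (e in ks) {
      if (e[[1]] <= post$D - 1) stop("improper posterior: kappa* must be > D - 1", call. = FALSE)
      assert_pd(e[[2]], "S*")
    }
  } else if (post$structure == "scaled_identity") {
    kap <- post$kappa
    if (any((kap + post$D + 1) * post$D <= 2)) {
      stop("improper posterior: (kappa* + D + 1) D must be > 2", call. = FALSE)
    }
    Ss <- if (post$coupling == "homoscedastic") list(post$S) else post$S
    lapply(Ss, assert_pd, name = "S*")
  }
  invisible(post)
}

#' Conjugate update of a Gaussian model with labeled data
#'
#' Updates all hyperparameters with the per-class sample mean and sample
#' covariance: `nu*_y = nu_y + n_y`, `m*_y = m_y + n_y (xbar_y - m_y) /
#' (nu_y + n_y)`; for covariance models `kappa* = kappa + n` (homoscedastic,
#' summing contributions over classes) or `kappa*_y = kappa_y + n_y`
#' (independent), and `S*` gains `(n_y - 1) Sighat_y + nu_y n_y / (nu_y +
#' n_y) (xbar_y - m_y)(xbar_y - m_y)'` (with `Sighat_y = 0` when
#' `n_y <= 1`). Known covariances are left untouched. Updates compose: a
#' posterior may itself be updated with further data.
#'
#' @param prior A [gaussian_prior()] object (or posterior).
#' @param X Numeric `n x D` matrix of feature vectors.
#' @param y Integer labels `0..M-1`, length `n`.
#' @return Updated `"gaussian_posterior"` (propriety checked).
#' @export
update_gaussian <- function(prior, X, y) {
  stopifnot(inherits(prior, "gaussian_posterior"))
  X <- as.matrix(X)
  if (ncol(X) != prior$D) stop("data dimension does not match D", call. = FALSE)
  if (nrow(X) != length(y)) stop("X rows and labels differ in length", call. = FALSE)
  check_labels(y, prior$M)

  post <- prior
  for (cls in seq_len(prior$M) - 1L) {
    Xy <- X[y == cls, , drop = FALSE]
    ny <- nrow(Xy)
    if (ny == 0L) next
    j <- cls + 1L
    nu0 <- prior$nu[j]
    xbar <- colMeans(Xy)
    dm <- xbar - prior$m[, j]
    post$nu[j] <- nu0 + ny
    post$m[, j] <- prior$m[, j] + ny * dm / (nu0 + ny)
    post$n_y[j] <- prior$n_y[j] + ny
    if (prior$structure != "known") {
      Sighat <- if (ny > 1L) stats::cov(Xy) else matrix(0, prior$D, prior$D)
      contrib <- (ny - 1) * Sighat + (nu0 * ny / (nu0 + ny)) * tcrossprod(dm)
      if (prior$coupling == "independent") {
        post$kappa[j] <- prior$kappa[j] + ny
        post$S[[j]] <- sym(post$S[[j]] + contrib)
      } else {
        post$kappa <- post$kappa + ny
        post$S <- sym(post$S + contrib)
      }
    }
  }
  check_proper(post)
  post
}

#' Method-of-moments prior calibration from a held-out feature table
#'
#' Builds an independent arbitrary-covariance prior for a `D`-dimensional
#' classification problem from calibration features that will not be used
#' for classification. Per class `y`, with per-feature means and variances
#' across the class-`y` calibration columns: `m_y` is the mean of the
#' means, `s_y` the mean of the variances, `t_y` the variance of the means
#' after discarding the 10 % of means largest in absolute value, and `u_y`
#' the variance of the variances after discarding the 10 % largest
#' variances. Then `nu_y = s_y / t_y`, `kappa_y = 2 s_y^2 / u_y + D + 3`,
#' `m_y = (m_y, ..., m_y)`, and `S_y = (kappa_y - D - 1) s_y I_D`.
#'
#' @param X Calibration feature matrix (`n x F`, `F >= 2`).
#' @param y Labels `0..M-1`.
#' @param D Dimension of the target classification problem.
#' @return A `"gaussian_posterior"` prior (independent arbitrary).
#' @export
calibrate_prior_moments <- function(X, y, D) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 calibration features", call. = FALSE)
  M <- check_labels(y)
  # drop the ceiling(10%) entries largest by `by`, keep the rest of `v`
  trim_top <- function(v, by) {
    k <- ceiling(0.1 * length(v))
    v[order(by, decreasing = TRUE)[-seq_len(k)]]
  }
  nu <- kap <- numeric(M); mloc <- numeric(M); Slist <- vector("list", M)
  for (cls in seq_len(M) - 1L) {
    Xy <- X[y == cls, , drop = FALSE]
    if (nrow(Xy) < 2L) stop("need >= 2 calibration points per class", call. = FALSE)
    mu_f <- colMeans(Xy)
    var_f <- apply(Xy, 2, stats::var)
    m_y <- mean(mu_f)
    s_y <- mean(var_f)
    t_y <- stats::var(trim_top(mu_f, abs(mu_f)))
    u_y <- stats::var(trim_top(var_f, var_f))
    if (!isTRUE(t_y > 0) || !isTRUE(u_y > 0)) {
      stop("degenerate calibration features: zero trimmed variance", call. = FALSE)
    }
    j <- cls + 1L
    nu[j] <- s_y / t_y
    kap[j] <- 2 * s_y^2 / u_y + D + 3
    mloc[j] <- m_y
    Slist[[j]] <- diag((kap[j] - D - 1) * s_y, D)
  }
  gaussian_prior(D, M, "arbitrary", "independent", nu = nu,
                 m = matrix(rep(mloc, each = D), D, M), kappa = kap, S = Slist)
}
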