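#' Effective densities
#'
#' The effective class-`y` conditional density `f(x | y, S)` is the
#' posterior predictive density `E[f(x | y, Theta_y) | S]`: it plays the
#' role of the (unknown) true class-conditional density in the Bayesian risk
#' estimator and the optimal Bayesian risk classifier. Depending on the
#' model it is categorical (discrete model), Gaussian (known covariance), or
#' multivariate Student-t (inverse-Wishart covariance models).
#'
#' Constructors are exported mainly for testing; users normally obtain
#' densities from [effective_density()], [effective_conditional()] and
#' [effective_joint()].
#'
#' @name effective-densities
NULL

eff_categorical <- function(prob) {
  stopifnot(all(prob >= 0), abs(sum(prob) - 1) < 1e-8)
  structure(list(prob = as.numeric(prob)), class = c("eff_categorical", "effective_density"))
}

eff_gaussian <- function(mean, cov) {
  assert_pd(cov, "cov")
  structure(list(mean = as.numeric(mean), cov = sym(cov)),
            class = c("eff_gaussian", "effective_density"))
}

eff_student_t <- function(df, loc, scale) {
  stopifnot(df > 0)
  assert_pd(scale, "scale")
  structure(list(df = df, loc = as.numeric(loc), scale = sym(scale)),
            class = c("eff_student_t", "effective_density"))
}

eff_categorical_joint <- function(P) {
  stopifnot(abs(sum(P) - 1) < 1e-8, all(P >= 0))
  structure(list(P = as.matrix(P)), class = c("eff_categorical_joint", "effective_joint_density"))
}

# product of two independent effective densities (independent coupling, y != z)
eff_product <- function(d1, d2) {
  structure(list(parts = list(d1, d2)),
            class = c("eff_product", "effective_joint_density"))
}

eff_gaussian_joint <- function(mean, cov) {
  structure(list(mean = as.numeric(mean), cov = sym(cov)),
            class = c("eff_gaussian_joint", "eff_gaussian", "effective_joint_density"))
}

eff_student_t_joint <- function(df, loc, scale) {
  structure(list(df = df, loc = as.numeric(loc), scale = sym(scale)),
            class = c("eff_student_t_joint", "eff_student_t", "effective_joint_density"))
}

# covariance "unit" entering the effective t scale: S* (arbitrary) or
# trace(S*) I_D (scaled identity), resolved per class
scale_unit <- function(post, j) {
  S <- if (post$coupling == "homoscedastic") post$S else post$S[[j]]
  if (post$structure == "scaled_identity") diag(sum(diag(S)), post$D) else S
}

#' Effective class-conditional density
#'
#' @param post A `"gaussian_posterior"` or `"discrete_posterior"`.
#' @param y Class label in `0..M-1`.
#' @return An `"effective_density"` object: categorical with probabilities
#'   `alpha*_x / alpha*_+` (discrete); `N(m*_y, (nu*+1)/nu* Sigma_y)`
#'   (known covariance); or Student-t with `k = kappa* - D + 1` degrees of
#'   freedom (arbitrary) or `k = (kappa* + D + 1) D - 2` (scaled identity),
#'   location `m*_y` and scale `(nu*+1)/(k nu*)` times the covariance unit.
#' @export
effective_density <- function(post, y) {
  UseMethod("effective_density")
}

#' @export
effective_density.discrete_posterior <- function(post, y) {
  j <- y + 1L
  a <- post$alpha[, j]
  if (any(a <= 0)) stop("improper posterior", call. = FALSE)
  eff_categorical(a / sum(a))
}

#' @export
effective_density.gaussian_posterior <- function(post, y) {
  check_proper(post)
  j <- y + 1L
  nu <- post$nu[j]
  if (post$structure == "known") {
    return(eff_gaussian(post$m[, j], (nu + 1) / nu * post$Sigma[[j]]))
  }
  k <- eff_dof(post)[j]
  if (k <= 0) stop("improper posterior: effective dof must be > 0", call. = FALSE)
  eff_student_t(k, post$m[, j], (nu + 1) / (k * nu) * scale_unit(post, j))
}

# covariance-only single-point update (homoscedastic, conditioning class y):
# kappa* <- kappa* + 1, S* <- S* + nu*_y/(nu*_y+1) (x - m*_y)(x - m*_y)'
cov_only_update <- function(post, x, y) {
  j <- y + 1L
  nu <- post$nu[j]
  d <- x - post$m[, j]
  post$kappa <- post$kappa + 1
  post$S <- sym(post$S + (nu / (nu + 1)) * tcrossprod(d))
  post
}

#' Effective conditional density of a second point given an observed one
#'
#' Density of a class-`z` point `w` given that a class-`y` point `x` has
#' been observed, under the posterior: `f(w | x, y, z, S) = f(w | z, S
#' union {x, y})`. Computed by delegating to the generic posterior update
#' with the single point `{x, y}` - a full update of class-`y`
#' hyperparameters when `z == y`; a covariance-only update when `z != y`
#' under homoscedastic coupling; and no change at all when `z != y` under
#' independent coupling (or known covariance), where it equals the
#' unconditional effective density of `z`.
#'
#' @param post Posterior object.
#' @param x A single feature vector (length `D`), or a bin index for the
#'   discrete model.
#' @param y Class of the conditioning point.
#' @param z Class of the new point.
#' @return An `"effective_density"`.
#' @export
effective_conditional <- function(post, x, y, z) {
  UseMethod("effective_conditional")
}

#' @export
effective_conditional.discrete_posterior <- function(post, x, y, z) {
  if (z != y) return(effective_density(post, z))
  counts <- matrix(0L, post$b, post$M)
  counts[x, y + 1L] <- 1L
  effective_density(update_discrete(post, counts), z)
}

#' @export
effective_conditional.gaussian_posterior <- function(post, x, y, z) {
  x <- as.numeric(x)
  if (length(x) != post$D) stop("`x` must have length D", call. = FALSE)
  if (z == y) {
    upd <- update_gaussian(post, matrix(x, 1L), y)
    return(effective_density(upd, z))
  }
  if (post$coupling == "independent" || post$structure == "known") {
    return(effective_density(post, z))
  }
  effective_density(cov_only_update(post, x, y), z)
}

#' Effective joint density of a class-`y` and a class-`z` point
#'
#' Joint predictive density `f(x, w | y, z, S)` of two points drawn from the
#' same feature-label distribution, used for second moments of the
#' misclassification probabilities. For the discrete model with `y == z`,
#' `P(x, w) = alpha*_x (alpha*_w + delta_xw) / (alpha*_+ (alpha*_+ + 1))`.
#' For Gaussian/Student-t models with `y == z` the stacked vector `(x, w)`
#' is a single elliptical law (Gaussian or Student-t with the marginal
#' degrees of freedom) whose off-diagonal scale block is `1/nu*_y` times the
#' covariance unit. With `y != z`, the joint factorizes under independent
#' coupling; under homoscedastic coupling it is a single Student-t with a
#' zero off-diagonal block (the shared covariance still couples the two
#' points through the common mixing variable).
#'
#' @param post Posterior object.
#' @param y,z Class labels.
#' @return An `"effective_joint_density"`.
#' @export
effective_joint <- function(post, y, z) {
  UseMethod("effective_joint")
}

#' @export
effective_joint.discrete_posterior <- function(post, y, z) {
  if (y != z) {
    py <- effective_density(post, y)$prob
    pz <- effective_density(post, z)$prob
    return(eff_categorical_joint(outer(py, pz)))
  }
  a <- post$alpha[, y + 1L]
  ap <- sum(a)
  P <- outer(a, a) + diag(a)
  eff_categorical_joint(P / (ap * (ap + 1)))
}

#' @export
effective_joint.gaussian_posterior <- function(post, y, z) {
  check_proper(post)
  D <- post$D
  jy <- y + 1L; jz <- z + 1L
  nuy <- post$nu[jy]; nuz <- post$nu[jz]
  if (post$structure == "known") {
    if (y != z) {
      return(eff_product(effective_density(post, y), effective_density(post, z)))
    }
    Sig <- post$Sigma[[jy]]
    cov <- rbind(cbind((nuy + 1) / nuy * Sig, Sig / nuy),
                 cbind(Sig / nuy, (nuy + 1) / nuy * Sig))
    return(eff_gaussian_joint(c(post$m[, jy], post$m[, jy]), cov))
  }
  if (y != z && post$coupling == "independent") {
    return(eff_product(effective_density(post, y), effective_density(post, z)))
  }
  if (post$structure == "scaled_identity") {
    # elliptical joint: the stacked vector is a single multivariate t
    k <- eff_dof(post)[jy]
    A <- scale_unit(post, jy)
    if (y == z) {
      blk <- rbind(cbind((nuy + 1) / nuy * A, A / nuy),
                   cbind(A / nuy, (nuy + 1) / nuy * A))
      return(eff_student_t_joint(k, c(post$m[, jy], post$m[, jy]), blk / k))
    }
    zero <- matrix(0, D, D)
    blk <- rbind(cbind((nuy + 1) / nuy * A, zero),
                 cbind(zero, (nuz + 1) / nuz * A))
    return(eff_student_t_joint(k, c(post$m[, jy], post$m[, jz]), blk / k))
  }
  # arbitrary covariance: the stacked pair follows a matrix-variate t, which
  # is *not* multivariate t for D > 1; represent the joint exactly as
  # marginal times effective conditional (1-D projections still satisfy the
  # bivariate-t closed forms)
  eff_conditional_joint(post, y, z)
}

eff_conditional_joint <- function(post, y, z) {
  base::structure(list(post = post, y = y, z = z,
                       marginal = effective_density(post, y)),
                  class = c("eff_conditional_joint", "effective_joint_density"))
}

#' @export
log_density.eff_conditional_joint <- function(d, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  D <- d$post$D
  lx <- log_density(d$marginal, X[, seq_len(D), drop = FALSE])
  lw <- vapply(seq_len(nrow(X)), function(r) {
    cond <- effective_conditional(d$post, X[r, seq_len(D)], d$y, d$z)
    as.numeric(log_density(cond, X[r, D + seq_len(D), drop = FALSE]))
  }, numeric(1L))
  lx + lw
}

#' @export
sample_effective_.eff_conditional_joint <- function(d, n) {
  post <- d$post
  D <- post$D
  jy <- d$y + 1L; jz <- d$z + 1L
  nuy <- post$nu[jy]
  k <- eff_dof(post)[jy]
  A <- if (post$coupling == "homoscedastic") post$S else post$S[[jy]]
  X <- sample_effective_(d$marginal, n)
  U <- sweep(X, 2L, post$m[, jy])          # x - m*_y, rank-1 direction per draw
  c2 <- nuy / (nuy + 1)
  if (d$y == d$z) {
    loc <- sweep(U / (nuy + 1), 2L, post$m[, jy], `+`)
    cs <- (nuy + 2) / ((k + 1) * (nuy + 1))
  } else {
    nuz <- post$nu[jz]
    loc <- matrix(post$m[, jz], n, D, byrow = TRUE)
    cs <- (nuz + 1) / ((k + 1) * nuz)
  }
  # draw from t(k+1, loc, cs * (S + c2 u u')) per row: a normal draw with
  # covariance S + c2 u u' is Z1 %*% chol(S) + sqrt(c2) z2 u, then divide by
  # the per-row chi-square mixing factor
  R <- chol(sym(A))
  Z1 <- matrix(stats::rnorm(n * D), n, D)
  z2 <- stats::rnorm(n)
  mix <- sqrt(stats::rchisq(n, df = k + 1) / (k + 1))
  W <- loc + sqrt(cs) * (Z1 %*% R + sqrt(c2) * z2 * U) / mix
  cbind(X, W)
}

#' Log density evaluation
#'
#' Evaluates the log density of an effective (or effective-joint) density at
#' a matrix of points (one row per point; for categorical densities, a
#' vector of bin indices). Normalization constants are computed through
#' `lgamma`, and quadratic forms through Cholesky back-substitution.
#'
#' @param d An `"effective_density"` or `"effective_joint_density"`.
#' @param X Points to evaluate at.
#' @return Numeric vector of log densities.
#' @export
log_density <- function(d, X) {
  UseMethod("log_density")
}

#' @export
log_density.eff_categorical <- function(d, X) log(d$prob[as.integer(X)])

#' @export
log_density.eff_categorical_joint <- function(d, X) {
  X <- matrix(as.integer(X), ncol = 2L)
  log(d$P[X])
}

#' @export
log_density.eff_gaussian <- function(d, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  D <- length(d$mean)
  R <- chol(d$cov)
  q <- quad_forms(X, d$mean, d$cov)
  -0.5 * (D * log(2 * pi) + 2 * sum(log(diag(R))) + q)
}

#' @export
log_density.eff_student_t <- function(d, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  D <- length(d$loc)
  k <- d$df
  R <- chol(d$scale)
  q <- quad_forms(X, d$loc, d$scale)
  lgamma((k + D) / 2) - lgamma(k / 2) - (D / 2) * log(k * pi) -
    sum(log(diag(R))) - ((k + D) / 2) * log1p(q / k)
}

#' @export
log_density.eff_product <- function(d, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1L)
  D1 <- length(d$parts[[1L]]$loc %||% d$parts[[1L]]$mean)
  log_density(d$parts[[1L]], X[, seq_len(D1), drop = FALSE]) +
    log_density(d$parts[[2L]], X[, -seq_len(D1), drop = FALSE])
}

#' Sample from an effective density
#'
#' Draws i.i.d. points. Student-t draws use the normal/chi-square scale
#' mixture with one mixing variable per draw; for joint Student-t densities
#' the mixing variable is shared across the two blocks, as required for a
#' single elliptical joint law (two independent t draws would have the wrong
#' dependence).
#'
#' @param d Density object.
#' @param n Number of draws (`>= 1`).
#' @param seed Optional integer seed for reproducibility.
#' @return Matrix with `n` rows (vector of bin indices for categorical).
#' @export
sample_effective <- function(d, n, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sample_effective_(d, n)
}

sample_effective_ <- function(d, n) UseMethod("sample_effective_")

#' @export
sample_effective_.eff_categorical <- function(d, n) {
  sample.int(length(d$prob), n, replace = TRUE, prob = d$prob)
}

#' @export
sample_effective_.eff_categorical_joint <- function(d, n) {
  b <- nrow(d$P)
  idx <- sample.int(b * b, n, replace = TRUE, prob = as.numeric(d$P))
  cbind(x = (idx - 1L) %% b + 1L, w = (idx - 1L) %/% b + 1L)
}

#' @export
sample_effective_.eff_gaussian <- function(d, n) {
  D <- length(d$mean)
  Z <- matrix(stats::rnorm(n * D), n, D)
  sweep(Z %*% chol(d$cov), 2L, d$mean, `+`)
}

#' @export
sample_effective_.eff_student_t <- function(d, n) {
  D <- length(d$loc)
  Z <- matrix(stats::rnorm(n * D), n, D)
  mix <- sqrt(stats::rchisq(n, df = d$df) / d$df)
  sweep((Z %*% chol(d$scale)) / mix, 2L, d$loc, `+`)
}

#' @export
sample_effective_.eff_product <- function(d, n) {
  cbind(sample_effective_(d$parts[[1L]], n), sample_effective_(d$parts[[2L]], n))
}

# analytic first/second moments where they exist (tests and diagnostics)
density_moments <- function(d) {
  if (inherits(d, "eff_gaussian")) {
    return(list(mean = d$mean, cov = d$cov))
  }
  if (inherits(d, "eff_student_t")) {
    if (d$df <= 2) return(list(mean = if (d$df > 1) d$loc else NULL, cov = NULL))
    return(list(mean = d$loc, cov = d$df / (d$df - 2) * d$scale))
  }
  stop("moments unavailable for this density", call. = FALSE)
}
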