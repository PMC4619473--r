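#' Standard normal CDF
#'
#' Thin, input-checked wrapper around [stats::pnorm()], kept as the package's
#' single entry point for the univariate normal CDF used in closed-form
#' misclassification probabilities.
#'
#' @param x Numeric vector of finite quantiles.
#' @return `P(Z <= x)` for `Z ~ N(0, 1)`.
#' @export
std_normal_cdf <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  stats::pnorm(x)
}

# Gauss-Legendre nodes/weights on [a, b], cached per (n) on [0, 1]
gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n, a = 0, b = 1) {
  key <- as.character(n)
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  }
  g <- gl_cache[[key]]
  list(x = a + (b - a) * g$x, w = (b - a) * g$w)
}

#' Bivariate standard normal CDF
#'
#' Joint CDF `P(X <= x, Y <= y)` of two standard normal variables with
#' correlation `rho`, computed from the single-integral reduction
#' `Phi(x)Phi(y) + (2*pi)^{-1} \int_0^rho exp(-(x^2 - 2 r x y + y^2) /
#' (2(1-r^2))) / sqrt(1-r^2) dr` evaluated by Gauss-Legendre quadrature.
#'
#' @param x,y Finite quantiles (vectorized, recycled).
#' @param rho Correlation in `[-1, 1]`.
#' @param nodes Number of quadrature nodes on the correlation path.
#' @return Probability in `[0, 1]`.
#' @export
bvn_cdf <- function(x, y, rho, nodes = 96L) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || abs(rho) > 1) {
    stop("`rho` must be a correlation in [-1, 1]", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  base <- stats::pnorm(x) * stats::pnorm(y)
  if (rho == 0) return(base)
  if (abs(rho) == 1) {
    # degenerate: Y = rho * X a.s.
    return(if (rho > 0) stats::pnorm(pmin(x, y)) else
      pmax(stats::pnorm(x) - stats::pnorm(-y), 0))
  }
  g <- gauss_legendre(nodes, 0, rho)
  out <- base
  for (k in seq_along(g$x)) {
    r <- g$x[k]
    out <- out + g$w[k] * exp(-(x^2 - 2 * r * x * y + y^2) / (2 * (1 - r^2))) /
      (2 * pi * sqrt(1 - r^2))
  }
  pmin(pmax(out, 0), 1)
}

#' Bivariate standard Student-t CDF
#'
#' Joint CDF `P(X <= x, Y <= y)` for a standard bivariate t vector with
#' correlation `rho` and `d` degrees of freedom, using the scale-mixture
#' representation: conditioned on the chi-square mixing variable `W ~
#' chisq(d)`, the pair is bivariate normal, so the CDF is the expectation of
#' [bvn_cdf()] at rescaled arguments. The expectation is evaluated by
#' Gauss-Legendre quadrature over the probability transform of `W`.
#'
#' @param x,y Finite quantiles (vectorized, recycled).
#' @param rho Correlation in `[-1, 1]`.
#' @param d Degrees of freedom, `> 0`.
#' @param rel_tol Relative tolerance of the adaptive mixing integral.
#' @return Probability in `[0, 1]`.
#' @export
bvt_cdf <- function(x, y, rho, d, rel_tol = 1e-10) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("`d` (degrees of freedom) must be > 0", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) > 1) {
    stop("`rho` must be a correlation in [-1, 1]", call. = FALSE)
  }
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  out <- numeric(n)
  # integrate over the central 1 - 2e-15 mass of the mixing chi-square; the
  # integrand is bounded by 1 so the truncation error is negligible
  lo <- stats::qchisq(1e-15, df = d)
  hi <- stats::qchisq(1e-15, df = d, lower.tail = FALSE)
  for (r in seq_len(n)) {
    out[r] <- stats::integrate(function(w) {
      stats::dchisq(w, df = d) * bvn_cdf(x[r] * sqrt(w / d), y[r] * sqrt(w / d), rho)
    }, lo, hi, rel.tol = rel_tol, abs.tol = 1e-13)$value
  }
  pmin(pmax(out, 0), 1)
}

#' CDF at zero of a non-standardized Student-t distribution
#'
#' For `T ~ t(d, m, s2)` (location `m`, scale `s2`), returns `P(T <= 0) =
#' 1/2 - sgn(m)/2 * I(m^2 / (m^2 + d s2); 1/2, d/2)` where `I` is the
#' regularized incomplete beta function. This is the workhorse for
#' closed-form misclassification probabilities under Student-t effective
#' densities.
#'
#' @param m Location (vectorized).
#' @param s2 Scale parameter, `> 0`.
#' @param d Degrees of freedom, `> 0`.
#' @return Probability in `[0, 1]`.
#' @export
t_cdf_at_zero <- function(m, s2, d) {
  if (!is.numeric(s2) || any(s2 <= 0) || any(!is.finite(s2))) {
    stop("`s2` must be positive and finite", call. = FALSE)
  }
  if (!is.numeric(d) || any(d <= 0) || any(!is.finite(d))) {
    stop("`d` must be positive and finite", call. = FALSE)
  }
  0.5 - sign(m) / 2 * stats::pbeta(m^2 / (m^2 + d * s2), 0.5, d / 2)
}

#' Distribution-free RMS bound for leave-one-out error estimation
#'
#' Upper bound `sqrt((1 + 6/e)/n + 6/sqrt(pi (n - 1)))` on the RMS deviation
#' between the leave-one-out error estimate of a discrete histogram rule and
#' the true error, holding for every feature-label distribution. Strictly
#' decreasing in the sample size `n`.
#'
#' @param n Sample size(s), `>= 2`.
#' @return The bound (vectorized over `n`).
#' @export
distribution_free_rms_bound <- function(n) {
  if (!is.numeric(n) || any(n < 2)) stop("`n` must be >= 2", call. = FALSE)
  sqrt((1 + 6 / exp(1)) / n + 6 / sqrt(pi * (n - 1)))
}
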