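#' Posterior knowledge of the class probabilities
#'
#' Represents what is known about the class-probability vector `c` of the
#' label distribution. Three modes are supported:
#' * `"known"` - `c` is a fixed point on the simplex (e.g. known prevalences);
#' * `"separate_sampling"` - per-class sample sizes were fixed by design, so
#'   the data carry no information about `c` and the posterior equals the
#'   (Dirichlet) prior;
#' * `"random_sampling"` - labels arrive i.i.d.; a Dirichlet prior with
#'   hyperparameters `alpha` is conjugate and updates to `alpha + counts`.
#'
#' @param mode One of `"known"`, `"separate_sampling"`, `"random_sampling"`.
#' @param c Known class-probability vector (mode `"known"`).
#' @param alpha Positive Dirichlet hyperparameters (other modes).
#' @return An object of class `"class_prob_posterior"`.
#' @export
class_prior <- function(mode = c("known", "separate_sampling", "random_sampling"),
                        c = NULL, alpha = NULL) {
  mode <- match.arg(mode)
  if (mode == "known") {
    if (is.null(c) || any(c < 0) || any(c > 1) || abs(sum(c) - 1) > 1e-8) {
      stop("known-mode `c` must lie on the probability simplex", call. = FALSE)
    }
    obj <- list(mode = mode, c = as.numeric(c), M = length(c))
  } else {
    if (is.null(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
      stop("Dirichlet `alpha` must all be positive", call. = FALSE)
    }
    obj <- list(mode = mode, alpha = as.numeric(alpha), M = length(alpha))
  }
  structure(obj, class = "class_prob_posterior")
}

#' Update the class-probability posterior with observed class counts
#'
#' Known and separate-sampling modes are returned unchanged (the counts are
#' uninformative about `c` there); under random sampling the Dirichlet
#' hyperparameters become `alpha + counts`.
#'
#' @param prior A [class_prior()] object.
#' @param counts Nonnegative integer vector of per-class sample sizes.
#' @return Updated `"class_prob_posterior"`.
#' @export
update_class_prob <- function(prior, counts) {
  stopifnot(inherits(prior, "class_prob_posterior"))
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("`counts` must be nonnegative integers", call. = FALSE)
  }
  if (length(counts) != prior$M) stop("`counts` length must equal M", call. = FALSE)
  if (prior$mode != "random_sampling") return(prior)
  class_prior("random_sampling", alpha = prior$alpha + counts)
}

#' First and second posterior moments of the class probabilities
#'
#' Returns `E[C_y]`, `E[C_y^2]`, and the full matrix `E[C_y C_z]`. For a
#' Dirichlet posterior with hyperparameters `a` and total `a+`:
#' `E[C_y] = a_y / a+`, `E[C_y^2] = a_y (a_y + 1) / (a+ (a+ + 1))`, and
#' `E[C_y C_z] = a_y a_z / (a+ (a+ + 1))` for `y != z`. In known mode the
#' moments are products of the fixed probabilities.
#'
#' @param post A `"class_prob_posterior"`.
#' @return List with `mean` (length `M`) and `second` (`M x M` matrix of
#'   `E[C_y C_z]`, diagonal `E[C_y^2]`).
#' @export
class_prob_moments <- function(post) {
  stopifnot(inherits(post, "class_prob_posterior"))
  if (post$mode == "known") {
    return(list(mean = post$c, second = outer(post$c, post$c)))
  }
  a <- post$alpha
  if (any(a <= 0)) stop("improper Dirichlet posterior", call. = FALSE)
  ap <- sum(a)
  second <- outer(a, a) / (ap * (1 + ap))
  diag(second) <- a * (1 + a) / (ap * (1 + ap))
  list(mean = a / ap, second = second)
}

# posterior mean f(y | S), used throughout classification and risk code
class_prob_mean <- function(post) class_prob_moments(post)$mean
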