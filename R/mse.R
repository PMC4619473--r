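#' Posterior cross moments of assignment probabilities
#'
#' `E[eps^{i,y}(Theta_y) eps^{j,z}(Theta_z) | S]`: the probability, under
#' the effective joint density of a class-`y` point `X` and a class-`z`
#' point `W`, of the joint event `{X in Gamma_i, W in Gamma_j}`. Closed
#' forms are available for the discrete model (any classifier) and for
#' binary linear classifiers under every Gaussian model: bivariate normal
#' CDF for known covariance, bivariate Student-t CDF with correlation
#' `(-1)^{i+j} / (nu*_y + 1)` for `y == z`, zero correlation (but a shared
#' mixing variable) for homoscedastic `y != z`; with independent coupling
#' and `y != z` the moment factorizes into the product of the two
#' assignment probabilities. The MC path samples pairs from the effective
#' joint density and tabulates joint assignment proportions.
#'
#' `cross_moment_table()` computes the full `(i, y, j, z)` tensor at once,
#' reusing one set of pair draws per `(y, z)` for the MC path.
#'
#' @param post Class-conditional posterior.
#' @param classifier Classifier object.
#' @param i,j Predicted-class indices (0-based).
#' @param y,z True-class indices (0-based).
#' @param method `"auto"`, `"closed"`, or `"mc"`.
#' @param n_mc Pair draws per `(y, z)` combination for the MC path.
#' @param seed Optional seed.
#' @return `cross_moment()`: a probability. `cross_moment_table()`: a 4-d
#'   array indexed `[i+1, y+1, j+1, z+1]` with attribute `method`.
#' @export
cross_moment <- function(post, classifier, i, y, j, z,
                         method = c("auto", "closed", "mc"),
                         n_mc = 1e6, seed = NULL) {
  tab <- cross_moment_table(post, classifier, method = method, n_mc = n_mc,
                            seed = seed, pairs = list(c(y, z)))
  tab[i + 1L, y + 1L, j + 1L, z + 1L]
}

#' @rdname cross_moment
#' @param pairs Optional list of `(y, z)` pairs to fill (default: all).
#' @export
cross_moment_table <- function(post, classifier,
                               method = c("auto", "closed", "mc"),
                               n_mc = 1e6, seed = NULL, pairs = NULL) {
  method <- match.arg(method)
  M <- post$M
  discrete <- inherits(post, "discrete_posterior")
  linear <- inherits(classifier, "linear_classifier")
  closed_ok <- discrete || linear
  if (method == "closed" && !closed_ok) {
    stop("closed-form cross moments need a discrete model or a binary linear classifier",
         call. = FALSE)
  }
  use_closed <- closed_ok && method != "mc"
  Mi <- if (linear && !discrete) 2L else M
  if (is.null(pairs)) {
    pairs <- list()
    for (y in seq_len(M) - 1L) for (z in seq_len(M) - 1L) {
      pairs[[length(pairs) + 1L]] <- c(y, z)
    }
  }
  out <- array(NA_real_, dim = c(Mi, M, Mi, M))
  if (!is.null(seed)) set.seed(seed)
  eps <- if (use_closed) eps_hat(classifier, post, method = "closed") else NULL

  for (p in pairs) {
    y <- p[1L]; z <- p[2L]
    out[, y + 1L, , z + 1L] <- if (use_closed) {
      cross_moment_closed(post, classifier, y, z, eps)
    } else {
      cross_moment_mc(post, classifier, y, z, Mi, n_mc)
    }
  }
  structure(out, method = if (use_closed) "closed" else "mc",
            n_mc = if (use_closed) NULL else n_mc)
}

# Mi x Mi matrix over (i, j) for one (y, z) pair, closed forms
cross_moment_closed <- function(post, classifier, y, z, eps) {
  if (inherits(post, "discrete_posterior")) {
    Mi <- nrow(eps)
    out <- matrix(0, Mi, Mi)
    if (y == z) {
      ap <- sum(post$alpha[, y + 1L])
      for (i in seq_len(Mi)) for (j in seq_len(Mi)) {
        out[i, j] <- eps[i, y + 1L] * (ap * eps[j, y + 1L] + (i == j)) / (ap + 1)
      }
    } else {
      out <- outer(eps[, y + 1L], eps[, z + 1L])
    }
    return(out)
  }
  # Gaussian, binary linear classifier
  if (y != z && (post$coupling == "independent" || post$structure == "known")) {
    return(outer(eps[, y + 1L], eps[, z + 1L]))
  }
  liny <- linear_summary(post, classifier, y)
  linz <- linear_summary(post, classifier, z)
  out <- matrix(0, 2L, 2L)
  for (i in 0:1) for (j in 0:1) {
    xi <- -(-1)^i * liny$g_m / liny$gamma * sqrt(liny$nu / (liny$nu + 1))
    xj <- -(-1)^j * linz$g_m / linz$gamma * sqrt(linz$nu / (linz$nu + 1))
    out[i + 1L, j + 1L] <- if (is.null(liny$k)) {
      # known covariance, y == z: bivariate normal with rho = (-1)^(i+j)/(nu*+1)
      bvn_cdf(xi, xj, (-1)^(i + j) / (liny$nu + 1))
    } else if (y == z) {
      bvt_cdf(xi * sqrt(liny$k), xj * sqrt(liny$k),
              (-1)^(i + j) / (liny$nu + 1), liny$k)
    } else {
      # homoscedastic y != z: shared dof couples the points, correlation 0
      bvt_cdf(xi * sqrt(liny$k), xj * sqrt(linz$k), 0, liny$k)
    }
  }
  out
}

cross_moment_mc <- function(post, classifier, y, z, Mi, n_mc) {
  jd <- effective_joint(post, y, z)
  XW <- sample_effective_(jd, n_mc)
  D <- if (inherits(post, "discrete_posterior")) 1L else post$D
  px <- predict(classifier, XW[, seq_len(D), drop = FALSE])
  pw <- predict(classifier, XW[, D + seq_len(D), drop = FALSE])
  table_ij <- matrix(0, Mi, Mi)
  tab <- table(factor(px, levels = 0:(Mi - 1L)), factor(pw, levels = 0:(Mi - 1L)))
  table_ij[] <- as.numeric(tab) / n_mc
  table_ij
}

#' Sample-conditioned MSE of the Bayesian risk estimator
#'
#' The posterior variance of the true risk around the BRE, conditioned on
#' the observed sample: assembled from the second moments of the class
#' probabilities, the cross moments of the assignment probabilities, and
#' the BRE itself:
#' `MSE = sum_{y,z,i,j} lambda(i,y) lambda(j,z) E[C_y C_z | S]
#'  E[eps^{i,y} eps^{j,z} | S] - Rhat^2`.
#' Tiny negative values arising from floating-point (or Monte Carlo)
#' cancellation are clamped to zero with a warning.
#'
#' @inheritParams cross_moment
#' @param class_post Class-probability posterior.
#' @param loss Loss matrix (default zero-one).
#' @return List with `mse`, `rms`, `bre` (the point estimate),
#'   `report` (the full `"risk_report"`), `cross_moments`, `method`.
#' @export
mse_bre <- function(post, class_post, classifier, loss = NULL,
                    method = c("auto", "closed", "mc"), n_mc = 1e6,
                    seed = NULL) {
  method <- match.arg(method)
  loss <- as_loss(loss, post$M)
  discrete <- inherits(post, "discrete_posterior")
  closed_ok <- discrete || inherits(classifier, "linear_classifier")
  if (!closed_ok || method == "mc") {
    return(mse_bre_mc(post, class_post, classifier, loss, n_mc, seed))
  }
  rep_ <- bre(classifier, post, class_post, loss, method = "closed", seed = seed)
  cm <- cross_moment_table(post, classifier, method = "closed")
  mom <- rep_$class_prob_moments
  L <- unclass(loss)
  Mi <- dim(cm)[1L]; M <- post$M
  second <- 0
  for (y in seq_len(M)) for (z in seq_len(M)) {
    lam_y <- L[seq_len(Mi), y]
    lam_z <- L[seq_len(Mi), z]
    second <- second + mom$second[y, z] *
      drop(t(lam_y) %*% cm[, y, , z] %*% lam_z)
  }
  mse <- second - rep_$bre^2
  if (mse < 0) {
    if (mse < -1e-6) {
      warning(sprintf("negative variance from cancellation (%.3g); clamped to 0", mse))
    }
    mse <- 0
  }
  list(mse = mse, rms = sqrt(mse), bre = rep_$bre, report = rep_,
       cross_moments = cm, method = attr(cm, "method"))
}

# Monte Carlo MSE with one coherent set of pair draws: for each class y,
# n_mc pairs (x, w) from the effective joint f(x, w | y, y, S) give both the
# cross-moment table T^{yy} and (through the two marginal halves) eps-hat;
# homoscedastic y != z pairs are drawn from their joint, while independent
# y != z moments factorize through the *same* eps-hat estimates. Using one
# draw set makes the factorized part of E[R^2] cancel exactly against
# Rhat^2, so the variance estimate is an empirical covariance rather than a
# difference of two independently noisy terms.
mse_bre_mc <- function(post, class_post, classifier, loss, n_mc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  M <- post$M
  Mi <- classifier$M %||% M
  L <- unclass(loss)
  eps <- matrix(0, Mi, M)
  tables <- vector("list", M * M)
  dim(tables) <- c(M, M)
  coupled <- !inherits(post, "discrete_posterior") &&
    post$structure != "known" && post$coupling == "homoscedastic"
  for (y in seq_len(M) - 1L) {
    jd <- effective_joint(post, y, y)
    XW <- sample_effective_(jd, n_mc)
    D <- ncol(XW) %/% 2L
    px <- predict(classifier, XW[, seq_len(D), drop = FALSE])
    pw <- predict(classifier, XW[, D + seq_len(D), drop = FALSE])
    tab <- table(factor(px, levels = 0:(Mi - 1L)), factor(pw, levels = 0:(Mi - 1L)))
    tables[[y + 1L, y + 1L]] <- (unclass(tab) + t(unclass(tab))) / (2 * n_mc)
    eps[, y + 1L] <- (tabulate(px + 1L, nbins = Mi) + tabulate(pw + 1L, nbins = Mi)) /
      (2 * n_mc)
  }
  for (y in seq_len(M) - 1L) for (z in seq_len(M) - 1L) {
    if (y == z) next
    tables[[y + 1L, z + 1L]] <- if (coupled) {
      jd <- effective_joint(post, y, z)
      XW <- sample_effective_(jd, n_mc)
      D <- ncol(XW) %/% 2L
      px <- predict(classifier, XW[, seq_len(D), drop = FALSE])
      pw <- predict(classifier, XW[, D + seq_len(D), drop = FALSE])
      unclass(table(factor(px, levels = 0:(Mi - 1L)),
                    factor(pw, levels = 0:(Mi - 1L)))) / n_mc
    } else {
      outer(eps[, y + 1L], eps[, z + 1L])
    }
  }
  mom <- class_prob_moments(class_post)
  bre_val <- sum(L[seq_len(Mi), ] * eps * rep(mom$mean, each = Mi))
  second <- 0
  for (y in seq_len(M)) for (z in seq_len(M)) {
    second <- second + mom$second[y, z] *
      drop(t(L[seq_len(Mi), y]) %*% tables[[y, z]] %*% L[seq_len(Mi), z])
  }
  mse <- second - bre_val^2
  if (mse < 0) mse <- 0   # MC noise floor; genuine MSE near zero
  cm <- array(NA_real_, dim = c(Mi, M, Mi, M))
  for (y in seq_len(M)) for (z in seq_len(M)) cm[, y, , z] <- tables[[y, z]]
  rep_ <- base::structure(
    list(bre = bre_val, eps_hat = base::structure(eps, method = "mc", n_mc = n_mc),
         class_prob_moments = mom, method = "mc", n_mc = n_mc, seed = seed),
    class = "risk_report")
  list(mse = mse, rms = sqrt(mse), bre = bre_val, report = rep_,
       cross_moments = base::structure(cm, method = "mc", n_mc = n_mc),
       method = "mc")
}

#' Sample-conditioned MSE of an arbitrary risk estimate
#'
#' For any risk estimate `Rdot`, `MSE(Rdot | S) = MSE(Rhat | S) +
#' (Rhat - Rdot)^2`: the BRE's MSE plus the squared gap to the BRE. The
#' minimum over `Rdot` is attained exactly at the BRE.
#'
#' @param bre_mse Result of [mse_bre()].
#' @param estimate The risk estimate to evaluate (scalar).
#' @return The MSE of the supplied estimate.
#' @export
mse_arbitrary <- function(bre_mse, estimate) {
  stopifnot_finite_scalar(estimate)
  bre_mse$mse + (bre_mse$bre - estimate)^2
}
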