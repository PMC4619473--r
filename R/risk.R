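#' True expected risk under a known feature-label distribution
#'
#' Computes `R(psi, c, theta) = sum_y sum_i lambda(i, y) c_y eps^{i,y}`
#' where `eps^{i,y}` is the probability that a class-`y` point is assigned
#' class `i`. Closed forms are used for binary linear classifiers under
#' Gaussian parameters (normal CDF of the signed margin) and for discrete
#' parameters (finite sum over bins); otherwise a stratified Monte Carlo
#' test sample is used, whose RMS error is bounded by `1 / sqrt(4 n_test)`.
#'
#' @param classifier A classifier object with a `predict` method.
#' @param c Class-probability vector.
#' @param theta Parameter set (see [bdr_classifier()]).
#' @param loss Loss matrix (default zero-one).
#' @param method `"auto"`, `"closed"`, or `"mc"`.
#' @param n_test Stratified test-sample size for the MC path.
#' @param seed Optional seed for the MC path.
#' @return The risk (scalar), with attributes `eps` (the `M x M` assignment
#'   probability matrix, rows = predicted class) and, for the MC path,
#'   `mc_rms_bound`.
#' @export
true_risk <- function(classifier, c, theta, loss = NULL,
                      method = c("auto", "closed", "mc"),
                      n_test = 10000L, seed = NULL) {
  method <- match.arg(method)
  M <- length(c)
  loss <- as_loss(loss, M)
  closed_ok <- (theta$type == "discrete") ||
    (theta$type == "gaussian" && inherits(classifier, "linear_classifier"))
  if (method == "closed" && !closed_ok) {
    stop("no closed form for this classifier/parameter combination", call. = FALSE)
  }
  use_closed <- closed_ok && method != "mc"

  if (use_closed) {
    eps <- matrix(0, M, M)
    if (theta$type == "discrete") {
      pred <- predict(classifier, seq_len(nrow(theta$p)))
      for (i in seq_len(M) - 1L) {
        eps[i + 1L, ] <- colSums(theta$p[pred == i, , drop = FALSE])
      }
    } else {
      a <- classifier$a
      for (jy in seq_len(M)) {
        g <- sum(a * theta$mu[, jy]) + classifier$b
        sd_a <- sqrt(drop(t(a) %*% theta$Sigma[[jy]] %*% a))
        eps[1L, jy] <- stats::pnorm(-g / sd_a)   # P(g(X) <= 0)
        eps[2L, jy] <- 1 - eps[1L, jy]
      }
    }
    risk <- sum(unclass(loss) * eps * rep(c, each = M))
    return(structure(risk, eps = eps, method = "closed"))
  }

  if (theta$type != "gaussian") stop("MC path expects gaussian parameters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_y <- stratified_counts(c, n_test)
  eps <- matrix(0, M, M)
  for (jy in seq_len(M)) {
    if (n_y[jy] == 0L) next
    Xy <- sample_effective_(eff_gaussian(theta$mu[, jy], theta$Sigma[[jy]]), n_y[jy])
    pred <- predict(classifier, Xy)
    eps[, jy] <- tabulate(pred + 1L, nbins = M) / n_y[jy]
  }
  risk <- sum(unclass(loss) * eps * rep(c, each = M))
  structure(risk, eps = eps, method = "mc", mc_rms_bound = 1 / sqrt(4 * n_test))
}

# apportion a test sample across classes proportional to c (largest
# remainders get the leftover points)
stratified_counts <- function(c, n) {
  raw <- c * n
  n_y <- floor(raw)
  rem <- n - sum(n_y)
  if (rem > 0) {
    top <- order(raw - n_y, decreasing = TRUE)[seq_len(rem)]
    n_y[top] <- n_y[top] + 1
  }
  as.integer(n_y)
}

#' Posterior assignment probabilities (eps-hat matrix)
#'
#' `epshat^{i,y} = P(X in Gamma_i | y, S)`, the posterior probability that
#' a class-`y` point is assigned class `i` by the classifier: the integral
#' of the class-`y` effective density over decision region `Gamma_i`. Each
#' column sums to 1. Closed forms cover the discrete model (any classifier)
#' and binary linear classifiers under every Gaussian model; otherwise the
#' effective density is sampled and assignment proportions tabulated.
#'
#' @param classifier Classifier object.
#' @param post Class-conditional posterior.
#' @param method `"auto"`, `"closed"`, or `"mc"`.
#' @param n_mc Draws per class for the MC path.
#' @param seed Optional seed.
#' @return `M x M` matrix (rows = predicted class `i`, columns = true class
#'   `y`), with attribute `method`.
#' @export
eps_hat <- function(classifier, post, method = c("auto", "closed", "mc"),
                    n_mc = 1e6, seed = NULL) {
  method <- match.arg(method)
  M_cl <- classifier$M %||% post$M
  discrete <- inherits(post, "discrete_posterior")
  closed_ok <- discrete || inherits(classifier, "linear_classifier")
  if (method == "closed" && !closed_ok) {
    stop("closed-form eps-hat needs a discrete model or a binary linear classifier",
         call. = FALSE)
  }
  use_closed <- closed_ok && method != "mc"
  M <- if (discrete || !inherits(classifier, "linear_classifier")) post$M else 2L

  if (use_closed) {
    eps <- matrix(0, M, post$M)
    if (discrete) {
      pred <- predict(classifier, seq_len(post$b))
      for (y in seq_len(post$M) - 1L) {
        p <- effective_density(post, y)$prob
        for (i in seq_len(M) - 1L) eps[i + 1L, y + 1L] <- sum(p[pred == i])
      }
    } else {
      for (y in seq_len(post$M) - 1L) {
        lin <- linear_summary(post, classifier, y)
        for (i in 0:1) {
          m_iy <- (-1)^i * lin$g_m
          eps[i + 1L, y + 1L] <- if (is.null(lin$k)) {
            # known covariance: normal CDF of the signed margin
            std_normal_cdf(-m_iy / lin$gamma * sqrt(lin$nu / (lin$nu + 1)))
          } else {
            t_cdf_at_zero(m_iy, (lin$nu + 1) / (lin$k * lin$nu) * lin$gamma^2, lin$k)
          }
        }
      }
    }
    return(structure(eps, method = "closed"))
  }

  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(0, M, post$M)
  for (y in seq_len(post$M) - 1L) {
    d <- effective_density(post, y)
    Xy <- sample_effective_(d, n_mc)
    pred <- predict(classifier, Xy)
    eps[, y + 1L] <- tabulate(pred + 1L, nbins = M) / n_mc
  }
  structure(eps, method = "mc", n_mc = n_mc)
}

# per-class summary of a binary linear classifier under a Gaussian
# posterior: signed discriminant at the location, the scale gamma, the
# effective dof k (NULL for known covariance) and nu*_y
linear_summary <- function(post, classifier, y) {
  j <- y + 1L
  a <- classifier$a
  g_m <- sum(a * post$m[, j]) + classifier$b
  if (post$structure == "known") {
    return(list(g_m = g_m, gamma = sqrt(drop(t(a) %*% post$Sigma[[j]] %*% a)),
                k = NULL, nu = post$nu[j]))
  }
  gamma2 <- drop(t(a) %*% scale_unit(post, j) %*% a)
  list(g_m = g_m, gamma = sqrt(gamma2), k = eff_dof(post)[j], nu = post$nu[j])
}

#' Bayesian risk estimator (BRE)
#'
#' The MMSE estimate of the expected risk of a classifier given the sample:
#' `Rhat(psi, S) = sum_y sum_i lambda(i, y) f(y | S) epshat^{i,y}`. Under
#' zero-one loss this is the Bayesian error estimator `1 - sum_y f(y | S)
#' epshat^{y,y}`.
#'
#' @param classifier Classifier object.
#' @param post Class-conditional posterior.
#' @param class_post Class-probability posterior.
#' @param loss Loss matrix (default zero-one).
#' @inheritParams eps_hat
#' @return A `"risk_report"` list: `bre`, `eps_hat`, `class_prob_moments`,
#'   `method`, `n_mc`, `seed`.
#' @export
bre <- function(classifier, post, class_post, loss = NULL,
                method = c("auto", "closed", "mc"), n_mc = 1e6, seed = NULL) {
  method <- match.arg(method)
  loss <- as_loss(loss, post$M)
  eps <- eps_hat(classifier, post, method, n_mc, seed)
  mom <- class_prob_moments(class_post)
  val <- sum(unclass(loss) * eps * rep(mom$mean, each = nrow(eps)))
  structure(list(bre = val, eps_hat = eps, class_prob_moments = mom,
                 method = attr(eps, "method"), n_mc = attr(eps, "n_mc"),
                 seed = seed),
            class = "risk_report")
}

empirical_risk <- function(pred, y, loss) {
  mean(unclass(loss)[cbind(pred + 1L, y + 1L)])
}

# stratified fold assignment: per class, shuffled indices dealt round-robin
stratified_folds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Classical resampling risk estimators
#'
#' Cross-validation, leave-one-out and 0.632-bootstrap estimates of the
#' risk of a classification rule trained on `(X, y)`. `rule` is a training
#' procedure `function(X, y)` returning a classifier (e.g. a wrapper around
#' [plugin_lda()], [plugin_qda()] or [obrc_classifier()] retraining the
#' posterior on the surrogate sample; the prior is never changed inside the
#' resampling loop). Cross-validation uses stratified folds and averages
#' over `reps` independent fold partitions; leave-one-out is the `n`-fold
#' special case. The 0.632 bootstrap reports `0.632 * (mean out-of-bag
#' risk over B replicates) + 0.368 * resubstitution risk`. Surrogate
#' training sets on which the rule fails (e.g. a singular covariance
#' estimate), and bootstrap replicates with an empty out-of-bag set, are
#' thrown out and counted; if every replicate fails, an error is raised.
#'
#' @param X,y Training data.
#' @param rule Training procedure `function(X, y)` returning a classifier.
#' @param loss Loss matrix (default zero-one over the observed classes).
#' @param method `"cv"`, `"loo"`, or `"boot632"`.
#' @param folds Number of CV folds.
#' @param reps CV repetitions (ignored for `"loo"`).
#' @param B Bootstrap replicates.
#' @param seed Optional seed.
#' @return Risk estimate (scalar), with attribute `n_failed` counting
#'   discarded surrogate replicates.
#' @export
classical_risk_estimate <- function(X, y, rule, loss = NULL,
                                    method = c("cv", "loo", "boot632"),
                                    folds = 10L, reps = 10L, B = 100L,
                                    seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  M <- if (!is.null(loss)) nrow(loss) else check_labels(y)
  loss <- as_loss(loss, M)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  n_failed <- 0L

  if (method %in% c("cv", "loo")) {
    if (method == "loo") { folds <- n; reps <- 1L }
    rep_vals <- numeric(0L)
    for (r in seq_len(reps)) {
      fold <- if (method == "loo") seq_len(n) else stratified_folds(y, folds)
      tot_loss <- 0; tot_n <- 0L
      for (f in unique(fold)) {
        hold <- fold == f
        cls <- tryCatch(rule(X[!hold, , drop = FALSE], y[!hold]), error = function(e) NULL)
        if (is.null(cls)) { n_failed <- n_failed + 1L; next }
        pred <- predict(cls, X[hold, , drop = FALSE])
        tot_loss <- tot_loss + sum(unclass(loss)[cbind(pred + 1L, y[hold] + 1L)])
        tot_n <- tot_n + sum(hold)
      }
      if (tot_n > 0L) rep_vals <- c(rep_vals, tot_loss / tot_n)
    }
    if (!length(rep_vals)) stop("rule failed on every surrogate training set", call. = FALSE)
    return(structure(mean(rep_vals), n_failed = n_failed))
  }

  # 0.632 bootstrap
  oob_vals <- numeric(0L)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (!length(oob)) { n_failed <- n_failed + 1L; next }
    cls <- tryCatch(rule(X[idx, , drop = FALSE], y[idx]), error = function(e) NULL)
    if (is.null(cls)) { n_failed <- n_failed + 1L; next }
    pred <- predict(cls, X[oob, , drop = FALSE])
    oob_vals <- c(oob_vals, empirical_risk(pred, y[oob], loss))
  }
  if (!length(oob_vals)) stop("rule failed on every bootstrap replicate", call. = FALSE)
  full <- rule(X, y)
  resub <- empirical_risk(predict(full, X), y, loss)
  structure(0.632 * mean(oob_vals) + 0.368 * resub, n_failed = n_failed)
}
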