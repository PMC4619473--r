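#' Synthetic-study model specifications
#'
#' `sim_model_spec()` bundles a Gaussian prior, known equal class
#' probabilities, and a loss matrix into a simulation model. The covariance
#' scale is specified through the expected covariance: writing `k` for the
#' effective Student-t degrees of freedom of the prior predictive
#' (`kappa - D + 1` for arbitrary structure, `(kappa + D + 1) D - 2` for
#' scaled identity), the prior satisfies `E[Sigma] = cov_scale * I_D` by
#' setting `S = cov_scale * (k - 2) * I_D` (arbitrary; inverse-Wishart mean
#' `S / (kappa - D - 1)`) or `trace(S) = cov_scale * (k - 2)` (scaled
#' identity; inverse-gamma mean `trace(S) / ((kappa + D + 1) D - 4)`).
#'
#' `preset_model(id)` returns the package's eight built-in study settings:
#' two-class and five-class problems at `D = 2` and `D = 20`, with
#' independent arbitrary, homoscedastic arbitrary and independent
#' scaled-identity priors, under an asymmetric binary loss
#' (`lambda(0,1) = 2`, `lambda(1,0) = 1`) or zero-one loss.
#'
#' @param D,M Dimension and number of classes.
#' @param nu Length-`M` mean-precision hyperparameters.
#' @param m `D x M` prior locations.
#' @param kappa Covariance hyperparameter (scalar; shared value per class
#'   for independent coupling).
#' @param cov_scale Expected covariance is `cov_scale * I_D`.
#' @param structure,coupling Covariance model (see [gaussian_prior()]).
#' @param loss Loss matrix (default zero-one).
#' @return A `"sim_model"` list: `prior`, `c`, `loss`, `D`, `M`.
#' @export
sim_model_spec <- function(D, M, nu, m, kappa, cov_scale = 0.3,
                           structure = c("arbitrary", "scaled_identity"),
                           coupling = c("independent", "homoscedastic"),
                           loss = NULL) {
  structure <- match.arg(structure)
  coupling <- match.arg(coupling)
  k <- if (structure == "arbitrary") kappa - D + 1 else (kappa + D + 1) * D - 2
  if (k <= 2) stop("prior predictive needs k > 2 for a finite covariance", call. = FALSE)
  S <- if (structure == "arbitrary") {
    diag(cov_scale * (k - 2), D)
  } else {
    diag(cov_scale * (k - 2) / D, D)   # trace(S) = cov_scale * (k - 2)
  }
  kap <- if (coupling == "homoscedastic") kappa else rep(kappa, M)
  Ss <- if (coupling == "homoscedastic") S else rep(list(S), M)
  prior <- gaussian_prior(D, M, structure, coupling, nu = nu, m = m,
                          kappa = kap, S = Ss)
  loss <- as_loss(loss, M)
  base::structure(list(prior = prior, c = rep(1 / M, M), loss = loss, D = D, M = M),
                  class = "sim_model")  # `structure` arg shadows base
}

#' @rdname sim_model_spec
#' @param id Preset number, 1-8.
#' @export
preset_model <- function(id) {
  stopifnot(id %in% 1:8)
  asym <- loss_matrix(rbind(c(0, 2), c(1, 0)))
  m5 <- cbind(c(0, 0), c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  m7 <- cbind(rep(0, 20), rep(0.1, 20), rep(-0.1, 20),
              c(rep(0.1, 10), rep(-0.1, 10)), c(rep(-0.1, 10), rep(0.1, 10)))
  switch(id,
    sim_model_spec(2, 2, nu = c(12, 2), m = cbind(c(0, 0), c(0.5, 0.5)),
                   kappa = 6, structure = "arbitrary", coupling = "independent",
                   loss = asym),
    sim_model_spec(2, 2, nu = c(12, 2), m = cbind(c(0, 0), c(0.5, 0.5)),
                   kappa = 6, structure = "arbitrary", coupling = "homoscedastic",
                   loss = asym),
    sim_model_spec(2, 5, nu = c(12, 2, 2, 2, 2), m = m5, kappa = 6,
                   structure = "arbitrary", coupling = "independent"),
    sim_model_spec(2, 5, nu = c(12, 2, 2, 2, 2), m = m5, kappa = 6,
                   structure = "arbitrary", coupling = "homoscedastic"),
    sim_model_spec(20, 2, nu = c(12, 2), m = cbind(rep(0, 20), rep(0.05, 20)),
                   kappa = -20.65, structure = "scaled_identity",
                   coupling = "independent", loss = asym),
    sim_model_spec(20, 2, nu = c(20, 20), m = matrix(0, 20, 2),
                   kappa = -20.65, structure = "scaled_identity",
                   coupling = "independent", loss = asym),
    sim_model_spec(20, 5, nu = c(12, 2, 2, 2, 2), m = m7, kappa = -20.65,
                   structure = "scaled_identity", coupling = "independent"),
    sim_model_spec(20, 5, nu = rep(20, 5), m = matrix(0, 20, 5),
                   kappa = -20.65, structure = "scaled_identity",
                   coupling = "independent")
  )
}

# draw one inverse-Wishart matrix: X ~ IW(kappa, S) iff X^{-1} ~ W(kappa, S^{-1})
riwish <- function(kappa, S) {
  W <- stats::rWishart(1L, df = kappa, Sigma = solve(S))[, , 1L]
  solve(W)
}

#' Draw a feature-label distribution from a simulation prior
#'
#' Two-step generation, step 1: class probabilities are the spec's known
#' equal probabilities; covariances are drawn from the prior
#' (inverse-Wishart for arbitrary structure - one shared draw under
#' homoscedastic coupling - or the inverse-gamma scaled-identity analogue),
#' then means given covariances from `N(m_y, Sigma_y / nu_y)`.
#'
#' @param spec A `"sim_model"`.
#' @param seed Optional seed.
#' @return List `(c, theta)` with `theta` as in [bdr_classifier()].
#' @export
sample_model <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- spec$prior
  check_proper_prior_for_sampling(pr)
  D <- pr$D; M <- pr$M
  Sig <- vector("list", M)
  if (pr$structure == "arbitrary") {
    if (pr$coupling == "homoscedastic") {
      Sig <- rep(list(riwish(pr$kappa, pr$S)), M)
    } else {
      for (j in seq_len(M)) Sig[[j]] <- riwish(pr$kappa[j], pr$S[[j]])
    }
  } else if (pr$structure == "scaled_identity") {
    draw_s2 <- function(kap, S) {
      shape <- (kap + D + 1) * D / 2 - 1
      if (shape <= 0) stop("improper scaled-identity prior", call. = FALSE)
      sum(diag(S)) / 2 / stats::rgamma(1L, shape = shape)
    }
    if (pr$coupling == "homoscedastic") {
      Sig <- rep(list(diag(draw_s2(pr$kappa, pr$S), D)), M)
    } else {
      for (j in seq_len(M)) Sig[[j]] <- diag(draw_s2(pr$kappa[j], pr$S[[j]]), D)
    }
  } else {
    Sig <- pr$Sigma
  }
  mu <- matrix(0, D, M)
  for (j in seq_len(M)) {
    L <- chol(Sig[[j]] / pr$nu[j])
    mu[, j] <- pr$m[, j] + drop(stats::rnorm(D) %*% L)
  }
  list(c = spec$c, theta = list(type = "gaussian", mu = mu, Sigma = Sig))
}

check_proper_prior_for_sampling <- function(pr) {
  if (any(pr$nu <= 0)) stop("sampling from the prior needs nu > 0", call. = FALSE)
  if (pr$structure == "arbitrary") {
    kmin <- min(pr$kappa)
    if (kmin <= pr$D - 1) stop("sampling needs kappa > D - 1", call. = FALSE)
  }
  invisible(pr)
}

#' Draw a stratified sample from a fixed feature-label distribution
#'
#' Step 2 of the two-step procedure: exactly `n / M` points per class
#' (`n` must be divisible by `M`).
#'
#' @param theta Gaussian parameter set.
#' @param n Total sample size.
#' @return List `(X, y)`.
#' @export
sample_stratified <- function(theta, n) {
  M <- ncol(theta$mu)
  if (n %% M != 0L) stop("`n` must be divisible by the number of classes", call. = FALSE)
  per <- n %/% M
  D <- nrow(theta$mu)
  X <- matrix(0, n, D)
  y <- rep(seq_len(M) - 1L, each = per)
  for (j in seq_len(M)) {
    X[y == j - 1L, ] <- sample_effective_(eff_gaussian(theta$mu[, j], theta$Sigma[[j]]), per)
  }
  list(X = X, y = y)
}

#' Monte Carlo study of classifiers and risk estimators
#'
#' For each replicate and sample size: draw `(c, theta)` from the prior,
#' draw a stratified training sample, train the requested classifiers,
#' compute each classifier's true risk on a stratified test sample, and
#' (optionally) the requested risk estimators, the sample-conditioned MSE
#' of the BRE, and the standardized deviation `Z = (Rhat - R) / RMS`.
#' Classifier or estimator failures on a replicate are recorded as `NA`
#' and excluded from summaries. Deterministic given `seed`.
#'
#' @param spec A `"sim_model"`.
#' @param n_grid Training sample sizes (each divisible by `M`).
#' @param replicates Number of Monte Carlo replicates.
#' @param classifiers Subset of `c("obrc", "lda", "qda")`.
#' @param estimators Subset of `c("bre", "cv", "loo", "boot632")` (risk
#'   estimators evaluated for every trained classifier).
#' @param mse Compute the sample-conditioned MSE (and `Z`) of the BRE for
#'   each classifier? Implies `"bre"`.
#' @param n_test Stratified test-sample size for true risk.
#' @param n_mc Effective-density draws per estimate for MC BRE/MSE paths.
#' @param folds,reps,B Resampling-estimator settings.
#' @param seed Master seed.
#' @return An `"experiment_result"`: `records` (one data.frame row per
#'   replicate x n x classifier) plus the call settings.
#' @export
run_experiment <- function(spec, n_grid, replicates,
                           classifiers = c("obrc", "lda", "qda"),
                           estimators = character(),
                           mse = FALSE,
                           n_test = 10000L, n_mc = 1e4,
                           folds = 10L, reps = 10L, B = 100L,
                           seed = 1L) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  if (length(estimators)) {
    estimators <- match.arg(estimators, c("bre", "cv", "loo", "boot632"),
                            several.ok = TRUE)
  }
  if (mse && !("bre" %in% estimators)) estimators <- c(estimators, "bre")
  pr <- spec$prior
  cpost <- class_prior("known", c = spec$c)
  rows <- vector("list", length(n_grid) * replicates * length(classifiers))
  ri <- 0L
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    for (r in seq_len(replicates)) {
      set.seed(derive_seed(seed, (gi - 1L) * replicates + r))
      dist <- sample_model(spec)
      train <- sample_stratified(dist$theta, n)
      post <- tryCatch(update_gaussian(pr, train$X, train$y), error = function(e) NULL)
      for (cl in classifiers) {
        ri <- ri + 1L
        rec <- list(replicate = r, n = n, classifier = cl,
                    true_risk = NA_real_, bre = NA_real_, cv = NA_real_,
                    loo = NA_real_, boot632 = NA_real_, mse = NA_real_,
                    rms = NA_real_, z = NA_real_)
        psi <- tryCatch(switch(cl,
          obrc = { if (is.null(post)) stop("posterior update failed")
                   obrc_classifier(post, cpost, spec$loss) },
          lda = plugin_lda(train$X, train$y, spec$loss, c = spec$c, M = spec$M),
          qda = plugin_qda(train$X, train$y, spec$loss, c = spec$c, M = spec$M)
        ), error = function(e) NULL)
        if (!is.null(psi)) {
          rec$true_risk <- as.numeric(true_risk(psi, dist$c, dist$theta, spec$loss,
                                                method = "mc", n_test = n_test))
          for (est in estimators) {
            val <- tryCatch(switch(est,
              bre = {
                if (mse) {
                  ms <- mse_bre(post, cpost, psi, spec$loss, method = "mc", n_mc = n_mc)
                  rec$mse <- ms$mse; rec$rms <- ms$rms
                  if (ms$rms > 0) rec$z <- (ms$bre - rec$true_risk) / ms$rms
                  ms$bre
                } else {
                  bre(psi, post, cpost, spec$loss, method = "mc", n_mc = n_mc)$bre
                }
              },
              cv = classical_risk_estimate(train$X, train$y, rule_for(cl, spec, pr, cpost),
                                           spec$loss, "cv", folds = folds, reps = reps),
              loo = classical_risk_estimate(train$X, train$y, rule_for(cl, spec, pr, cpost),
                                            spec$loss, "loo"),
              boot632 = classical_risk_estimate(train$X, train$y, rule_for(cl, spec, pr, cpost),
                                                spec$loss, "boot632", B = B)
            ), error = function(e) NA_real_)
            if (est %in% c("cv", "loo", "boot632")) rec[[est]] <- as.numeric(val)
            if (est == "bre") rec$bre <- as.numeric(val)
          }
        }
        rows[[ri]] <- rec
      }
    }
  }
  records <- do.call(rbind, lapply(rows[seq_len(ri)], function(r) as.data.frame(r)))
  structure(list(records = records, spec = spec, n_grid = n_grid,
                 replicates = replicates, estimators = estimators,
                 n_test = n_test, n_mc = n_mc, seed = seed),
            class = "experiment_result")
}

# training procedure for resampling estimators: retrains on the surrogate
# sample, prior unchanged
rule_for <- function(cl, spec, prior, cpost) {
  force(cl); force(spec); force(prior); force(cpost)
  function(X, y) {
    switch(cl,
      obrc = obrc_classifier(update_gaussian(prior, X, y), cpost, spec$loss),
      lda = plugin_lda(X, y, spec$loss, c = spec$c, M = spec$M),
      qda = plugin_qda(X, y, spec$loss, c = spec$c, M = spec$M))
  }
}

#' Aggregate an experiment into summary tables
#'
#' Per `(n, classifier)`: mean and standard deviation of the true risk;
#' per risk estimator: the empirical RMS `sqrt(mean (Rdot - R)^2)`; for
#' the BRE additionally the Bayesian RMS `sqrt(mean MSE(Rhat | S))` and
#' the mean and variance of `Z = (Rhat - R) / RMS(Rhat | S)`.
#'
#' @param result An `"experiment_result"`.
#' @return A data.frame of aggregates.
#' @export
summarize_experiment <- function(result) {
  rec <- result$records
  groups <- unique(rec[, c("n", "classifier")])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sub <- rec[rec$n == groups$n[g] & rec$classifier == groups$classifier[g], ]
    row <- list(n = groups$n[g], classifier = groups$classifier[g],
                replicates = sum(!is.na(sub$true_risk)),
                mean_risk = mean(sub$true_risk, na.rm = TRUE),
                sd_risk = stats::sd(sub$true_risk, na.rm = TRUE))
    for (est in c("bre", "cv", "loo", "boot632")) {
      v <- sub[[est]]
      row[[paste0("rms_", est)]] <- if (all(is.na(v))) NA_real_ else
        sqrt(mean((v - sub$true_risk)^2, na.rm = TRUE))
    }
    row$bayes_rms <- if (all(is.na(sub$mse))) NA_real_ else sqrt(mean(sub$mse, na.rm = TRUE))
    row$z_mean <- mean(sub$z, na.rm = TRUE)
    row$z_var <- stats::var(sub$z, na.rm = TRUE)
    out[[g]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}

#' Write a small labeled fixture and its matching model configuration
#'
#' Generates a reproducible CSV (features + `label` column) with known
#' generating parameters, plus a YAML model configuration describing a
#' prior suitable for analysing it. Intended for examples and tests.
#'
#' @param kind `"gaussian"` or `"discrete"`.
#' @param size Number of rows.
#' @param seed Seed (fixtures are byte-identical given the seed).
#' @param dir Output directory.
#' @return Invisible list with `data` and `config` file paths.
#' @export
make_fixture <- function(kind = c("gaussian", "discrete"), size = 40L,
                         seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  set.seed(seed)
  data_path <- file.path(dir, paste0(kind, "_fixture.csv"))
  cfg_path <- file.path(dir, paste0(kind, "_fixture.yaml"))
  if (kind == "gaussian") {
    M <- 2L; per <- size %/% M
    mu <- cbind(c(0, 0), c(1, 1))
    y <- rep(0:1, each = per)
    X <- do.call(rbind, lapply(1:M, function(j) {
      matrix(stats::rnorm(per * 2, mean = rep(mu[, j], each = per)), per, 2)
    }))
    df <- data.frame(f1 = round(X[, 1], 6), f2 = round(X[, 2], 6), label = y)
    cfg <- list(model = list(structure = "arbitrary", coupling = "independent",
                             D = 2L, M = 2L, nu = c(1, 1), m = list(c(0, 0), c(1, 1)),
                             kappa = c(5, 5), S = 3),
                class_prob = list(mode = "known", c = c(0.5, 0.5)),
                loss = list(c(0, 1), c(1, 0)))
  } else {
    b <- 8L; M <- 2L; per <- size %/% M
    p0 <- (8:1) / sum(1:8); p1 <- (1:8) / sum(1:8)
    x <- c(sample.int(b, per, TRUE, p0), sample.int(b, per, TRUE, p1))
    df <- data.frame(bin = x, label = rep(0:1, each = per))
    cfg <- list(model = list(type = "discrete", b = b, M = M, alpha = 1),
                class_prob = list(mode = "known", c = c(0.5, 0.5)),
                loss = list(c(0, 1), c(1, 0)))
  }
  utils::write.csv(df, data_path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(cfg, cfg_path)
  invisible(list(data = data_path, config = cfg_path))
}
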