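# shared fixtures: small posteriors covering every covariance model, and
# independent quadrature oracles for the bivariate CDFs

make_gaussian_post <- function(structure, coupling, seed = 42, D = 2, M = 2) {
  set.seed(seed)
  pr <- gaussian_prior(
    D, M, structure, coupling,
    nu = seq(2, 3, length.out = M),
    m = matrix(seq(0, 1, length.out = D * M), D, M),
    kappa = if (structure == "known") NULL else
      if (coupling == "homoscedastic") D + 4 else seq(D + 4, D + 5, length.out = M),
    S = if (structure == "known") NULL else diag(0.9, D),
    Sigma = if (structure == "known") diag(0.5, D) else NULL
  )
  n_y <- rep(8L, M)
  X <- do.call(rbind, lapply(seq_len(M), function(j) {
    matrix(stats::rnorm(n_y[j] * D, mean = j - 1), n_y[j], D)
  }))
  y <- rep(seq_len(M) - 1L, n_y)
  update_gaussian(pr, X, y)
}

all_model_posts <- function(seed = 42) {
  list(
    known     = make_gaussian_post("known", "independent", seed),
    arb_ind   = make_gaussian_post("arbitrary", "independent", seed),
    arb_homo  = make_gaussian_post("arbitrary", "homoscedastic", seed),
    sid_ind   = make_gaussian_post("scaled_identity", "independent", seed),
    sid_homo  = make_gaussian_post("scaled_identity", "homoscedastic", seed)
  )
}

# brute-force 2-D quadrature oracles (independent of the package's
# single-integral / mixing-integral implementations): iterated adaptive
# integration of the bivariate density
quad2 <- function(f, x, y, lo) {
  outer_f <- function(us) {
    vapply(us, function(u) {
      stats::integrate(function(v) f(u, v), lo, y, rel.tol = 1e-10,
                       abs.tol = 1e-13)$value
    }, numeric(1L))
  }
  stats::integrate(outer_f, lo, x, rel.tol = 1e-9, abs.tol = 1e-12)$value
}

oracle_bvn <- function(x, y, rho) {
  quad2(function(u, v) {
    exp(-(u^2 - 2 * rho * u * v + v^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  }, x, y, lo = -10)
}

dbvt_std <- function(u, v, rho, d) {
  det <- 1 - rho^2
  q <- (u^2 - 2 * rho * u * v + v^2) / det
  gamma((d + 2) / 2) / (gamma(d / 2) * d * pi * sqrt(det)) * (1 + q / d)^(-(d + 2) / 2)
}

oracle_bvt <- function(x, y, rho, d) {
  quad2(function(u, v) dbvt_std(u, v, rho, d), x, y, lo = -200)
}

# discrete-histogram training rule used in resampling tests: per-bin
# majority class, ties to class 0
histogram_rule <- function(b, M, loss = NULL) {
  function(X, y) {
    counts <- discrete_counts(X[, 1L], y, b, M)
    p <- apply(counts, 2L, function(cl) (cl + 1e-12) / sum(cl + 1e-12))
    bdr_classifier(rep(1 / M, M), list(type = "discrete", p = p), loss)
  }
}
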