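test_that("true risk: closed forms, degenerate cases and the MC bound", {
  # indistinguishable classes: risk 1/2 under zero-one loss for any classifier
  theta_eq <- list(type = "gaussian", mu = matrix(0, 1, 2),
                   Sigma = list(diag(1, 1), diag(1, 1)))
  psi <- linear_classifier(1, -0.3)
  r <- true_risk(psi, c(0.5, 0.5), theta_eq, method = "closed")
  expect_equal(as.numeric(r), 0.5)
  # discrete finite sum: p0=(0.9,0.1), p1=(0.2,0.8), c=(0.5,0.5) -> 0.15
  theta_d <- list(type = "discrete", p = cbind(c(0.9, 0.1), c(0.2, 0.8)))
  psi_d <- histogram_rule(2, 2)(matrix(c(1, 2), 2, 1), c(0L, 1L))
  r_d <- true_risk(psi_d, c(0.5, 0.5), theta_d)
  expect_equal(as.numeric(r_d), 0.15)
  # reported MC error bound: 1 / sqrt(4 n_test)
  theta_g <- list(type = "gaussian", mu = matrix(c(0, 1), 1, 2),
                  Sigma = list(diag(1, 1), diag(1, 1)))
  r_mc <- true_risk(psi, c(0.5, 0.5), theta_g, method = "mc",
                    n_test = 10000L, seed = 1)
  expect_equal(attr(r_mc, "mc_rms_bound"), 0.005)
  # closed and MC paths agree within the bound (3x slack)
  r_cl <- true_risk(psi, c(0.5, 0.5), theta_g, method = "closed")
  expect_lt(abs(as.numeric(r_mc) - as.numeric(r_cl)), 3 * 0.005)
  # eps columns are distributions
  expect_equal(colSums(attr(r_cl, "eps")), c(1, 1))
  expect_error(true_risk(bdr_classifier(c(0.5, 0.5), theta_g), c(0.5, 0.5),
                         theta_g, method = "closed"), "closed")
})

test_that("eps-hat closed forms match the printed special cases", {
  # discrete: alpha0* = (4, 2), bin-identity classifier
  post <- update_discrete(discrete_prior(matrix(1, 2, 2)),
                          cbind(c(3, 1), c(1, 3)))
  psi_d <- histogram_rule(2, 2)(matrix(c(1, 2), 2, 1), c(0L, 1L))
  e <- eps_hat(psi_d, post, "closed")
  expect_equal(e[1, 1], 2 / 3)
  expect_equal(colSums(e), c(1, 1))
  # Gaussian with zero margin at the location: eps-hat = 1/2
  p <- all_model_posts()$arb_homo
  a <- c(0, 1); b0 <- -p$m[2, 1]          # g(m*_0) = 0
  e2 <- eps_hat(linear_classifier(a, b0), p, "closed")
  expect_equal(e2[1, 1], 0.5)
  # known covariance, D=1: eps^{1,0} = Phi(g(m*) sqrt(nu*/(nu*+1)) / sd)
  prk <- gaussian_prior(1, 2, "known", nu = c(3, 3),
                        m = matrix(c(1, 0), 1, 2), Sigma = diag(1, 1))
  e3 <- eps_hat(linear_classifier(1, 0), prk, "closed")
  expect_equal(e3[2, 1], pnorm(sqrt(3 / 4)), tolerance = 1e-12)
  # MC oracle over posterior draws of mu: average Phi(mu)
  set.seed(2)
  mu_draws <- rnorm(2e5, mean = 1, sd = sqrt(1 / 3))
  expect_equal(e3[2, 1], mean(pnorm(mu_draws)), tolerance = 0.005)
})

test_that("closed-form eps-hat equals MC sampling for every Gaussian model", {
  posts <- all_model_posts()
  psi <- linear_classifier(c(0.8, -0.6), 0.1)
  for (nm in names(posts)) {
    e_cl <- eps_hat(psi, posts[[nm]], "closed")
    e_mc <- eps_hat(psi, posts[[nm]], "mc", n_mc = 2e5, seed = 3)
    expect_lt(max(abs(e_cl - e_mc)), 0.005)
    expect_equal(colSums(e_cl), c(1, 1), tolerance = 1e-12)
  }
})

test_that("the BRE assembles eps-hat and class-probability means", {
  # engineered eps-hat: eps^{1,0} = 0.2, eps^{0,1} = 0.3 -> BRE = 0.25
  post <- update_discrete(discrete_prior(matrix(0, 2, 2) + 1e-9),
                          cbind(c(8, 2), c(3, 7)))
  cpost <- class_prior("known", c = c(0.5, 0.5))
  psi_d <- histogram_rule(2, 2)(matrix(c(1, 2), 2, 1), c(0L, 1L))
  r <- bre(psi_d, post, cpost)
  expect_equal(r$bre, 0.25, tolerance = 1e-8)
  # zero-one loss reduces to 1 - sum_y f(y|S) eps^{y,y}
  expect_equal(r$bre, 1 - sum(c(0.5, 0.5) * diag(r$eps_hat)), tolerance = 1e-12)
  # all-zero loss gives zero risk
  r0 <- bre(psi_d, post, cpost, loss = matrix(0, 2, 2))
  expect_equal(r0$bre, 0)
  # brute force: sample (C, Theta) from the posteriors and average Eq-style risk
  post2 <- update_discrete(discrete_prior(matrix(0, 2, 2) + 1e-9),
                           cbind(c(4, 2), c(2, 4)))
  cpost2 <- class_prior("random_sampling", alpha = c(4, 4))
  r2 <- bre(psi_d, post2, cpost2)
  set.seed(4)
  N <- 4e5
  C0 <- rbeta(N, 4, 4); P0 <- rbeta(N, 4, 2); P1 <- rbeta(N, 2, 4)
  risks <- C0 * (1 - P0) + (1 - C0) * P1
  expect_equal(r2$bre, mean(risks), tolerance = 0.003)
})

test_that("resampling risk estimators behave on engineered cases", {
  set.seed(5)
  X <- matrix(c(rep(1, 4), rep(2, 4)), 8, 1); y <- rep(0:1, each = 4)
  rule <- histogram_rule(2, 2)
  # all-zero loss: every estimate is 0
  for (m in c("cv", "loo", "boot632")) {
    expect_equal(as.numeric(classical_risk_estimate(X, y, rule,
                                                    loss = matrix(0, 2, 2),
                                                    method = m, seed = 1)), 0)
  }
  # LOO on bin-separable data: every surrogate classifies its point right
  expect_equal(as.numeric(classical_risk_estimate(X, y, rule, method = "loo")), 0)
  # 0.632 weights: a rule that predicts 0 exactly on its training bins has
  # resubstitution risk 0 and out-of-bag risk 1 on all-zero labels, so the
  # estimate is exactly 0.632 * 1 + 0.368 * 0
  memorizer <- function(X, y) {
    seen <- tabulate(X[, 1L], nbins = 12) > 0
    p <- cbind(seen / sum(seen), (!seen) / max(sum(!seen), 1))
    bdr_classifier(c(0.5, 0.5), list(type = "discrete", p = p))
  }
  Xu <- matrix(seq_len(12), 12, 1); yu <- rep(0L, 12)
  b <- classical_risk_estimate(Xu, yu, memorizer, loss = zero_one_loss(2),
                               method = "boot632", B = 30, seed = 2)
  expect_equal(as.numeric(b), 0.632)
  # surrogate failures are thrown out and counted
  set.seed(6)
  # leave-one-out on a 2-point class: those surrogates fail and are skipped
  Xf <- matrix(rnorm(6), 6, 1); yf <- c(0L, 0L, 0L, 0L, 1L, 1L)
  qda_rule <- function(X, y) plugin_qda(X, y, M = 2L)
  est <- classical_risk_estimate(Xf, yf, qda_rule, method = "loo")
  expect_gt(attr(est, "n_failed"), 0)
  expect_true(is.finite(est))
})

test_that("CV is reproducible and near the true risk on easy data", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 4), 20, 2))
  y <- rep(0:1, each = 20)
  lda_rule <- function(X, y) plugin_lda(X, y, M = 2L)
  v1 <- classical_risk_estimate(X, y, lda_rule, method = "cv", seed = 11)
  v2 <- classical_risk_estimate(X, y, lda_rule, method = "cv", seed = 11)
  expect_identical(v1, v2)
  expect_lt(as.numeric(v1), 0.1)   # classes are ~4 sd apart
})

test_that("the BRE is unbiased within the model and converges to the risk", {
  spec <- preset_model(1)
  cpost <- class_prior("known", c = spec$c)
  psi <- linear_classifier(c(1, 1), -0.5)
  set.seed(8)
  gaps <- replicate(400, {
    dist <- sample_model(spec)
    tr <- sample_stratified(dist$theta, 20)
    post <- update_gaussian(spec$prior, tr$X, tr$y)
    b <- bre(psi, post, cpost, spec$loss, method = "closed")$bre
    r <- as.numeric(true_risk(psi, dist$c, dist$theta, spec$loss, "closed"))
    b - r
  })
  expect_lt(abs(mean(gaps)), 3 * sd(gaps) / sqrt(length(gaps)))
  # consistency: |BRE - true risk| shrinks with n on a fixed distribution
  med_gap <- function(n) {
    median(replicate(50, {
      dist <- sample_model(spec)
      tr <- sample_stratified(dist$theta, n)
      post <- update_gaussian(spec$prior, tr$X, tr$y)
      abs(bre(psi, post, cpost, spec$loss, method = "closed")$bre -
            as.numeric(true_risk(psi, dist$c, dist$theta, spec$loss, "closed")))
    }))
  }
  set.seed(9)
  gaps_n <- vapply(c(10, 50, 250), med_gap, numeric(1))
  expect_true(all(diff(gaps_n) < 0))
})
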