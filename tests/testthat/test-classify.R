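test_that("Bayes decision rule thresholds and ties follow the conventions", {
  # 1-D Gaussians N(0,1), N(1,1), equal priors, zero-one loss: threshold 0.5
  theta <- list(type = "gaussian", mu = matrix(c(0, 1), 1, 2),
                Sigma = list(diag(1, 1), diag(1, 1)))
  psi <- bdr_classifier(c(0.5, 0.5), theta)
  expect_equal(predict(psi, matrix(c(0.49, 0.51, -3, 3), 4, 1)), c(0L, 1L, 0L, 1L))
  # exact tie in conditional risk: lowest index wins
  theta_tie <- list(type = "gaussian", mu = matrix(0, 1, 2),
                    Sigma = list(diag(1, 1), diag(1, 1)))
  psi_tie <- bdr_classifier(c(0.5, 0.5), theta_tie)
  expect_equal(predict(psi_tie, matrix(c(-1, 0, 2), 3, 1)), c(0L, 0L, 0L))
  # class-0 density larger at x under equal priors: predict 0
  expect_equal(predict(psi, matrix(-0.2, 1, 1)), 0L)
})

test_that("linear classifier predicts the sign convention", {
  psi <- linear_classifier(c(1, -1), 0.5)
  expect_equal(predict(psi, rbind(c(0, 1), c(1, 0))), c(0L, 1L))
  expect_equal(predict(psi, rbind(c(0, 0.5))), 0L)  # boundary -> class 0
  expect_error(linear_classifier(c(0, 0), 1), "all-zero")
})

test_that("posterior class probabilities follow Bayes' rule", {
  post <- update_discrete(discrete_prior(matrix(0, 2, 2) + 1e-9),
                          cbind(c(7, 3), c(3, 7)))
  cpost <- class_prior("known", c = c(0.5, 0.5))
  expect_equal(posterior_class_prob(1, post, cpost), c(0.7, 0.3), tolerance = 1e-7)
  # degenerate class prior passes through
  cp0 <- class_prior("known", c = c(1, 0))
  expect_equal(posterior_class_prob(1, post, cp0), c(1, 0))
  # equal densities, equal prior: (0.5, 0.5)
  post_eq <- update_discrete(discrete_prior(matrix(1, 2, 2)),
                             cbind(c(2, 2), c(2, 2)))
  expect_equal(posterior_class_prob(1, post_eq, cpost), c(0.5, 0.5))
  # brute-force Bayes arithmetic on the discrete model
  p0 <- effective_density(post, 0)$prob[2]
  p1 <- effective_density(post, 1)$prob[2]
  expect_equal(posterior_class_prob(2, post, cpost),
               c(p0, p1) / (p0 + p1), tolerance = 1e-9)
})

test_that("BCRE combines posterior probabilities with the loss", {
  post <- update_discrete(discrete_prior(matrix(0, 2, 2) + 1e-9),
                          cbind(c(7, 3), c(3, 7)))
  cpost <- class_prior("known", c = c(0.5, 0.5))
  lam <- loss_matrix(rbind(c(0, 2), c(1, 0)))
  # f(y | x=1, S) = (0.7, 0.3): Rhat = (0.6, 0.7)
  expect_equal(bcre(1, post, cpost, lam), c(0.6, 0.7), tolerance = 1e-7)
  # zero-one loss: 1 - f(i | x, S)
  expect_equal(bcre(1, post, cpost), c(0.3, 0.7), tolerance = 1e-7)
  # M = 5 uniform posterior class probs, zero-one: all 0.8
  post5 <- update_discrete(discrete_prior(matrix(1, 2, 5)), matrix(0L, 2, 5))
  cp5 <- class_prior("known", c = rep(0.2, 5))
  expect_equal(bcre(1, post5, cp5), rep(0.8, 5))
})

test_that("OBRC is the argmin of the BCRE and ties go to the lowest index", {
  posts <- all_model_posts()
  cpost <- class_prior("known", c = c(0.5, 0.5))
  lam <- loss_matrix(rbind(c(0, 2), c(1, 0)))
  for (p in posts[c("known", "arb_ind", "sid_homo")]) {
    psi <- obrc_classifier(p, cpost, lam)
    set.seed(31)
    X <- matrix(rnorm(40), 20, 2)
    pred <- predict(psi, X)
    byhand <- apply(X, 1, function(x) which.min(bcre(x, p, cpost, lam)) - 1L)
    expect_equal(pred, byhand)
  }
  # identical classes: everything ties, lowest index everywhere
  pr_eq <- gaussian_prior(2, 2, "known", nu = c(2, 2), m = matrix(0, 2, 2),
                          Sigma = diag(1, 2))
  psi_eq <- obrc_classifier(pr_eq, cpost)
  expect_true(all(predict(psi_eq, matrix(rnorm(20), 10, 2)) == 0L))
})

test_that("equal-precision homoscedastic OBRC has a linear boundary", {
  pr <- gaussian_prior(2, 2, "arbitrary", "homoscedastic", nu = c(3, 3),
                       m = cbind(c(0, 0), c(1, 0.5)), kappa = 8,
                       S = matrix(c(1, 0.3, 0.3, 0.8), 2))
  cpost <- class_prior("known", c = c(0.5, 0.5))
  psi <- obrc_classifier(pr, cpost)
  # equal nu*: the t-density ratio reduces to equal Mahalanobis distances,
  # i.e. the hyperplane a'x + b = 0 with a = S^{-1}(m1 - m0)
  A <- solve(pr$S)
  a <- 2 * A %*% (pr$m[, 2] - pr$m[, 1])
  b <- drop(t(pr$m[, 1]) %*% A %*% pr$m[, 1] - t(pr$m[, 2]) %*% A %*% pr$m[, 2])
  lin <- linear_classifier(a, b)   # predict 1 when q0 - q1 > 0
  set.seed(32)
  X <- matrix(rnorm(400, sd = 2), 200, 2)
  expect_equal(predict(psi, X), predict(lin, X))
})

test_that("OBRC minimizes the BRE over random competitor classifiers", {
  p <- all_model_posts()$arb_ind
  cpost <- class_prior("random_sampling", alpha = c(3, 5))
  lam <- loss_matrix(rbind(c(0, 2), c(1, 0)))
  psi <- obrc_classifier(p, cpost, lam)
  bre_obrc <- bre(psi, p, cpost, lam, method = "mc", n_mc = 4e4, seed = 5)$bre
  set.seed(33)
  for (r in 1:60) {
    cand <- linear_classifier(rnorm(2), rnorm(1))
    expect_lte(bre_obrc,
               bre(cand, p, cpost, lam, method = "closed")$bre + 0.012)
  }
  for (r in 1:5) {  # random plug-in competitors (nonlinear): MC BRE
    Xr <- matrix(rnorm(24, sd = 1.5), 12, 2); yr <- rep(0:1, 6)
    cand <- plugin_qda(Xr, yr, lam)
    expect_lte(bre_obrc,
               bre(cand, p, cpost, lam, method = "mc", n_mc = 2e4, seed = r)$bre + 0.03)
  }
})

test_that("averaging the BCRE over the marginal reproduces the BRE", {
  p <- all_model_posts()$arb_homo
  cpost <- class_prior("known", c = c(0.4, 0.6))
  lam <- loss_matrix(rbind(c(0, 2), c(1, 0)))
  psi <- linear_classifier(c(1, 0.5), -0.4)
  closed <- bre(psi, p, cpost, lam, method = "closed")$bre
  # sample the marginal f(x | S) as a mixture of effective densities
  set.seed(34)
  N <- 2e4
  y <- sample(0:1, N, TRUE, prob = c(0.4, 0.6))
  X <- matrix(0, N, 2)
  for (cls in 0:1) {
    idx <- y == cls
    X[idx, ] <- sample_effective(effective_density(p, cls), sum(idx))
  }
  pred <- predict(psi, X)
  vals <- vapply(seq_len(N), function(r) {
    bcre(X[r, ], p, cpost, lam)[pred[r] + 1L]
  }, numeric(1))
  expect_equal(mean(vals), closed, tolerance = 0.02)
})

test_that("OBRC predictions are invariant to invertible affine maps", {
  p <- all_model_posts()$arb_ind
  cpost <- class_prior("known", c = c(0.5, 0.5))
  psi <- obrc_classifier(p, cpost)
  set.seed(35)
  A <- matrix(c(2, 0.5, -0.3, 1.2), 2); b <- c(1, -2)
  # transform posterior hyperparameters along with the data
  p2 <- p
  p2$m <- apply(p$m, 2, function(mm) A %*% mm + b)
  p2$S <- lapply(p$S, function(S) A %*% S %*% t(A))
  psi2 <- obrc_classifier(p2, cpost)
  X <- matrix(rnorm(60), 30, 2)
  X2 <- t(A %*% t(X) + b)
  expect_equal(predict(psi, X), predict(psi2, X2))
})

test_that("plug-in LDA/QDA reproduce the Bayes-rule functional form", {
  # 1-D equal sample variances: LDA threshold at the midpoint of the means
  X <- matrix(c(-1, 0, 1, 4, 5, 6), 6, 1); y <- rep(0:1, each = 3)
  psi <- plugin_lda(X, y)
  expect_equal(predict(psi, matrix(c(2.49, 2.51), 2, 1)), c(0L, 1L))
  # QDA with identical per-class estimates predicts identically to LDA
  Xq <- rbind(X, X + 10); yq <- c(y, y)  # same within-class covariances
  Xs <- matrix(c(-1, 0, 1, 0, 1, 2), 6, 1); ys <- rep(0:1, each = 3)
  expect_equal(predict(plugin_qda(Xs, ys), matrix(seq(-2, 3, 0.25))),
               predict(plugin_lda(Xs, ys), matrix(seq(-2, 3, 0.25))))
  # 2-D: predictions match a brute-force plug-in of the decision rule
  set.seed(36)
  X2 <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 1.5), 20, 2))
  y2 <- rep(0:1, each = 20)
  lam <- loss_matrix(rbind(c(0, 2), c(1, 0)))
  psi2 <- plugin_qda(X2, y2, lam)
  mu <- sapply(0:1, function(cl) colMeans(X2[y2 == cl, ]))
  Sg <- lapply(0:1, function(cl) cov(X2[y2 == cl, ]))
  test_pts <- matrix(rnorm(60, 0.75), 30, 2)
  byhand <- apply(test_pts, 1, function(x) {
    f <- sapply(1:2, function(j) {
      mvd <- x - mu[, j]
      exp(-0.5 * drop(t(mvd) %*% solve(Sg[[j]]) %*% mvd)) /
        (2 * pi * sqrt(det(Sg[[j]])))
    })
    risks <- unclass(lam) %*% (0.5 * f)
    which.min(risks) - 1L
  })
  expect_equal(predict(psi2, test_pts), as.integer(byhand))
  # failure modes are reported as errors
  expect_error(plugin_qda(matrix(1:2, 2, 1), 0:1), "insufficient")
  expect_error(plugin_qda(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 2)),
                          c(0, 0, 1, 1)), "singular")
})
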