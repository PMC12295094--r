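test_that("scalar posterior matches hand arithmetic", {
  # psi = x, X = (1,2), y = (1,2), eta = lambda = 1, mu = 0:
  # precision = 1 + 5 = 6, C = 1/6, m = (1/6) * 5 = 5/6
  post <- compute_posterior_ggwp(hyperparameters(1, 1, 0), scalar_data())
  expect_equal(drop(post$C), 1 / 6, tolerance = 1e-12)
  expect_equal(post$m, 5 / 6, tolerance = 1e-12)
  expect_false(post$used_pseudo_inverse)
})

test_that("posterior mean approaches the prior mean as eta grows", {
  inst <- random_instance(10, n = 15, M = 4)
  hp <- hyperparameters(rep(1e12, 4), inst$hp$lambda, inst$hp$mu)
  post <- compute_posterior_ggwp(hp, inst$data)
  expect_lt(max(abs(post$m - hp$mu)), 1e-6 * (1 + max(abs(hp$mu))))
})

test_that("posterior mean approaches OLS as eta vanishes", {
  inst <- random_instance(11, n = 20, M = 4)
  hp <- hyperparameters(rep(1e-12, 4), inst$hp$lambda, inst$hp$mu)
  post <- compute_posterior_ggwp(hp, inst$data)
  ols <- qr.solve(inst$data$Psi, inst$data$y)   # independent QR solve
  expect_lt(max(abs(post$m - ols)) / max(abs(ols)), 1e-6)
})

test_that("diagonal conjugate prior reproduces the per-weight posterior", {
  worst <- 0
  for (s in 1:100) {
    inst <- random_instance(1000 + s, n = 10, M = 3)
    p_ggwp <- compute_posterior_ggwp(inst$hp, inst$data)
    prior <- conjugate_prior(inst$hp$mu, diag(1 / inst$hp$eta))
    p_gen <- compute_posterior_general(prior, inst$hp$lambda, inst$data)
    worst <- max(worst, max(abs(p_ggwp$m - p_gen$m)),
                 max(abs(p_ggwp$C - p_gen$C)))
  }
  expect_lt(worst, 1e-8)
})

test_that("no-data limit returns the prior", {
  inst <- random_instance(12, n = 8, M = 3)
  C0 <- crossprod(matrix(rnorm(9), 3)) + diag(3)
  m0 <- rnorm(3)
  post <- compute_posterior_general(conjugate_prior(m0, C0), 1e-15, inst$data)
  expect_equal(post$m, m0, tolerance = 1e-6)
  expect_equal(post$C, C0, tolerance = 1e-6)
})

test_that("general posterior agrees with a numerical-optimisation oracle", {
  # mode and curvature of the log joint found by BFGS + numerical Hessian,
  # never touching the closed-form update
  inst <- random_instance(13, n = 5, M = 3)
  C0 <- crossprod(matrix(rnorm(9, sd = 0.7), 3)) + diag(3)
  m0 <- rnorm(3)
  lam <- 1.7
  post <- compute_posterior_general(conjugate_prior(m0, C0), lam, inst$data)
  negloj <- function(w) {
    -(sum(dnorm(inst$data$y, drop(inst$data$Psi %*% w), 1 / sqrt(lam),
                log = TRUE)) +
        mvtnorm_logd(w, m0, C0))
  }
  mvtnorm_logd <- function(w, m, S) {
    R <- chol(S)
    z <- backsolve(R, w - m, transpose = TRUE)
    -0.5 * sum(z^2) - sum(log(diag(R))) - length(w) / 2 * log(2 * pi)
  }
  opt <- optim(m0, negloj, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-14))
  expect_equal(post$m, opt$par, tolerance = 1e-5)
  expect_equal(post$C, solve(opt$hessian), tolerance = 1e-4)
})

test_that("posterior mean interpolates monotonically between prior and OLS", {
  d <- scalar_data(c(1, 2, 3), c(2.5, 4.1, 6.3))
  ols <- qr.solve(d$Psi, d$y)
  mu0 <- 0
  etas <- 10^seq(-6, 6, length.out = 25)
  means <- vapply(etas, function(e) {
    compute_posterior_ggwp(hyperparameters(e, 1, mu0), d)$m
  }, 0)
  # shrinks from OLS toward mu as eta grows, monotonically
  expect_true(all(diff(means) < 1e-12))
  expect_equal(means[1], ols, tolerance = 1e-4)
  expect_equal(means[25], mu0, tolerance = 1e-4)
})

test_that("near-singular precision takes the flagged pseudo-inverse path", {
  # duplicated RBF centers give rank-deficient Psi'Psi; a huge precision
  # spread then drives rcond below the threshold
  X <- matrix(seq(-1, 1, length.out = 10))
  cfg <- basis_config("gaussian_rbf", include_bias = FALSE,
                      centers = c(0, 0), width = 0.5)
  d <- regression_data(X, rnorm(10), basis = cfg)
  post <- compute_posterior_ggwp(hyperparameters(c(1e13, 1e-10), 1e-2, c(0, 0)), d)
  expect_true(post$used_pseudo_inverse)
  expect_lt(post$rcond, 1e-12)
  expect_equal(post$C, t(post$C))
})

test_that("dimension mismatches and singular priors are contract errors", {
  d <- scalar_data()
  expect_error(compute_posterior_ggwp(hyperparameters(c(1, 1), 1, c(0, 0)), d),
               "mismatch")
  expect_error(conjugate_prior(c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "positive-definite")
})

test_that("predictive moments match a Monte Carlo sampling oracle", {
  inst <- random_instance(14, n = 25, M = 3)
  post <- compute_posterior_ggwp(inst$hp, inst$data)
  lam <- inst$hp$lambda
  cfg <- basis_config("identity", include_bias = FALSE)
  x_star <- c(0.4, -1.1, 0.8)
  p <- predictive_distribution(x_star, post, lam, cfg)
  set.seed(99)
  n_draw <- 1e5
  Rc <- chol(post$C)
  W <- matrix(rnorm(n_draw * 3), n_draw) %*% Rc +
    matrix(post$m, n_draw, 3, byrow = TRUE)
  tt <- rnorm(n_draw, drop(W %*% x_star), 1 / sqrt(lam))
  se_mean <- sd(tt) / sqrt(n_draw)
  expect_lt(abs(mean(tt) - p$mean), 5 * se_mean)
  expect_lt(abs(var(tt) - p$variance) / p$variance, 5 * sqrt(2 / n_draw))
})

test_that("predictive degenerates gracefully", {
  d <- scalar_data()
  post <- compute_posterior_ggwp(hyperparameters(1, 1, 0), d)
  cfg <- basis_config("identity", include_bias = FALSE)
  # zero covariance: variance is exactly the noise floor 1/lambda
  post0 <- post
  post0$C <- matrix(0)
  expect_equal(predictive_distribution(2, post0, 4, cfg)$variance, 0.25)
  # zero posterior mean predicts zero everywhere
  postm <- post
  postm$m <- 0
  expect_equal(predictive_distribution(17.3, postm, 1, cfg)$mean, 0)
})
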