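# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the code paths they check: quadrature for the
# evidence, QR least squares for the posterior mean, numerical optimisation
# for the general conjugate posterior, Monte Carlo for the predictive.

# A small scalar-input regression problem with an identity basis (no bias),
# so M = 1 and everything is checkable by hand.
scalar_data <- function(x = c(1, 2), y = c(1, 2)) {
  regression_data(matrix(x), y,
                  basis = basis_config("identity", include_bias = FALSE))
}

# Random small instance with a raw-column basis of rank M.
random_instance <- function(seed, n = 12, M = 3, with_bias = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * (M - with_bias)), n)
  cfg <- basis_config("identity", include_bias = with_bias)
  y <- rnorm(n)
  data <- regression_data(X, y, basis = cfg)
  hp <- hyperparameters(eta = exp(runif(M, -2, 2)),
                        lambda = exp(runif(1, -1, 1)),
                        mu = rnorm(M))
  list(data = data, hp = hp)
}

# Log evidence by adaptive quadrature over the single weight (M = 1).
log_evidence_quad_1d <- function(hp, data) {
  psi <- data$Psi[, 1]
  loginteg <- function(w) {
    sum(dnorm(data$y, psi * w, 1 / sqrt(hp$lambda), log = TRUE)) +
      dnorm(w, hp$mu, 1 / sqrt(hp$eta), log = TRUE)
  }
  # centre the integration window at the mode, located independently
  opt <- optimize(loginteg, c(-1e3, 1e3), maximum = TRUE, tol = 1e-12)
  shift <- opt$objective
  val <- integrate(function(w) exp(vapply(w, loginteg, 0) - shift),
                   opt$maximum - 60, opt$maximum + 60,
                   rel.tol = 1e-11, abs.tol = 0)
  log(val$value) + shift
}

# Log evidence by tensor-grid Gauss-Legendre quadrature over two weights.
log_evidence_quad_2d <- function(hp, data, n_nodes = 90, half_width = 10) {
  loginteg <- function(w) {
    mu_y <- drop(data$Psi %*% w)
    sum(dnorm(data$y, mu_y, 1 / sqrt(hp$lambda), log = TRUE)) +
      sum(dnorm(w, hp$mu, 1 / sqrt(hp$eta), log = TRUE))
  }
  # locate the mode and curvature numerically, independent of the
  # closed-form posterior
  opt <- optim(hp$mu, function(w) -loginteg(w), method = "BFGS",
               hessian = TRUE, control = list(reltol = 1e-14))
  sds <- sqrt(diag(solve(opt$hessian)))
  gl1 <- pracma::gaussLegendre(n_nodes, opt$par[1] - half_width * sds[1],
                               opt$par[1] + half_width * sds[1])
  gl2 <- pracma::gaussLegendre(n_nodes, opt$par[2] - half_width * sds[2],
                               opt$par[2] + half_width * sds[2])
  shift <- loginteg(opt$par)
  vals <- outer(seq_len(n_nodes), seq_len(n_nodes), Vectorize(function(i, j) {
    exp(loginteg(c(gl1$x[i], gl2$x[j])) - shift)
  }))
  log(drop(gl1$w %*% vals %*% gl2$w)) + shift
}

# Central finite difference of the log evidence in one hyperparameter.
evidence_fd <- function(hp, data, what = c("mu", "lambda"), index = 1L,
                        h_scale = 1e-5) {
  what <- match.arg(what)
  f <- function(hp2) log_marginal_likelihood(hp2, data)$log_value
  if (what == "mu") {
    h <- h_scale * (1 + abs(hp$mu[index]))
    hp_p <- hp; hp_p$mu[index] <- hp$mu[index] + h
    hp_m <- hp; hp_m$mu[index] <- hp$mu[index] - h
  } else {
    h <- h_scale * (1 + hp$lambda)
    hp_p <- hp; hp_p$lambda <- hp$lambda + h
    hp_m <- hp; hp_m$lambda <- hp$lambda - h
  }
  (f(hp_p) - f(hp_m)) / (2 * h)
}

# Scratch files under the session tempdir.
tmp_file <- function(name) file.path(tempdir(), name)
tmp_dir <- function() tempdir()
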