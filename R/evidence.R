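#' Quadratic energy of the evidence exponent
#'
#' The exponent of the marginal likelihood evaluated at the posterior
#' mean:
#' \deqn{G(m) = \frac{\lambda}{2}\|y - \Psi m\|^2 +
#'   \frac{1}{2}(m - \mu)^T \Lambda (m - \mu).}
#' Both terms are non-negative, so \eqn{G(m) \ge 0}.
#'
#' @param m Length-`M` vector (typically the posterior mean).
#' @param hp A [hyperparameters()] object.
#' @param data A [regression_data()].
#' @return Non-negative scalar.
#' @export
energy_G <- function(m, hp, data) {
  stopifnot(inherits(hp, "hyperparameters"), inherits(data, "regression_data"))
  m <- as.numeric(m)
  if (length(m) != ncol(data$Psi) || length(m) != length(hp$eta)) {
    stop_contract("dimension mismatch between `m`, design matrix and `hp`")
  }
  r <- data$y - drop(data$Psi %*% m)
  hp$lambda / 2 * sum(r^2) + 0.5 * sum(hp$eta * (m - hp$mu)^2)
}

#' Log marginal likelihood (log evidence)
#'
#' The objective of the whole method: the log of the marginal likelihood
#' of the targets with the weights integrated out,
#' \deqn{\ln p(y \mid X, \eta, \lambda, \mu) = \frac{N}{2}\ln\lambda
#'   - G(m) + \frac{1}{2}\sum_i \ln\eta_i + \frac{1}{2}\ln|C|
#'   - \frac{N}{2}\ln 2\pi,}
#' with \eqn{(m, C)} the posterior moments from
#' [compute_posterior_ggwp()].  All computation is carried out in log
#' space; \eqn{\ln|C|} is the negated log-determinant of the posterior
#' precision, obtained from its Cholesky factor (or, on the
#' pseudo-inverse path, from a floored symmetric eigendecomposition).
#'
#' @param hp A [hyperparameters()] object.
#' @param data A [regression_data()].
#' @param posterior Optional precomputed posterior for `hp` (saves the
#'   solve when the caller already has it).
#' @return Object of class `evidence_value` with fields `log_value`,
#'   `g_of_m`, `logdet_C`, `logdet_Lambda` and the propagated
#'   `used_pseudo_inverse` flag (set when the near-singular fallback was
#'   taken, in which case the value is only approximate).
#' @export
log_marginal_likelihood <- function(hp, data, posterior = NULL) {
  stopifnot(inherits(hp, "hyperparameters"), inherits(data, "regression_data"))
  if (is.null(posterior)) posterior <- compute_posterior_ggwp(hp, data)
  N <- length(data$y)
  G <- energy_G(posterior$m, hp, data)
  logdet_Lambda <- sum(log(hp$eta))
  log_value <- N / 2 * log(hp$lambda) - G + 0.5 * logdet_Lambda +
    0.5 * posterior$logdet_C - N / 2 * log(2 * pi)
  structure(
    list(log_value = log_value, g_of_m = G, logdet_C = posterior$logdet_C,
         logdet_Lambda = logdet_Lambda,
         used_pseudo_inverse = posterior$used_pseudo_inverse),
    class = "evidence_value"
  )
}

#' Marginal likelihood in product (non-log) form
#'
#' Direct evaluation of
#' \deqn{p(y \mid X, \eta, \lambda, \mu) = \left(\frac{\lambda}{2\pi}
#'   \right)^{N/2} |\Lambda|^{1/2} |C|^{1/2} e^{-G(m)},}
#' using plain determinants.  Overflows/underflows for all but small
#' problems; it exists as the direct counterpart of the log-space
#' computation for cross-checking, not for routine use.
#'
#' @inheritParams log_marginal_likelihood
#' @return Positive scalar (may underflow to 0 for large `N`).
#' @export
marginal_likelihood <- function(hp, data) {
  stopifnot(inherits(hp, "hyperparameters"), inherits(data, "regression_data"))
  posterior <- compute_posterior_ggwp(hp, data)
  N <- length(data$y)
  G <- energy_G(posterior$m, hp, data)
  (hp$lambda / (2 * pi))^(N / 2) * sqrt(prod(hp$eta)) *
    sqrt(det(posterior$C)) * exp(-G)
}

# Lean log-evidence evaluation used by the optimisation loops (PSO in
# particular calls this hundreds of thousands of times).  Works entirely
# from the precomputed Gram quantities, so cost is O(M^3) per call with no
# dependence on N; skips the condition estimate and falls straight back to
# the eigendecomposition pseudo-inverse when Cholesky fails.
log_evidence_core <- function(eta, lambda, mu, data) {
  P <- lambda * data$PtP
  diag(P) <- diag(P) + eta
  b <- eta * mu + lambda * data$Pty
  R <- tryCatch(chol(P), error = function(e) NULL)
  if (!is.null(R)) {
    m <- backsolve(R, backsolve(R, b, transpose = TRUE))
    logdet_C <- -2 * sum(log(diag(R)))
  } else {
    ee <- eigen(symmetrize(P), symmetric = TRUE)
    ev <- pmax(ee$values, 1e-300)
    m <- drop(ee$vectors %*% ((crossprod(ee$vectors, b)) / ev))
    logdet_C <- -sum(log(ev))
  }
  rss <- data$yty - 2 * sum(m * data$Pty) + sum(m * (data$PtP %*% m))
  rss <- max(rss, 0)
  G <- lambda / 2 * rss + 0.5 * sum(eta * (m - mu)^2)
  N <- length(data$y)
  N / 2 * log(lambda) - G + 0.5 * sum(log(eta)) + 0.5 * logdet_C -
    N / 2 * log(2 * pi)
}

#' @export
print.evidence_value <- function(x, ...) {
  cat(sprintf("<evidence_value> log evidence = %.6f (G(m) = %.6g)%s\n",
              x$log_value, x$g_of_m,
              if (isTRUE(x$used_pseudo_inverse)) " [pseudo-inverse]" else ""))
  invisible(x)
}
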