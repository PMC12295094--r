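#' Hyperparameters of the general Gaussian weight prior
#'
#' The model places an independent Gaussian prior on every weight,
#' \eqn{p(\omega \mid \eta, \mu) = \prod_i N(\omega_i \mid \mu_i,
#' \eta_i^{-1})}, and Gaussian observation noise with precision
#' \eqn{\lambda}.  This container holds the full hyperparameter vector
#' \eqn{(\eta, \lambda, \mu)} being optimised.  The classical zero-mean
#' relevance vector machine prior is the special case \eqn{\mu = 0}.
#'
#' @param eta Length-`M` vector of positive per-weight prior precisions.
#' @param lambda Positive noise precision (inverse noise variance).
#' @param mu Length-`M` vector of per-weight prior means.
#' @return Object of class `hyperparameters`.
#' @export
hyperparameters <- function(eta, lambda, mu) {
  eta <- as.numeric(eta)
  mu <- as.numeric(mu)
  lambda <- as.numeric(lambda)
  if (length(eta) != length(mu)) {
    stop_contract("`eta` and `mu` must have the same length")
  }
  if (length(eta) < 1L) stop_contract("need at least one weight (M >= 1)")
  if (!all(is.finite(eta)) || any(eta <= 0)) {
    stop_contract("all prior precisions `eta` must be finite and > 0")
  }
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0) {
    stop_contract("`lambda` must be a single finite positive number")
  }
  if (!all(is.finite(mu))) stop_contract("`mu` must be finite")
  structure(list(eta = eta, lambda = lambda, mu = mu),
            class = "hyperparameters")
}

#' Draw random initial hyperparameters
#'
#' Initialisation used both to start the EM loop and to draw the
#' ground-truth hyperparameters of the synthetic generator: each
#' \eqn{\eta_i} is log-uniform on \eqn{[10^{-3}, 10^{3}]}, \eqn{\lambda}
#' is log-uniform on \eqn{[10^{-2}, 10^{2}]}, and each \eqn{\mu_i} is
#' standard normal.
#'
#' @param M Number of weights (basis columns).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#'   `NULL` draws from the current RNG stream.
#' @return A [hyperparameters()] object.
#' @export
initialize_hyperparameters <- function(M, seed = NULL) {
  if (length(M) != 1L || M < 1 || M != round(M)) {
    stop_contract("`M` must be a positive integer")
  }
  with_seed(seed, function() {
    eta <- exp(stats::runif(M, log(1e-3), log(1e3)))
    lambda <- exp(stats::runif(1, log(1e-2), log(1e2)))
    mu <- stats::rnorm(M)
    hyperparameters(eta, lambda, mu)
  })
}

#' @export
print.hyperparameters <- function(x, ...) {
  M <- length(x$eta)
  cat(sprintf("<hyperparameters> M = %d\n", M))
  cat(sprintf("  lambda (noise precision): %.6g\n", x$lambda))
  cat("  eta: ", paste(signif(utils::head(x$eta, 6), 4), collapse = ", "),
      if (M > 6) ", ..." else "", "\n", sep = "")
  cat("  mu:  ", paste(signif(utils::head(x$mu, 6), 4), collapse = ", "),
      if (M > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}
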