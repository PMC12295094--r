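#' Weight posterior under the general Gaussian weight prior
#'
#' Computes the Gaussian posterior over the weights,
#' \deqn{m = (\Lambda + \lambda \Psi^T \Psi)^{-1} (\Lambda \mu + \lambda
#'   \Psi^T y), \qquad C = (\Lambda + \lambda \Psi^T \Psi)^{-1},}
#' where \eqn{\Lambda = \mathrm{diag}(\eta_i)}.  The precision matrix is
#' factorised by Cholesky; when its reciprocal condition estimate falls
#' below `rcond_threshold` (or the factorisation fails) the covariance is
#' obtained through the Moore--Penrose pseudo-inverse instead and the
#' `used_pseudo_inverse` flag is set, so callers (notably the EM loop) can
#' react to the near-singular regime.
#'
#' @param hp A [hyperparameters()] object with `M` entries.
#' @param data A [regression_data()] whose design matrix has `M` columns.
#' @param rcond_threshold Reciprocal-condition cutoff below which the
#'   pseudo-inverse path is taken.
#' @return Object of class `ggwp_posterior`: mean `m`, covariance `C`
#'   (explicitly symmetrised), `rcond`, `used_pseudo_inverse`, and the log
#'   determinant `logdet_C` of the covariance.
#' @export
compute_posterior_ggwp <- function(hp, data, rcond_threshold = 1e-12) {
  stopifnot(inherits(hp, "hyperparameters"), inherits(data, "regression_data"))
  M <- ncol(data$Psi)
  if (length(hp$eta) != M) {
    stop_contract(sprintf(
      "dimension mismatch: design matrix has %d columns, hyperparameters %d",
      M, length(hp$eta)))
  }
  P <- hp$lambda * data$PtP
  diag(P) <- diag(P) + hp$eta
  if (!all(is.finite(P))) {
    stop("posterior precision matrix has non-finite entries", call. = FALSE)
  }
  rc <- tryCatch(1 / kappa(P, exact = FALSE), error = function(e) 0)
  if (!is.finite(rc)) rc <- 0
  used_pinv <- FALSE
  C <- NULL
  logdet_C <- NA_real_
  if (rc >= rcond_threshold) {
    R <- tryCatch(chol(P), error = function(e) NULL)
    if (!is.null(R)) {
      C <- chol2inv(R)
      logdet_C <- -2 * sum(log(diag(R)))
    }
  }
  if (is.null(C)) {
    # near-singular precision: pseudo-inverse fallback, log-determinant from
    # the symmetric eigenvalues with a hard floor against log(0)
    used_pinv <- TRUE
    ee <- eigen(symmetrize(P), symmetric = TRUE)
    C <- MASS::ginv(P)
    logdet_C <- -sum(log(pmax(ee$values, 1e-300)))
  }
  C <- symmetrize(C)
  m <- drop(C %*% (hp$eta * hp$mu + hp$lambda * data$Pty))
  structure(
    list(m = m, C = C, rcond = rc, used_pseudo_inverse = used_pinv,
         logdet_C = logdet_C),
    class = "ggwp_posterior"
  )
}

#' General Gaussian conjugate prior
#'
#' A full-covariance Gaussian prior \eqn{N(m_0, C_0)} over the weights;
#' the per-weight prior is the diagonal special case
#' \eqn{C_0 = \Lambda^{-1}}, \eqn{m_0 = \mu}.
#'
#' @param m0 Prior mean vector.
#' @param C0 Symmetric positive-definite prior covariance.
#' @return Object of class `conjugate_prior`.
#' @export
conjugate_prior <- function(m0, C0) {
  m0 <- as.numeric(m0)
  C0 <- as.matrix(C0)
  if (nrow(C0) != ncol(C0) || nrow(C0) != length(m0)) {
    stop_contract("`C0` must be square with dimension matching `m0`")
  }
  if (max(abs(C0 - t(C0))) > 1e-8 * (1 + max(abs(C0)))) {
    stop_contract("`C0` must be symmetric")
  }
  if (inherits(tryCatch(chol(C0), error = function(e) e), "error")) {
    stop_contract("`C0` must be positive-definite")
  }
  structure(list(m0 = m0, C0 = C0), class = "conjugate_prior")
}

#' Weight posterior under a general Gaussian conjugate prior
#'
#' The textbook conjugate update for Gaussian-likelihood linear
#' regression:
#' \deqn{C_N^{-1} = C_0^{-1} + \lambda \Psi^T \Psi, \qquad
#'   m_N = C_N (C_0^{-1} m_0 + \lambda \Psi^T y).}
#'
#' @param prior A [conjugate_prior()].
#' @param lambda Positive noise precision.
#' @param data A [regression_data()].
#' @param rcond_threshold As in [compute_posterior_ggwp()].
#' @return A `ggwp_posterior` object.
#' @export
compute_posterior_general <- function(prior, lambda, data,
                                      rcond_threshold = 1e-12) {
  stopifnot(inherits(prior, "conjugate_prior"),
            inherits(data, "regression_data"))
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0) {
    stop_contract("`lambda` must be a single positive number")
  }
  M <- ncol(data$Psi)
  if (length(prior$m0) != M) {
    stop_contract("prior dimension does not match the design matrix")
  }
  R0 <- tryCatch(chol(prior$C0), error = function(e) NULL)
  if (is.null(R0)) stop_contract("prior covariance `C0` is singular")
  C0inv <- chol2inv(R0)
  P <- C0inv + lambda * data$PtP
  rc <- tryCatch(1 / kappa(P, exact = FALSE), error = function(e) 0)
  if (!is.finite(rc)) rc <- 0
  used_pinv <- FALSE
  if (rc >= rcond_threshold) {
    R <- tryCatch(chol(P), error = function(e) NULL)
  } else {
    R <- NULL
  }
  if (!is.null(R)) {
    C <- chol2inv(R)
    logdet_C <- -2 * sum(log(diag(R)))
  } else {
    used_pinv <- TRUE
    ee <- eigen(symmetrize(P), symmetric = TRUE)
    C <- MASS::ginv(P)
    logdet_C <- -sum(log(pmax(ee$values, 1e-300)))
  }
  C <- symmetrize(C)
  m <- drop(C %*% (drop(C0inv %*% prior$m0) + lambda * data$Pty))
  structure(
    list(m = m, C = C, rcond = rc, used_pseudo_inverse = used_pinv,
         logdet_C = logdet_C),
    class = "ggwp_posterior"
  )
}

#' Approximate predictive distribution at a new input
#'
#' Plugging the optimised hyperparameters into the weight posterior and
#' marginalising the weights gives a Gaussian predictive distribution with
#' \deqn{\mathrm{mean} = m^T \psi(x_*), \qquad
#'   \mathrm{variance} = 1/\lambda + \psi(x_*)^T C\, \psi(x_*).}
#' The variance is the standard Gaussian completion of the plug-in
#' predictive integral: observation noise plus weight uncertainty.
#'
#' @param x_star A single new input (length-`d` vector).
#' @param posterior A `ggwp_posterior`.
#' @param lambda Positive noise precision.
#' @param config The (resolved) [basis_config()] used for fitting.
#' @return List with elements `mean` and `variance`.
#' @export
predictive_distribution <- function(x_star, posterior, lambda, config) {
  stopifnot(inherits(posterior, "ggwp_posterior"))
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0) {
    stop_contract("`lambda` must be a single positive number")
  }
  psi <- drop(build_design_matrix(matrix(x_star, nrow = 1L), config))
  if (length(psi) != length(posterior$m)) {
    stop_contract("basis evaluation does not match the posterior dimension")
  }
  mean <- sum(posterior$m * psi)
  variance <- 1 / lambda + drop(psi %*% posterior$C %*% psi)
  if (!is.finite(variance) || variance <= 0) {
    stop("degenerate prediction: non-positive predictive variance ",
         "(pseudo-inverse covariance?)", call. = FALSE)
  }
  list(mean = mean, variance = variance)
}

#' @export
print.ggwp_posterior <- function(x, ...) {
  cat(sprintf("<ggwp_posterior> M = %d, rcond = %.3g%s\n",
              length(x$m), x$rcond,
              if (x$used_pseudo_inverse) " (pseudo-inverse)" else ""))
  cat("  m: ", paste(signif(utils::head(x$m, 6), 4), collapse = ", "),
      if (length(x$m) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}
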