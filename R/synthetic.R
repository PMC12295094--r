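#' Generate a synthetic dataset from the model's own generative process
#'
#' Draws a dataset with exactly the structure the model assumes, exposing
#' every piece of ground truth for recovery tests:
#' inputs \eqn{X} uniform on a box (default \eqn{[-1, 1]^d}); design
#' matrix \eqn{\Psi} from the basis configuration; weights
#' \eqn{\omega_i \sim N(\mu_i, \eta_i^{-1})}; noise
#' \eqn{\varepsilon_n \sim N(0, \lambda^{-1})}; targets
#' \eqn{y = \Psi\omega + \varepsilon}.  When `hp` is `NULL` the
#' ground-truth hyperparameters are drawn by
#' [initialize_hyperparameters()] within the same seeded stream.
#'
#' @param n Number of observations.
#' @param basis A [basis_config()]; data-dependent RBF fields are resolved
#'   against the drawn `X`.
#' @param hp Ground-truth [hyperparameters()] or `NULL` to draw them.
#' @param seed Optional integer seed making the whole draw reproducible.
#' @param d Input dimension.
#' @param x_range Length-2 range of the uniform input box.
#' @return Object of class `synthetic_dataset`: `data` (a
#'   [regression_data()]), `true_weights`, `true_hp`, `noise`, `seed`.
#' @export
generate_synthetic <- function(n, basis = basis_config(), hp = NULL,
                               seed = NULL, d = 1L, x_range = c(-1, 1)) {
  if (length(n) != 1L || n < 1 || n != round(n)) {
    stop_contract("`n` must be a positive integer")
  }
  if (!is.null(hp) && !inherits(hp, "hyperparameters")) {
    stop_contract("`hp` must be NULL or a hyperparameters object")
  }
  with_seed(seed, function() {
    X <- matrix(stats::runif(n * d, x_range[1], x_range[2]), n, d)
    cfg <- resolve_basis(basis, X)
    Psi <- build_design_matrix(X, cfg)
    M <- ncol(Psi)
    if (is.null(hp)) {
      hp <- initialize_hyperparameters(M)
    } else if (length(hp$eta) != M) {
      stop_contract(sprintf(
        "`hp` has %d entries but the basis produces M = %d columns",
        length(hp$eta), M))
    }
    omega <- stats::rnorm(M, mean = hp$mu, sd = 1 / sqrt(hp$eta))
    eps <- stats::rnorm(n, mean = 0, sd = 1 / sqrt(hp$lambda))
    y <- drop(Psi %*% omega) + eps
    structure(
      list(data = regression_data(X, y, basis = cfg, Psi = Psi),
           true_weights = omega, true_hp = hp, noise = eps,
           seed = seed),
      class = "synthetic_dataset"
    )
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> N = %d, M = %d, true lambda = %.4g, seed = %s\n",
    length(x$data$y), length(x$true_weights), x$true_hp$lambda,
    if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}
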