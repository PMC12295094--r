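#' Basis-function configuration
#'
#' Describes how the raw inputs `X` (an `N x d` matrix) are mapped to the
#' `N x M` design matrix of basis-function evaluations.  Three families are
#' supported:
#'
#' * `"gaussian_rbf"` -- radial basis functions
#'   \eqn{\psi_c(x) = \exp(-\|x - c\|^2 / (2 w^2))} with shared width `w`
#'   and a set of centers.  Centers and width may be left `NULL` and are
#'   then resolved from the data by [resolve_basis()]: the centers default
#'   to the first `n_centers` input points and the width to the median
#'   pairwise distance of the inputs.
#' * `"polynomial"` -- powers \eqn{x^1, \dots, x^{degree}} of a scalar
#'   input.
#' * `"identity"` -- the raw input columns.
#'
#' When `include_bias` is `TRUE` (the default, matching the usual
#' convention \eqn{\psi_0(x) = 1}) a constant column of ones is prepended.
#'
#' @param family Basis family, one of `"gaussian_rbf"`, `"identity"`,
#'   `"polynomial"`.
#' @param include_bias Prepend a constant bias column \eqn{\psi_0 \equiv 1}?
#' @param degree Polynomial degree (polynomial family only), integer
#'   \eqn{\ge 1}.
#' @param centers Matrix (one row per center) or vector of RBF centers, or
#'   `NULL` to resolve from data.
#' @param width Positive shared RBF length-scale, or `NULL` to resolve
#'   from data.
#' @param n_centers Number of centers to pick from the data when `centers`
#'   is `NULL` (gaussian_rbf only).  Defaults to 9 so that the default
#'   basis with bias has \eqn{M = 10} columns.
#' @param center_method How data-driven centers are chosen:
#'   `"first_points"` (the first `n_centers` rows of `X`) or `"kmeans"`.
#' @return An object of class `basis_config`.
#' @seealso [build_design_matrix()], [resolve_basis()]
#' @export
basis_config <- function(family = c("gaussian_rbf", "identity", "polynomial"),
                         include_bias = TRUE,
                         degree = NULL,
                         centers = NULL,
                         width = NULL,
                         n_centers = NULL,
                         center_method = c("first_points", "kmeans")) {
  family <- match.arg(family)
  center_method <- match.arg(center_method)
  if (family == "polynomial") {
    if (is.null(degree) || length(degree) != 1L || !is.finite(degree) ||
        degree < 1 || degree != round(degree)) {
      stop_contract("polynomial basis requires an integer `degree` >= 1")
    }
    degree <- as.integer(degree)
  }
  if (family == "gaussian_rbf") {
    if (!is.null(width) && (length(width) != 1L || !is.finite(width) ||
                            width <= 0)) {
      stop_contract("gaussian_rbf basis requires `width` > 0")
    }
    if (!is.null(centers)) {
      centers <- as.matrix(centers)
      if (nrow(centers) < 1L) {
        stop_contract("gaussian_rbf basis requires at least one center")
      }
    }
    if (is.null(centers) && is.null(n_centers)) n_centers <- 9L
    if (!is.null(n_centers) &&
        (length(n_centers) != 1L || n_centers < 1 ||
         n_centers != round(n_centers))) {
      stop_contract("`n_centers` must be a positive integer")
    }
  }
  structure(
    list(family = family, include_bias = isTRUE(include_bias),
         degree = degree, centers = centers, width = width,
         n_centers = if (is.null(n_centers)) NULL else as.integer(n_centers),
         center_method = center_method),
    class = "basis_config"
  )
}

#' Resolve data-dependent parts of a basis configuration
#'
#' For the gaussian_rbf family, fills in `centers` (first `n_centers` input
#' points, or k-means centroids) and `width` (median pairwise distance of
#' the inputs; at most 500 rows are used for the median to bound cost)
#' whenever they are `NULL`.  Other families are returned unchanged.
#'
#' @param config A [basis_config()].
#' @param X The `N x d` input matrix the basis will be applied to.
#' @return A fully concrete `basis_config`.
#' @export
resolve_basis <- function(config, X) {
  stopifnot(inherits(config, "basis_config"))
  X <- as.matrix(X)
  if (config$family != "gaussian_rbf") return(config)
  if (is.null(config$centers)) {
    k <- min(config$n_centers, nrow(X))
    if (config$center_method == "kmeans" && nrow(X) > k) {
      config$centers <- stats::kmeans(X, centers = k, nstart = 3)$centers
    } else {
      config$centers <- X[seq_len(k), , drop = FALSE]
    }
  }
  if (is.null(config$width)) {
    Xs <- if (nrow(X) > 500L) X[seq_len(500L), , drop = FALSE] else X
    w <- stats::median(stats::dist(Xs))
    if (!is.finite(w) || w <= 0) w <- 1
    config$width <- w
  }
  config
}

#' Build the design matrix of basis-function evaluations
#'
#' Evaluates every basis function at every input point, returning the
#' `N x M` design matrix with entry `[n, j]` equal to
#' \eqn{\psi_j(x_n)}.  With `include_bias`, column 1 is identically one.
#'
#' @param X `N x d` numeric input matrix (a vector is treated as a single
#'   column).
#' @param config A [basis_config()]; data-dependent RBF fields are
#'   resolved on the fly via [resolve_basis()] if still `NULL`.
#' @return `N x M` numeric matrix.
#' @examples
#' build_design_matrix(matrix(c(2, 3)), basis_config("identity"))
#' build_design_matrix(matrix(2), basis_config("polynomial", degree = 2))
#' @export
build_design_matrix <- function(X, config) {
  stopifnot(inherits(config, "basis_config"))
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop_contract("`X` must have at least one row")
  if (!all(is.finite(X))) stop_contract("`X` contains non-finite entries")
  config <- resolve_basis(config, X)
  Psi <- switch(
    config$family,
    identity = X,
    polynomial = {
      if (ncol(X) != 1L) {
        stop_contract("polynomial basis supports scalar (d = 1) inputs only")
      }
      outer(drop(X), seq_len(config$degree), `^`)
    },
    gaussian_rbf = {
      centers <- as.matrix(config$centers)
      if (ncol(centers) != ncol(X)) {
        stop_contract("RBF centers must have the same dimension as `X`")
      }
      w2 <- 2 * config$width^2
      cols <- apply(centers, 1L, function(ctr) {
        d2 <- rowSums((X - matrix(ctr, nrow(X), ncol(X), byrow = TRUE))^2)
        exp(-d2 / w2)
      })
      matrix(cols, nrow = nrow(X))
    }
  )
  if (config$include_bias) Psi <- cbind(1, Psi)
  if (ncol(Psi) < 1L) stop_contract("basis produced zero columns")
  if (!all(is.finite(Psi))) stop_contract("design matrix has non-finite entries")
  colnames(Psi) <- NULL
  Psi
}

#' Bundle inputs, targets and design matrix
#'
#' Container for a regression problem: the raw inputs `X`, the target
#' vector `y` and the design matrix `Psi` of basis evaluations.  Gram
#' quantities (`Psi'Psi`, `Psi'y`, `y'y`) are precomputed once here; every
#' posterior and evidence evaluation afterwards is O(M^3), independent of
#' N, which keeps the optimisation loops cheap.
#'
#' @param X `N x d` input matrix.
#' @param y Length-`N` target vector.
#' @param basis A [basis_config()] used to build `Psi` when `Psi` is not
#'   supplied.  Stored (resolved) for later prediction.
#' @param Psi Optional precomputed `N x M` design matrix.
#' @return Object of class `regression_data` with elements `X`, `y`,
#'   `Psi`, `basis`, and Gram products `PtP`, `Pty`, `yty`.
#' @export
regression_data <- function(X, y, basis = basis_config(), Psi = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) {
    stop_contract("`X` and `y` must have the same number of rows")
  }
  if (is.null(Psi)) {
    basis <- resolve_basis(basis, X)
    Psi <- build_design_matrix(X, basis)
  } else {
    Psi <- as.matrix(Psi)
  }
  if (nrow(Psi) != length(y)) {
    stop_contract("`Psi` and `y` must have the same number of rows")
  }
  if (!all(is.finite(Psi))) stop_contract("`Psi` has non-finite entries")
  structure(
    list(X = X, y = y, Psi = Psi, basis = basis,
         PtP = crossprod(Psi), Pty = drop(crossprod(Psi, y)),
         yty = sum(y^2)),
    class = "regression_data"
  )
}

#' @export
print.regression_data <- function(x, ...) {
  cat(sprintf("<regression_data> N = %d, d = %d, M = %d basis columns (%s)\n",
              nrow(x$X), ncol(x$X), ncol(x$Psi),
              if (inherits(x$basis, "basis_config")) x$basis$family else "custom"))
  invisible(x)
}
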