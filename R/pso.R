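#' Particle swarm configuration
#'
#' Settings for the global-best particle swarm baseline.  Defaults follow
#' the canonical constriction-like parametrisation (inertia 0.72,
#' cognitive = social = 1.49, 30 particles); the velocity clamp is a
#' fraction of the per-dimension box width.  Convergence detection for the
#' comparison with EM uses the same tolerance as the EM loop, applied to
#' the global-best objective over a patience window: the swarm counts as
#' converged at the first iteration where the best-objective improvement
#' has stayed below `tol` for `patience` consecutive iterations.
#'
#' @param n_particles Number of particles (>= 2).
#' @param n_iterations Iteration budget.
#' @param inertia Inertia weight in (0, 1).
#' @param cognitive,social Acceleration coefficients.
#' @param velocity_clamp Fraction of the box width clamping each velocity
#'   component.
#' @param bounds Optional `2 x D` matrix (rows: lower, upper) overriding
#'   the default search box.
#' @param tol Convergence-detection tolerance (defaults to the EM
#'   tolerance so the two methods share one criterion).
#' @param patience Window length (iterations) for convergence detection.
#' @param seed Optional integer seed.
#' @return Object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 30L, n_iterations = 200L,
                       inertia = 0.72, cognitive = 1.49, social = 1.49,
                       velocity_clamp = 0.2, bounds = NULL,
                       tol = 1e-6, patience = 50L, seed = NULL) {
  if (n_particles < 2) stop_contract("`n_particles` must be >= 2")
  if (n_iterations < 1) stop_contract("`n_iterations` must be >= 1")
  if (inertia <= 0 || inertia >= 1) stop_contract("`inertia` must be in (0, 1)")
  if (cognitive <= 0 || social <= 0) {
    stop_contract("`cognitive` and `social` must be > 0")
  }
  if (velocity_clamp <= 0) stop_contract("`velocity_clamp` must be > 0")
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != 2L || !all(is.finite(bounds)) ||
        any(bounds[2, ] <= bounds[1, ])) {
      stop_contract("`bounds` must be a finite 2 x D matrix with lower < upper")
    }
  }
  structure(
    list(n_particles = as.integer(n_particles),
         n_iterations = as.integer(n_iterations),
         inertia = inertia, cognitive = cognitive, social = social,
         velocity_clamp = velocity_clamp, bounds = bounds,
         tol = tol, patience = as.integer(patience), seed = seed),
    class = "pso_config"
  )
}

#' Global-best particle swarm maximisation of an arbitrary objective
#'
#' The standard global-best update: for each particle,
#' \deqn{v \leftarrow w v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x),
#'   \qquad x \leftarrow x + v,}
#' with velocities clamped to `velocity_clamp` times the box width and
#' positions clamped to the box.  Runs the full budget (no early exit) and
#' records the first iteration at which the convergence criterion of
#' [pso_config()] is met.
#'
#' @param objective Function mapping a position vector to a scalar to be
#'   maximised (may return `-Inf`/`NaN` for infeasible points, treated as
#'   `-Inf`).
#' @param lower,upper Per-dimension search-box limits.
#' @param config A [pso_config()].
#' @param x0 Optional matrix of initial positions (rows = particles);
#'   missing rows are drawn uniformly in the box.
#' @param v0 Optional matrix of initial velocities (default: uniform in
#'   +/- half the clamp).
#' @return List with `best_x`, `best_f`, `trace` (global best per
#'   iteration), `first_converged_iteration` (`NA` if never met).
#' @export
pso_optimize <- function(objective, lower, upper, config = pso_config(),
                         x0 = NULL, v0 = NULL) {
  stopifnot(inherits(config, "pso_config"))
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  D <- length(lower)
  if (length(upper) != D || any(upper <= lower)) {
    stop_contract("`lower` and `upper` must match with lower < upper")
  }
  S <- config$n_particles
  width <- upper - lower
  vmax <- config$velocity_clamp * width
  with_seed(config$seed, function() {
    draw_positions <- function() {
      matrix(stats::runif(S * D), S, D) * rep(width, each = S) +
        rep(lower, each = S)
    }
    eval_all <- function(X) {
      f <- vapply(seq_len(S), function(i) objective(X[i, ]), numeric(1))
      f[!is.finite(f)] <- -Inf
      f
    }
    X <- draw_positions()
    if (!is.null(x0)) {
      x0 <- as.matrix(x0)
      k <- min(nrow(x0), S)
      X[seq_len(k), ] <- x0[seq_len(k), , drop = FALSE]
    }
    f <- eval_all(X)
    if (all(f == -Inf)) {
      X <- draw_positions()
      f <- eval_all(X)
      if (all(f == -Inf)) {
        stop("PSO initialisation failed: objective non-finite for every ",
             "particle after one re-draw", call. = FALSE)
      }
    }
    V <- if (is.null(v0)) {
      (matrix(stats::runif(S * D), S, D) - 0.5) * rep(vmax, each = S)
    } else {
      as.matrix(v0)
    }
    Pbest <- X
    pbest_f <- f
    g <- which.max(f)
    gbest <- X[g, ]
    gbest_f <- f[g]
    trace <- numeric(config$n_iterations)
    streak <- 0L
    first_conv <- NA_integer_
    for (it in seq_len(config$n_iterations)) {
      r1 <- matrix(stats::runif(S * D), S, D)
      r2 <- matrix(stats::runif(S * D), S, D)
      V <- config$inertia * V +
        config$cognitive * r1 * (Pbest - X) +
        config$social * r2 * (matrix(gbest, S, D, byrow = TRUE) - X)
      V <- pmin(pmax(V, matrix(-vmax, S, D, byrow = TRUE)),
                matrix(vmax, S, D, byrow = TRUE))
      X <- X + V
      X <- pmin(pmax(X, matrix(lower, S, D, byrow = TRUE)),
                matrix(upper, S, D, byrow = TRUE))
      f <- eval_all(X)
      better <- f > pbest_f
      if (any(better)) {
        Pbest[better, ] <- X[better, , drop = FALSE]
        pbest_f[better] <- f[better]
      }
      prev_best <- gbest_f
      g <- which.max(pbest_f)
      if (pbest_f[g] > gbest_f) {
        gbest_f <- pbest_f[g]
        gbest <- Pbest[g, ]
      }
      trace[it] <- gbest_f
      improvement <- gbest_f - prev_best
      streak <- if (improvement < config$tol) streak + 1L else 0L
      if (is.na(first_conv) && streak >= config$patience) first_conv <- it
    }
    list(best_x = gbest, best_f = gbest_f, trace = trace,
         first_converged_iteration = first_conv)
  })
}

#' Particle swarm baseline over the evidence objective
#'
#' Maximises the same log marginal likelihood as [fit_em()] with
#' global-best PSO.  Particles encode
#' \eqn{(\ln\eta_1, \dots, \ln\eta_M, \ln\lambda, \mu_1, \dots, \mu_M)};
#' the precisions are searched in log space to respect positivity.  The
#' default box is \eqn{\ln\eta \in [-7, 28]} (so \eqn{\eta} stays at or
#' below the EM precision cap), \eqn{\ln\lambda \in [-7, 7]},
#' \eqn{\mu \in [-10, 10]}.
#'
#' @param data A [regression_data()].
#' @param config A [pso_config()].
#' @return Object of class `pso_result`: `best_hp`,
#'   `best_log_evidence`, `trace` (non-decreasing global best per
#'   iteration), `first_converged_iteration` (`NA` when the criterion is
#'   never met within the budget).
#' @export
pso_fit <- function(data, config = pso_config()) {
  stopifnot(inherits(data, "regression_data"))
  M <- ncol(data$Psi)
  if (is.null(config$bounds)) {
    lower <- c(rep(-7, M), -7, rep(-10, M))
    upper <- c(rep(28, M), 7, rep(10, M))
  } else {
    if (ncol(config$bounds) != 2L * M + 1L) {
      stop_contract("`bounds` must have 2*M + 1 columns")
    }
    lower <- config$bounds[1, ]
    upper <- config$bounds[2, ]
  }
  objective <- function(z) {
    log_evidence_core(exp(z[seq_len(M)]), exp(z[M + 1L]),
                      z[(M + 2L):(2L * M + 1L)], data)
  }
  res <- pso_optimize(objective, lower, upper, config)
  best_hp <- hyperparameters(eta = exp(res$best_x[seq_len(M)]),
                             lambda = exp(res$best_x[M + 1L]),
                             mu = res$best_x[(M + 2L):(2L * M + 1L)])
  structure(
    list(best_hp = best_hp, best_log_evidence = res$best_f,
         trace = res$trace,
         first_converged_iteration = res$first_converged_iteration,
         config = config),
    class = "pso_result"
  )
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("<pso_result> best log evidence = %.6f after %d iterations\n",
              x$best_log_evidence, length(x$trace)))
  cat(sprintf("  convergence criterion met: %s\n",
              if (is.na(x$first_converged_iteration)) "never"
              else sprintf("iteration %d", x$first_converged_iteration)))
  invisible(x)
}
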