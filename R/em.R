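#' EM loop configuration
#'
#' Controls for [fit_em()].  Convergence is declared on the log evidence
#' (monitoring the objective is far easier to implement than monitoring
#' the hyperparameters themselves, and hyperparameter convergence implies
#' a constant objective): the loop stops when the absolute change in the
#' log marginal likelihood between successive iterations falls below
#' `tol`.
#'
#' Two M-step variants are available.  `"as_printed"` (default) applies
#' the simultaneous update laws
#' \eqn{\eta_i \leftarrow 1/(m_i^2 + C_{ii})},
#' \eqn{\lambda \leftarrow N/(\|y - \Psi m\|^2 + \mathrm{Tr}(\Psi^T\Psi C))},
#' \eqn{\mu \leftarrow m}, all computed from the same E-step moments.
#' `"centered_sequential"` is a coordinate-ascent generalised M step that
#' updates \eqn{\eta_i \leftarrow 1/((m_i - \mu_i)^2 + C_{ii})} with
#' \eqn{\mu} held at its old value before setting \eqn{\mu \leftarrow m};
#' each sub-step maximises the variational lower bound, so this variant
#' carries a monotone-evidence guarantee.  With `mu_mode = "fixed_zero"`
#' (the relevance-vector-machine prior) the two variants coincide.
#'
#' @param tol Absolute change in log evidence declaring convergence.
#' @param max_iter Maximum number of EM cycles.
#' @param update_variant `"as_printed"` or `"centered_sequential"`.
#' @param mu_mode `"free"` (update the prior means) or `"fixed_zero"`
#'   (pin \eqn{\mu = 0}, the RVM prior).
#' @param max_restarts How many times to re-draw initial hyperparameters
#'   when the posterior precision goes numerically singular before falling
#'   back to the pseudo-inverse path.
#' @param singular_action `"restart"` (default) or `"pseudo_inverse"`
#'   (accept the pseudo-inverse posterior immediately).
#' @param eta_cap Upper clip for the precisions `eta`, preventing
#'   overflow-driven singularity.
#' @param seed Optional integer seed for the initial draw; restart `r`
#'   uses `seed + r` so every run is replayable.
#' @return Object of class `em_config`.
#' @export
em_config <- function(tol = 1e-6, max_iter = 1000L,
                      update_variant = c("as_printed", "centered_sequential"),
                      mu_mode = c("free", "fixed_zero"),
                      max_restarts = 20L,
                      singular_action = c("restart", "pseudo_inverse"),
                      eta_cap = 1e12, seed = NULL) {
  update_variant <- match.arg(update_variant)
  mu_mode <- match.arg(mu_mode)
  singular_action <- match.arg(singular_action)
  if (tol <= 0) stop_contract("`tol` must be > 0")
  if (max_iter < 1) stop_contract("`max_iter` must be >= 1")
  if (eta_cap <= 1) stop_contract("`eta_cap` must be > 1")
  if (max_restarts < 0) stop_contract("`max_restarts` must be >= 0")
  structure(
    list(tol = tol, max_iter = as.integer(max_iter),
         update_variant = update_variant, mu_mode = mu_mode,
         max_restarts = as.integer(max_restarts),
         singular_action = singular_action, eta_cap = eta_cap, seed = seed),
    class = "em_config"
  )
}

#' E step: posterior moments at the current hyperparameters
#'
#' Maximising the variational lower bound over the weight distribution
#' zeroes the KL divergence to the exact posterior, so the E step reduces
#' to computing the posterior mean and covariance; this simply delegates
#' to [compute_posterior_ggwp()] (including its singularity diagnostics).
#'
#' @inheritParams compute_posterior_ggwp
#' @return A `ggwp_posterior`.
#' @export
e_step <- function(hp, data, rcond_threshold = 1e-12) {
  compute_posterior_ggwp(hp, data, rcond_threshold = rcond_threshold)
}

#' M step: re-estimate the hyperparameters from the posterior moments
#'
#' Applies the update laws described in [em_config()] to produce new
#' hyperparameters from the E-step moments `(m, C)`.  All precisions are
#' clipped to `(0, eta_cap]`.
#'
#' @param posterior A `ggwp_posterior` from [e_step()].
#' @param hp_old The hyperparameters the posterior was computed under
#'   (the old \eqn{\mu} enters the centered variant).
#' @param data A [regression_data()].
#' @param variant `"as_printed"` or `"centered_sequential"`.
#' @param mu_mode `"free"` or `"fixed_zero"`.
#' @param eta_cap Upper clip for the new precisions.
#' @return A [hyperparameters()] object.
#' @export
m_step <- function(posterior, hp_old, data,
                   variant = c("as_printed", "centered_sequential"),
                   mu_mode = c("free", "fixed_zero"),
                   eta_cap = 1e12) {
  variant <- match.arg(variant)
  mu_mode <- match.arg(mu_mode)
  stopifnot(inherits(posterior, "ggwp_posterior"),
            inherits(hp_old, "hyperparameters"),
            inherits(data, "regression_data"))
  m <- posterior$m
  Cii <- diag(posterior$C)
  N <- length(data$y)
  mu_ref <- if (mu_mode == "fixed_zero") rep(0, length(m)) else hp_old$mu
  # eta update: second moment of the weight about the prior reference;
  # as_printed measures it about zero, centered_sequential about mu_old
  dev <- if (variant == "as_printed") m else m - mu_ref
  s <- dev^2 + Cii
  if (any(s <= 0)) {
    stop("degenerate precision update: m_i^2 + C_ii = 0 for some weight",
         call. = FALSE)
  }
  eta_new <- pmin(1 / s, eta_cap)
  r <- data$y - drop(data$Psi %*% m)
  denom <- sum(r^2) + sum(data$PtP * posterior$C)   # ||y-Psi m||^2 + Tr(Psi'Psi C)
  if (denom <= 0) {
    stop("degenerate fit: zero expected residual, lambda update undefined",
         call. = FALSE)
  }
  lambda_new <- N / denom
  mu_new <- if (mu_mode == "fixed_zero") rep(0, length(m)) else m
  hyperparameters(eta_new, lambda_new, mu_new)
}

#' Fit hyperparameters by expectation-maximisation
#'
#' Alternates [e_step()] and [m_step()], appending the log evidence to the
#' trace after every cycle, until the absolute evidence change drops below
#' `config$tol` or `config$max_iter` is reached.  If the posterior
#' precision goes numerically singular (reciprocal condition below
#' `1e-12`), the default policy re-draws the initial hyperparameters — up
#' to `config$max_restarts` times, with a logged seed sequence — and only
#' then accepts the pseudo-inverse evaluation of the covariance, which is
#' known to give imprecise evidence values.
#'
#' @param data A [regression_data()].
#' @param config An [em_config()].
#' @param init Optional starting [hyperparameters()]; when `NULL` they are
#'   drawn via [initialize_hyperparameters()].
#' @return Object of class `em_fit`: final `hyperparameters` and
#'   `posterior`, a `trace` data frame (`iteration`, `log_evidence`,
#'   `used_pseudo_inverse`), `status` (`"converged"`,
#'   `"max_iter_reached"` or `"degenerate"`), `n_iterations` (first
#'   iteration meeting the tolerance, `NA` if never), `n_restarts` and the
#'   seeds used.
#' @export
fit_em <- function(data, config = em_config(), init = NULL) {
  stopifnot(inherits(data, "regression_data"), inherits(config, "em_config"))
  M <- ncol(data$Psi)
  N <- length(data$y)
  if (N < M) {
    warning(sprintf("N = %d < M = %d: posterior is prior-dominated and may be ill-conditioned", N, M))
  }
  seeds_used <- integer(0)
  draw_init <- function(r) {
    if (!is.null(init) && r == 0L) return(init)
    s <- if (is.null(config$seed)) NULL else as.integer(config$seed + r)
    seeds_used <<- c(seeds_used, if (is.null(s)) NA_integer_ else s)
    initialize_hyperparameters(M, seed = s)
  }
  res <- NULL
  n_restarts <- 0L
  for (r in 0:config$max_restarts) {
    hp0 <- draw_init(r)
    allow_pinv <- config$singular_action == "pseudo_inverse"
    res <- run_em_once(data, hp0, config, allow_pinv = allow_pinv)
    if (!res$singular_abort) {
      n_restarts <- r
      break
    }
    if (r == config$max_restarts) {
      # restarts exhausted: accept the pseudo-inverse path on a fresh draw
      hp0 <- draw_init(r + 1L)
      res <- run_em_once(data, hp0, config, allow_pinv = TRUE)
      n_restarts <- r + 1L
    }
  }
  if (!all(is.finite(res$trace$log_evidence))) {
    stop("fatal degeneracy: non-finite log evidence even on the ",
         "pseudo-inverse path", call. = FALSE)
  }
  structure(
    list(hyperparameters = res$hp, posterior = res$posterior,
         trace = res$trace, status = res$status,
         n_iterations = res$n_iterations, n_restarts = n_restarts,
         restart_seeds = seeds_used, config = config,
         basis = data$basis),
    class = "em_fit"
  )
}

# One EM run from a fixed starting point.  Returns singular_abort = TRUE
# when a pseudo-inverse event occurs and allow_pinv is FALSE (the caller
# then restarts from new initial values).
run_em_once <- function(data, hp, config, allow_pinv) {
  trace_it <- integer(0)
  trace_L <- numeric(0)
  trace_pinv <- logical(0)
  L_prev <- NA_real_
  status <- "max_iter_reached"
  n_iterations <- NA_integer_
  any_pinv <- FALSE
  posterior <- NULL
  for (k in seq_len(config$max_iter)) {
    post <- e_step(hp, data)
    if (post$used_pseudo_inverse && !allow_pinv) {
      return(list(singular_abort = TRUE))
    }
    hp <- m_step(post, hp, data, variant = config$update_variant,
                 mu_mode = config$mu_mode, eta_cap = config$eta_cap)
    posterior <- compute_posterior_ggwp(hp, data)
    if (posterior$used_pseudo_inverse && !allow_pinv) {
      return(list(singular_abort = TRUE))
    }
    ev <- log_marginal_likelihood(hp, data, posterior = posterior)
    any_pinv <- any_pinv || posterior$used_pseudo_inverse ||
      post$used_pseudo_inverse
    trace_it <- c(trace_it, k)
    trace_L <- c(trace_L, ev$log_value)
    trace_pinv <- c(trace_pinv, posterior$used_pseudo_inverse)
    if (k > 1L && is.finite(ev$log_value) && is.finite(L_prev) &&
        abs(ev$log_value - L_prev) < config$tol) {
      status <- "converged"
      n_iterations <- k
      break
    }
    L_prev <- ev$log_value
  }
  if (status != "converged" && any_pinv) status <- "degenerate"
  list(singular_abort = FALSE, hp = hp, posterior = posterior,
       trace = data.frame(iteration = trace_it, log_evidence = trace_L,
                          used_pseudo_inverse = trace_pinv),
       status = status, n_iterations = n_iterations)
}

#' @export
print.em_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<em_fit> status = %s after %d iteration(s), %d restart(s)\n",
              x$status, nrow(x$trace), x$n_restarts))
  cat(sprintf("  final log evidence: %.6f\n", last$log_evidence))
  cat(sprintf("  lambda-hat: %.6g\n", x$hyperparameters$lambda))
  invisible(x)
}

#' Predictions from a fitted model
#'
#' @param object An `em_fit`.
#' @param newdata Matrix (or vector) of new inputs, one row per point.
#' @param ... Unused.
#' @return Data frame with columns `mean` and `variance`.
#' @export
predict.em_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- t(apply(newdata, 1L, function(x) {
    p <- predictive_distribution(x, object$posterior,
                                 object$hyperparameters$lambda, object$basis)
    c(mean = p$mean, variance = p$variance)
  }))
  as.data.frame(out)
}
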