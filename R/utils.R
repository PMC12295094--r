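# Internal helpers shared across modules.

# Run `fn()` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.  seed = NULL means "use the current
# RNG stream" (no seeding, nothing restored).
with_seed <- function(seed, fn) {
  if (is.null(seed)) {
    return(fn())
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old_seed <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  fn()
}

# Symmetrize a square matrix; the closed-form covariances are symmetric in
# exact arithmetic but accumulate asymmetry of order machine epsilon.
symmetrize <- function(A) (A + t(A)) / 2

stop_contract <- function(...) stop(..., call. = FALSE)
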