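# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's global RNG state afterwards.  All randomness in the package
# flows through this, so one integer seed fully determines any output and
# no function perturbs the user's random stream.  The generator is R's
# default Mersenne-Twister with Inversion for normals (documented contract;
# identical across platforms for a given R version).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Moment (Fisher-Pearson) skewness: m3 / m2^(3/2) with biased central moments.
moment_skewness <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two observations", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_prob <- function(p, what) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", what), call. = FALSE)
  }
}
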