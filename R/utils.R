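# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else if (exists(".Random.seed", envir = env, inherits = FALSE)) rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stream seed from a master seed
#'
#' Deterministic mixing of a master seed with a stream index (e.g. a subject
#' number), so that all randomness in a run flows from one master seed while
#' streams stay decoupled. Results stay below 2^31 - 1, the range of valid R
#' integer seeds.
#'
#' @param master Master seed (integer).
#' @param stream Stream index (integer).
#' @return An integer seed.
#' @export
derive_seed <- function(master, stream) {
  m <- 2147483647
  s <- (as.double(master) %% m) * 48271 + as.double(stream) * 104729 + 12345
  as.integer(s %% m)
}

# Largest-remainder integer allocation of n among weights; exact when the
# weights are integers summing to n.
allocate_counts <- function(n, weights) {
  stopifnot(all(weights >= 0), sum(weights) > 0)
  share <- n * weights / sum(weights)
  base <- floor(share)
  left <- n - sum(base)
  if (left > 0) {
    idx <- order(share - base, decreasing = TRUE)[seq_len(left)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

# Truncated draws via inverse-CDF so truncation introduces no atoms.
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  lo <- plnorm(lower, meanlog, sdlog)
  hi <- plnorm(upper, meanlog, sdlog)
  qlnorm(runif(n, lo, hi), meanlog, sdlog)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pab <- function(...) stop(sprintf(...), call. = FALSE)
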