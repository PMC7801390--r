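# Internal helpers shared across the package.

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_len = FALSE) {
  if (!is.numeric(x) || (!allow_zero_len && length(x) != 1L))
    stopf("'%s' must be a single number", name)
  if (any(!is.finite(x))) stopf("'%s' must be finite", name)
  if (any(x < lower)) stopf("'%s' must be >= %g", name, lower)
  if (any(x > upper)) stopf("'%s' must be <= %g", name, upper)
  invisible(x)
}

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so simulation helpers are deterministic without
# clobbering the session RNG.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a per-stage seed from a master seed; keeps results
# reproducible from one flag while decorrelating stages. Result < 2^31.
#' @noRd
spawn_seed <- function(master, stage) {
  stage_codes <- utf8ToInt(as.character(stage))
  h <- (as.numeric(master) %% 2147483647)
  for (code in stage_codes) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Truncated-normal draws by rejection with a cap on the rejection rate.
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf,
                       max_tries = 1000L) {
  if (sd < 0) stopf("'sd' must be >= 0")
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stopf("degenerate truncated normal: mean %g outside [%g, %g]",
            mean, lower, upper)
    return(rep(mean, n))
  }
  out <- numeric(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stopf("truncated-normal rejection rate too high for mean %g, sd %g on [%g, %g]",
            mean, sd, lower, upper)
    draw <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}
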