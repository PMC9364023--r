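# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  Every stochastic operation in the
# package routes through this so that no simulator mutates global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had_seed) old_seed <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_probability <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < 0 || x > 1 || (!allow_zero && x == 0)) {
    stop(sprintf("`%s` must be a single probability in [%s, 1]",
                 name, if (allow_zero) "0" else "(0"), call. = FALSE)
  }
  invisible(x)
}

check_color_probs <- function(color_probs) {
  if (!is.numeric(color_probs) || length(color_probs) != 2L ||
      any(!is.finite(color_probs)) || any(color_probs < 0) ||
      abs(sum(color_probs) - 1) > 1e-8) {
    stop("`color_probs` must be two non-negative probabilities summing to 1",
         call. = FALSE)
  }
  invisible(color_probs)
}

check_scalar_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (strict) "positive" else "non-negative"), call. = FALSE)
  }
  invisible(x)
}
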