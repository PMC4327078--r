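# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Classed error so callers/tests can condition on failure type without
# matching message text.
stop_ecgmcda <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "ecgmcda_error", "error")))
}

# Evaluate `expr` under set.seed(seed) and restore the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_ecgmcda("ecgmcda_parameter_error", "seed must be a single finite number")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-item child seed that stays inside 32-bit integer range.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 10007 + 7919 * as.numeric(index)) %% 2147483647
}

# Round half away from zero (base round() is half-to-even).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Population (divide-by-n) standard deviation; exact zero for constant input.
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
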