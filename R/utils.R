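# Internal helpers shared across the package.

# Signal a classed condition so callers/tests can distinguish failure modes.
eq_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "equiclock_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

eq_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# Run code under a fixed RNG state and restore the caller's state afterwards,
# so generators are deterministic without clobbering the session RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Full-precision decimal formatting: survives write -> read round trips.
format_full <- function(x) {
  formatC(x, digits = 17, format = "g")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
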