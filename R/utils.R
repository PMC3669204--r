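# Classed conditions so callers (and tests) can distinguish failure modes
# without string-matching messages.
stop_hrss <- function(message, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "hrss_error", "error", "condition"),
    list(message = message, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

warn_hrss <- function(message, class) {
  cond <- structure(
    class = c(class, "hrss_warning", "warning", "condition"),
    list(message = message, call = NULL)
  )
  warning(cond)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
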