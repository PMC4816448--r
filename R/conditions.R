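# Classed conditions so callers can branch on failure modes without
# string-matching messages.

mf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("markerfill_", class), "markerfill_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

mf_warn <- function(msg, ...) {
  warning(sprintf(msg, ...), call. = FALSE)
}

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
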