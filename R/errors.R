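# Classed conditions used across the package. Every domain error carries a
# short name (e.g. "MissingLead") both in the condition class and at the head
# of the message so callers and the CLI can match on either.

abort_pronecg <- function(name, message, ...) {
  cond <- structure(
    class = c(paste0("pronecg_", tolower(name)), "pronecg_error",
              "error", "condition"),
    list(message = paste0(name, ": ", message), call = sys.call(-1), ...)
  )
  stop(cond)
}

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}
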