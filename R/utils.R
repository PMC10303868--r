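# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded operations do not perturb the global stream.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(...) stop(..., call. = FALSE)

warn_ps <- function(...) warning(..., call. = FALSE)

# Numeric coercion that errors (rather than silently NA-ing) on bad cells.
as_numeric_strict <- function(x, what) {
  suppressWarnings(out <- as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(as.character(x)) != "")
  if (length(bad) > 0) {
    stop_ps(sprintf("non-numeric value %s in %s (entry %d)",
                    dQuote(as.character(x[bad[1]])), what, bad[1]))
  }
  out
}
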