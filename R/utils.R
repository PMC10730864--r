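# Internal helpers: classed conditions, seeded evaluation, small utilities.

bapfish_error <- function(message, class, ...) {
  structure(
    class = c(class, "bapfish_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_validation <- function(fmt, ...) {
  stop(bapfish_error(sprintf(fmt, ...), "bapfish_validation_error"))
}

stop_parse <- function(fmt, ..., offset = NA_integer_) {
  msg <- sprintf(fmt, ...)
  if (!is.na(offset)) msg <- sprintf("%s (at character %d)", msg, offset)
  stop(bapfish_error(msg, "bapfish_parse_error", offset = offset))
}

stop_assembly <- function(fmt, ...) {
  stop(bapfish_error(sprintf(fmt, ...), "bapfish_assembly_error"))
}

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L

is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
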