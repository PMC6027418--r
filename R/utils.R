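# Internal helpers: structured error conditions and RNG scoping.

stop_graftde <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "graftDE_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

format_error  <- function(msg) stop_graftde(msg, "graftDE_format_error")
design_error  <- function(msg) stop_graftde(msg, "graftDE_design_error")
param_error   <- function(msg) stop_graftde(msg, "graftDE_parameter_error")

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    param_error("seed must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
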