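## Structured error conditions.
##
## Two error classes cross the CLI boundary with distinct exit codes:
##   poolscan_config_error -> exit 2 (bad parameters / configuration)
##   poolscan_format_error -> exit 3 (malformed input file)
## Everything else is an ordinary R error (exit 1 from the CLI).

config_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("poolscan_config_error", "poolscan_error")))
}

format_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("poolscan_format_error", "poolscan_error")))
}

validation_error <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("poolscan_validation_error", "poolscan_error")))
}

## Run `expr` with the RNG seeded by `seed` (when non-NULL), restoring the
## caller's RNG state afterwards so library code never clobbers user seeds.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
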