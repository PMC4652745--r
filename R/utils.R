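# Internal helpers: seeded evaluation and logging.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

ruv_log <- function(level, ...) {
  if (isTRUE(getOption("ruvm.quiet", FALSE))) return(invisible(NULL))
  msg <- paste0(...)
  message(sprintf("%s %-5s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), level, msg))
  invisible(NULL)
}

log_info <- function(...) ruv_log("INFO", ...)
log_warn <- function(...) ruv_log("WARN", ...)

# Stop with a plain (non-call) error message.
fail <- function(...) stop(..., call. = FALSE)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
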