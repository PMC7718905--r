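# Internal helpers: deterministic seed streams, classed errors, logging.

# Deterministic 31-bit hash of an arbitrary key (integers/strings), used to
# split one master seed into independent reproducible substreams, e.g. per
# subject or per (cell, subset size, repetition).  Plain modular LCG mixing;
# collisions are astronomically unlikely at the stream counts used here and
# the mixing is pure arithmetic, so it is identical on every platform.
mix_seed <- function(...) {
  parts <- list(...)
  h <- 104729
  for (p in parts) {
    v <- if (is.character(p)) utf8ToInt(paste(p, collapse = "\r")) else as.numeric(p)
    for (x in v) {
      h <- (h * 48271 + abs(x) %% 2147483629 + 1) %% 2147483629
    }
  }
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pbsi_config_error", "pbsi_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("pbsi_data_error", "pbsi_error")))
}

pbsi_log <- function(msg, ..., verbose = getOption("pbsi.verbose", TRUE)) {
  if (isTRUE(verbose)) message(sprintf(msg, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
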