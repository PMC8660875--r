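# Internal helpers: seeded evaluation and seed-stream derivation.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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
  expr
}

# Derive `n` child seeds from a master seed, each a valid 32-bit seed.
# Used to give each bootstrap iteration / ensemble draw its own substream.
spawn_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structured progress/diagnostic notes: plain messages, so callers can
# suppressMessages() them; results never travel through this channel.
flunet_log <- function(fmt, ...) {
  message(sprintf(paste0("[flunet] ", fmt), ...))
}

stop_stage <- function(stage, fmt, ...) {
  stop(sprintf(paste0("[", stage, "] ", fmt), ...), call. = FALSE)
}
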