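# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All randomness in the package flows through withr::with_seed so that the
# caller's RNG state is never disturbed and every routine is reproducible
# from its own seed argument.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Messages are emitted through this wrapper so they can be silenced in one
# place (suppressMessages) without touching warnings.
mc_log <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stopf <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}
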