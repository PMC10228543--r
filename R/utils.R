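# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 31-bit sub-seed from a base seed and a text tag, so every
# simulated experiment has its own reproducible stream.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  v <- utf8ToInt(tag)
  h <- (sum(v * seq_along(v)) * 104729) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647) + 1L
}

stop_if_not_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(what, " must be a finite number")
  invisible(x)
}
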