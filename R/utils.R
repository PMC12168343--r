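# shared internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# run `code` under a fixed RNG state without disturbing the caller's stream
.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  withr::with_seed(as.integer(seed), code)
}

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

.is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

# derive a stream-specific 32-bit sub-seed from a user seed
.sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1009L) %% .Machine$integer.max
}
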