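# internal helpers

# derive a child seed from a master seed and an offset / label, staying
# inside the 32-bit signed integer range
derive_seed <- function(seed, offset) {
  stopifnot(is.finite(seed))
  as.integer((abs(seed) + 104729 * (offset %% 20011)) %% 2147483562 + 1)
}

# stable non-cryptographic hash of a label, for seeds keyed by name rather
# than by list position
label_offset <- function(label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 31 + v) %% 1999993
  h
}

clip0 <- function(x) {
  x[x < 0] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
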