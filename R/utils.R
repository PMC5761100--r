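# internal helpers: deterministic seed derivation and input checks

# Derive a child seed from a master seed and a label (stage name, bird id).
# Plain 32-bit-safe polynomial string hash so the same (seed, label) pair
# always maps to the same child seed, independent of platform or locale.
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- as.double(master_seed) %% 2147483647
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(TRUE)
}
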