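# internal helpers shared across modules

clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# derive a reproducible sub-seed from a master seed and a component label;
# kept below 2^31 - 1 so it is always a valid R integer seed
derive_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647L)
}

# run code under a temporary RNG seed (NULL = use the current stream)
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, lo, hi))
  }
  invisible(x)
}
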