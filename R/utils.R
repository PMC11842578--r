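# internal helpers

# evaluate `expr` under a scoped RNG seed; NULL seed leaves the RNG alone
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# derive a per-unit stream seed from a root seed; kept below 2^31 - 1 so it
# is always a valid R integer. The rule is fixed so batches are
# order-independent: unit i always gets the same stream for a given root.
# Nested levels use different strides (coprime primes) so the sub-streams
# of one unit never collide with those of another.
derive_seed <- function(root_seed, i, stride = 1000003) {
  as.integer((as.double(root_seed) + stride * as.double(i)) %% 2147483647)
}

stop_if_not_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
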