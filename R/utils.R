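# Internal helpers shared across modules.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream; a NULL seed uses (and advances) the current stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Counter-based sub-seed derivation so that individual Monte-Carlo trials are
# reproducible in isolation.  Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

# Half-up rounding, platform-stable (round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == trunc(x)
}

stop_class <- function(class, msg, ...) {
  abort(sprintf(msg, ...), class = paste0("leafagree_", class))
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict_min) x > min else x >= min)
  if (!ok) {
    stop_class("invalid_design", "`%s` must be a single finite number %s %s",
               name, if (strict_min) ">" else ">=", format(min))
  }
  invisible(x)
}

sample_kurtosis_raw <- function(x) {
  # Raw (non-excess) moment-ratio kurtosis m4 / m2^2; 3 for a normal sample.
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 < .Machine$double.eps) return(NA_real_)
  mean((x - m)^4) / m2^2
}
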