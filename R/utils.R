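# Internal helpers.

# Round half away from zero (the convention of the printed tables; base
# round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a reproducible 32-bit sub-seed from a parent seed and a stream
# index, so each simulated artifact draws from its own stream.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483647L)
}

# Format a molar Kd for human-readable reports: 2 significant figures,
# micromolar or nanomolar as appropriate.
format_kd <- function(kd_molar, digits = 2) {
  vapply(kd_molar, function(k) {
    if (!is.finite(k)) return(NA_character_)
    if (k >= 1e-6) sprintf("%s µM", signif(k * 1e6, digits))
    else sprintf("%s nM", signif(k * 1e9, digits))
  }, character(1))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be positive.", name))
  invisible(x)
}
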