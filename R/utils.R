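BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Commercial rounding (0.5 always rounds up in magnitude), used for all
#' reported percentages and densities. Base `round()` rounds half to even,
#' which disagrees with the convention used in published variant tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Phred+33 encoding of integer qualities
qual_to_string <- function(q) {
  vapply(q, function(qi) rawToChar(as.raw(qi + 33L)), character(1))
}

string_to_qual <- function(s) {
  lapply(s, function(si) as.integer(charToRaw(si)) - 33L)
}

# derive a stream-specific 32-bit seed from a base seed
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

stopifnot_scalar_prob <- function(p, name = "p") {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p >= 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1)", name))
  }
}
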