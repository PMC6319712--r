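# Internal numerical helpers shared across modules.

# Round half away from zero (the reporting convention for percentages,
# e.g. 564/594 -> 94.9). base::round() rounds half to even.
.roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Numerically stable log(sum(exp(x))).
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Derive a reproducible sub-stream seed from a master seed; keeps the result
# a valid 32-bit integer whatever the master is.
.subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * offset) %% .Machine$integer.max)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
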