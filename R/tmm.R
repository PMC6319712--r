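#' TMM normalization factors
#'
#' Trimmed mean of M-values: for each library versus the reference library,
#' per-feature log2 expression ratios (M) and average log2 abundances (A) are
#' computed over features with non-zero counts in both libraries; the upper
#' and lower 30% of M and 5% of A are trimmed; the remaining M values are
#' averaged with inverse-asymptotic-variance weights and exponentiated.
#' Factors are rescaled to multiply to one, and multiply the raw library
#' sizes to give effective sizes. A library that is an exact scalar multiple
#' of the reference gets factor 1.
#'
#' @param counts a [MiRNAExperiment-class] or count matrix (>= 2 libraries).
#' @param reference reference library (name or index); by default the
#'   library whose count-fraction upper quartile is closest to the mean
#'   upper quartile.
#' @param logratioTrim,sumTrim trim fractions on M and A.
#' @return named numeric vector of normalization factors (product 1).
#' @export
tmmFactors <- function(counts, reference = NULL,
                       logratioTrim = 0.3, sumTrim = 0.05) {
  cts <- if (methods::is(counts, "MiRNAExperiment")) mirCounts(counts)
         else as.matrix(counts)
  if (ncol(cts) < 2L) stop("TMM needs at least two libraries")
  N <- colSums(cts)
  if (any(N <= 0)) stop("every library must have a positive total")

  if (is.null(reference)) {
    q75 <- apply(sweep(cts, 2, N, "/"), 2, stats::quantile, probs = 0.75)
    reference <- which.min(abs(q75 - mean(q75)))
  } else if (is.character(reference)) {
    reference <- match(reference, colnames(cts))
    if (is.na(reference)) stop("unknown reference library")
  }
  ref <- cts[, reference]
  Nr <- N[reference]

  f <- vapply(seq_len(ncol(cts)), function(j) {
    .tmmPair(cts[, j], ref, N[j], Nr, logratioTrim, sumTrim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))          # geometric mean 1
  names(f) <- colnames(cts)
  f
}

# One library against the reference: weighted trimmed mean of M-values.
.tmmPair <- function(obs, ref, N, Nr, logratioTrim, sumTrim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep))
    stop("library shares no non-zero features with the reference")
  po <- obs[keep] / N
  pr <- ref[keep] / Nr
  M <- log2(po / pr)
  A <- 0.5 * log2(po * pr)
  # asymptotic binomial variance of M (delta method); weights are 1/v
  v <- (N - obs[keep]) / (N * obs[keep]) + (Nr - ref[keep]) / (Nr * ref[keep])

  if (max(abs(M)) < 1e-6) return(1)   # scalar multiple of the reference

  n <- length(M)
  loM <- floor(n * logratioTrim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  f <- sum(M[sel] / v[sel]) / sum(1 / v[sel])
  if (!is.finite(f)) f <- 0
  2^f
}
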