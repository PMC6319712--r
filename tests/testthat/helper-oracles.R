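# Shared fixtures and independent oracle implementations used across tests.
# The oracles deliberately use R's distribution functions (dnbinom, dbinom)
# and naive arithmetic, independent of the package's lgamma-based internals.

# Exhaustive-enumeration oracle for the conditional two-group exact test:
# probability of all splits of s = sA + sB no more likely than the observed
# one, under NB group sums (sizes nA/phi, nB/phi) or, for phi = 0, the
# conditional binomial.
oracleExactP <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(1)
  a <- 0:s
  pr <- if (phi > 0) {
    w <- dnbinom(a, size = nA / phi, mu = 50 * nA) *
      dnbinom(s - a, size = nB / phi, mu = 50 * nB)
    w / sum(w)
  } else {
    dbinom(a, s, nA / (nA + nB))
  }
  sum(pr[pr <= pr[sA + 1] * (1 + 1e-12)])
}

# Direct, unoptimized TMM: trimmed weighted mean of M-values of one library
# against a reference, written straight from the formula.
oracleTMMPair <- function(obs, ref) {
  N <- sum(obs); Nr <- sum(ref)
  keep <- obs > 0 & ref > 0
  M <- log2((obs[keep] / N) / (ref[keep] / Nr))
  A <- 0.5 * log2((obs[keep] / N) * (ref[keep] / Nr))
  v <- (N - obs[keep]) / (N * obs[keep]) + (Nr - ref[keep]) / (Nr * ref[keep])
  n <- length(M)
  lo <- sort(M)[floor(n * 0.3) + 1]; hi <- sort(M)[n - floor(n * 0.3)]
  loA <- sort(A)[floor(n * 0.05) + 1]; hiA <- sort(A)[n - floor(n * 0.05)]
  sel <- M >= lo & M <= hi & A >= loA & A <= hiA
  2^(sum(M[sel] / v[sel]) / sum(1 / v[sel]))
}

# Small experiment with fixed per-library counts for arithmetic tests.
toyExperiment <- function(counts, compartments = rep("CL", ncol(counts)),
                          cellLine = "lineA") {
  MiRNAExperiment(counts,
                  cellLine = cellLine,
                  compartment = compartments,
                  replicate = ave(seq_len(ncol(counts)),
                                  compartments, FUN = seq_along))
}

# A small NB count matrix with equal column totals (so pseudo-counts equal
# raw counts and factors of 1 are exact), padded by a filler feature.
equalTotalMatrix <- function(core) {
  tot <- colSums(core)
  filler <- max(tot) + 1000 - tot
  rbind(core, filler = filler)
}
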