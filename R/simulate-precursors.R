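#' Simulate pre-miRNA sequences with a controlled motif-bearing fraction
#'
#' Generates `n` random RNA sequences of which exactly
#' `round(n * plantedFraction)` contain at least one occurrence of `motif`.
#' Motif-free sequences are produced by rejection sampling; motif-bearing
#' ones by overwriting a random window of a motif-free draw with the motif.
#' The planted flag is recorded in `mcols(x)$planted`.
#'
#' @param n number of sequences.
#' @param length sequence length (default 82 nt, a typical pre-miRNA hairpin
#'   length); must exceed `nchar(motif)`.
#' @param motif literal RNA motif over A/C/G/U (e.g. `"CUGU"`, `"GGAG"`).
#' @param plantedFraction fraction of sequences carrying the motif, in
#'   \[0, 1\].
#' @param seed integer random seed.
#' @return A [Biostrings::RNAStringSet] with per-sequence `planted` flags.
#' @examples
#' pre <- simulatePrecursors(20, motif = "CUGU", plantedFraction = 0.5)
#' sum(S4Vectors::mcols(pre)$planted)
#' @export
simulatePrecursors <- function(n, length = 82L, motif = "CUGU",
                               plantedFraction = 0.5, seed = 1L) {
  .assertScalarNumber(n, "n", lower = 1)
  .assertScalarNumber(plantedFraction, "plantedFraction", lower = 0, upper = 1)
  motif <- toupper(motif)
  if (!nzchar(motif) || grepl("[^ACGU]", motif))
    stop("motif must be a non-empty string over {A, C, G, U}")
  if (length <= nchar(motif))
    stop("sequence length must exceed the motif length")

  set.seed(as.integer(seed))
  n <- as.integer(n)
  nPlanted <- round(n * plantedFraction)
  alphabet <- c("A", "C", "G", "U")

  drawMotifFree <- function() {
    repeat {
      s <- paste(sample(alphabet, length, replace = TRUE), collapse = "")
      if (!grepl(motif, s, fixed = TRUE)) return(s)
    }
  }
  seqs <- vapply(seq_len(n), function(i) drawMotifFree(), character(1))

  planted <- rep(FALSE, n)
  if (nPlanted > 0) {
    idx <- sample.int(n, nPlanted)
    planted[idx] <- TRUE
    for (i in idx) {
      at <- sample.int(length - nchar(motif) + 1L, 1L)
      substr(seqs[i], at, at + nchar(motif) - 1L) <- motif
    }
  }
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- sprintf("pre-mir-%04d", seq_len(n))
  S4Vectors::mcols(out)$planted <- planted
  out
}
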