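#' Scan precursor sequences for a literal RNA motif
#'
#' Exact, case-insensitive substring matching of a short motif (e.g. the
#' candidate EV-sorting signals `CUGU` or `GGAG`) against a set of
#' pre-miRNA sequences. A sequence counts once however many occurrences it
#' contains; all (including overlapping) match positions are reported,
#' 0-based at the left end of the match. DNA input (T instead of U) is
#' mapped to the RNA alphabet with a warning.
#'
#' @param sequences a [Biostrings::RNAStringSet], a character vector of
#'   sequences, or the path to a FASTA file.
#' @param motif literal motif over A/C/G/U.
#' @return A [MotifReport-class].
#' @examples
#' rep <- scanMotif(c(s1 = "CUGUCUGU", s2 = "AAAA"), "CUGU")
#' motifFraction(rep)          # 50
#' motifPositions(rep)$s1      # 0 4
#' @export
scanMotif <- function(sequences, motif) {
  motif <- toupper(motif)
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (grepl("[^ACGU]", motif))
    stop("motif must be over the RNA alphabet {A, C, G, U}")

  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    sequences <- Biostrings::readRNAStringSet(sequences)
  }
  if (is.character(sequences)) {
    sequences <- toupper(sequences)
    if (any(grepl("T", sequences, fixed = TRUE))) {
      warning("DNA alphabet detected: mapping T to U")
      sequences <- gsub("T", "U", sequences, fixed = TRUE)
    }
    bad <- grepl("[^ACGU]", sequences)
    if (any(bad))
      stop("sequence(s) contain characters outside {A, C, G, U}: ",
           paste(which(bad), collapse = ", "))
    sequences <- Biostrings::RNAStringSet(sequences)
  } else if (methods::is(sequences, "DNAStringSet")) {
    warning("DNA alphabet detected: mapping T to U")
    sequences <- Biostrings::RNAStringSet(sequences)
  }
  if (!methods::is(sequences, "RNAStringSet"))
    stop("sequences must be an RNAStringSet, character vector or FASTA path")
  if (!length(sequences)) stop("empty sequence set")

  pat <- Biostrings::RNAString(motif)
  hits <- Biostrings::vmatchPattern(pat, sequences)
  positions <- lapply(hits, function(h) BiocGenerics::start(h) - 1L)
  if (is.null(names(sequences)))
    names(positions) <- sprintf("seq%04d", seq_along(sequences))
  else names(positions) <- names(sequences)
  withMotif <- vapply(positions, length, integer(1)) > 0L

  methods::new("MotifReport",
    motif = motif,
    nSequences = length(sequences),
    nWithMotif = sum(withMotif),
    positions = positions)
}

#' @describeIn motifFraction Percentage of scanned sequences containing the
#'   motif, rounded half-up to one decimal (176/334 -> 52.7).
#' @param object a [MotifReport-class].
#' @export
setMethod("motifFraction", "MotifReport", function(object, ...) {
  .roundHalfUp(100 * object@nWithMotif / object@nSequences, 1)
})

#' @describeIn motifPositions 0-based match positions per sequence (all
#'   occurrences, overlapping included).
#' @param object a [MotifReport-class].
#' @export
setMethod("motifPositions", "MotifReport", function(object, ...) {
  object@positions
})

setMethod("show", "MotifReport", function(object) {
  cat(sprintf("MotifReport: motif %s found in %d / %d sequences (%.1f%%)\n",
              object@motif, object@nWithMotif, object@nSequences,
              motifFraction(object)))
})
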