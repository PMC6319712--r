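#' MiRNAExperiment: miRNA counts with library metadata
#'
#' A thin subclass of [SummarizedExperiment::SummarizedExperiment] holding a
#' raw miRNA count matrix (assay `"counts"`, features x libraries) with
#' per-library metadata in `colData`: `cellLine`, `compartment` (typically
#' `"CL"`, `"sMV"`, `"Exo"`) and `replicate`. Optional per-feature columns in
#' `rowData` include `passenger` (logical, star-strand flag) and, for
#' simulated data, the planted ground-truth class.
#'
#' Validity requires non-negative integer-valued counts, unique library
#' identifiers, and the three metadata columns.
#'
#' @seealso [MiRNAExperiment()], [simulateMirCounts()]
#' @export
setClass("MiRNAExperiment", contains = "SummarizedExperiment")

setValidity("MiRNAExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(cts)) msg <- c(msg, "counts must be numeric")
    else {
      bad <- which(!is.finite(cts) | cts < 0 | abs(cts - round(cts)) > 1e-8)
      if (length(bad)) {
        idx <- arrayInd(bad[1L], dim(cts))
        msg <- c(msg, sprintf(
          "counts must be non-negative integers; offending cell [%d, %d] = %s",
          idx[1L], idx[2L], format(cts[bad[1L]])))
      }
    }
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("cellLine", "compartment", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("missing colData column(s):", paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "library identifiers (colnames) must be unique")
  if (nrow(object) < 1L || ncol(object) < 1L)
    msg <- c(msg, "at least one feature and one library are required")
  if (is.null(msg)) TRUE else msg
})

#' Two-group differential expression result
#'
#' Holds the per-feature table of a negative-binomial exact-test contrast:
#' group mean TPM, log2 fold change (sign is group B relative to group A),
#' p-value, BH-adjusted FDR and the dysregulation call (`up`/`down`/`ns`),
#' together with the normalization factors, dispersion and thresholds used.
#'
#' @seealso [nbExactTest()], [classifyDysregulated()], [resultTable()]
#' @export
setClass("DifferentialResult",
  representation(
    table = "data.frame",
    groupA = "character",
    groupB = "character",
    dispersion = "numeric",
    normFactors = "numeric",
    thresholds = "list"
  )
)

setValidity("DifferentialResult", function(object) {
  tab <- object@table
  need <- c("feature", "meanA_tpm", "meanB_tpm", "log2fc", "pvalue", "fdr", "call")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    return(paste("result table lacks column(s):", paste(miss, collapse = ", ")))
  if (nrow(tab) && (any(tab$pvalue < 0 | tab$pvalue > 1, na.rm = TRUE) ||
                    any(tab$fdr < 0 | tab$fdr > 1, na.rm = TRUE)))
    return("p-values and FDR must lie in [0, 1]")
  if (nrow(tab) && !all(tab$call %in% c("up", "down", "ns")))
    return("calls must be 'up', 'down' or 'ns'")
  TRUE
})

#' Venn partition of feature sets
#'
#' Exclusive-region partition of k named feature sets: every non-empty
#' membership signature (e.g. `"sMV&Exo"`) maps to the features belonging to
#' exactly those sets. Cells are disjoint and their union is the union of the
#' input sets, so inclusion-exclusion identities hold by construction.
#'
#' @seealso [vennPartition()], [vennCounts()], [cellMembers()]
#' @export
setClass("DistributionReport",
  representation(
    sets = "list",
    cells = "list",
    counts = "integer"
  )
)

setValidity("DistributionReport", function(object) {
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    return("sets must be uniquely named")
  uni <- unique(unlist(object@sets, use.names = FALSE))
  part <- unlist(object@cells, use.names = FALSE)
  if (anyDuplicated(part)) return("partition cells must be disjoint")
  if (!setequal(part, uni)) return("partition cells must cover the set union")
  TRUE
})

#' Signature-correlation classification report
#'
#' Per-sample Pearson correlation of an expression signature with each panel
#' sample, the predicted label under the chosen decision rule, plus the
#' per-stage correlation summary (min/max/mean, the layout used for
#' tumour-stage tables) and the decision threshold.
#'
#' @seealso [predictSamples()], [evaluateClassifier()]
#' @export
setClass("ClassificationReport",
  representation(
    samples = "data.frame",
    threshold = "numeric",
    rule = "character",
    stageSummary = "data.frame",
    signatureSize = "integer"
  )
)

#' Labelled expression panel
#'
#' A features x samples matrix of non-negative normalized expression values
#' with one label per sample (`normal` or tumour stage `I`--`IV`). Stands in
#' for clinical tumour/normal miRNA panels.
#'
#' @seealso [simulateTumourPanel()], [predictSamples()]
#' @export
setClass("LabeledPanel",
  representation(
    exprs = "matrix",
    labels = "factor"
  )
)

setValidity("LabeledPanel", function(object) {
  if (ncol(object@exprs) != length(object@labels))
    return("one label per sample is required")
  if (any(object@exprs < 0, na.rm = TRUE))
    return("expression values must be non-negative")
  if (is.null(rownames(object@exprs)))
    return("panel features must be named")
  TRUE
})

#' Motif scan report
#'
#' Result of scanning a precursor sequence set for a literal RNA motif:
#' number of sequences scanned, number containing at least one occurrence,
#' and all (0-based, overlapping) match positions per sequence.
#'
#' @seealso [scanMotif()], [motifFraction()]
#' @export
setClass("MotifReport",
  representation(
    motif = "character",
    nSequences = "integer",
    nWithMotif = "integer",
    positions = "list"
  )
)

setValidity("MotifReport", function(object) {
  if (object@nWithMotif < 0L || object@nWithMotif > object@nSequences)
    return("0 <= n_with_motif <= n_sequences must hold")
  TRUE
})
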