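#' TPM normalization on total miRNA-mapped reads
#'
#' Scales each library to transcripts per million miRNA-mapped reads:
#' `tpm[f, l] = counts[f, l] / sum(counts[, l]) * 1e6`. The denominator is
#' the miRNA-assigned total of the library, not all sequenced reads, and no
#' length normalization is applied (mature miRNAs are of uniform length).
#' Every column of the result sums to exactly one million before any
#' filtering.
#'
#' @param object a [MiRNAExperiment-class] or a count matrix.
#' @return For a `MiRNAExperiment`, the object with a `"tpm"` assay added;
#'   for a matrix, the TPM matrix.
#' @examples
#' m <- matrix(c(5, 1999995), 2, dimnames = list(c("a", "b"), "L1"))
#' computeTPM(m)["a", ]  # 2.5 TPM
#' @export
computeTPM <- function(object) {
  cts <- if (methods::is(object, "MiRNAExperiment")) mirCounts(object)
         else as.matrix(object)
  totals <- colSums(cts)
  if (any(totals <= 0)) {
    bad <- colnames(cts)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    stop("library with zero total counts: ", paste(bad, collapse = ", "))
  }
  tpm <- sweep(cts, 2, totals, "/") * 1e6
  if (methods::is(object, "MiRNAExperiment")) {
    SummarizedExperiment::assay(object, "tpm") <- tpm
    object
  } else tpm
}

# Return the tpm assay, computing it on the fly when absent.
.tpmOf <- function(object) {
  if (methods::is(object, "MiRNAExperiment")) {
    if ("tpm" %in% SummarizedExperiment::assayNames(object))
      SummarizedExperiment::assay(object, "tpm")
    else
      computeTPM(mirCounts(object))
  } else as.matrix(object)
}

#' Average replicate TPM columns
#'
#' Arithmetic mean of the member libraries of each group, one output column
#' per group. For a [MiRNAExperiment-class] the default grouping is
#' `<cellLine>-<compartment>`.
#'
#' @param expr a [MiRNAExperiment-class] (its `"tpm"` assay is used, computed
#'   if absent) or a numeric matrix.
#' @param grouping vector assigning each column to a group; required for
#'   plain matrices.
#' @return matrix of group-mean values, features x groups.
#' @examples
#' m <- cbind(R1 = c(a = 100), R2 = c(a = 300))
#' averageReplicates(m, c("g", "g"))  # 200
#' @export
averageReplicates <- function(expr, grouping = NULL) {
  tpm <- .tpmOf(expr)
  if (is.null(grouping)) {
    if (!methods::is(expr, "MiRNAExperiment"))
      stop("'grouping' is required for matrix input")
    grouping <- libraryGroups(expr)
  }
  grouping <- as.character(rep_len(grouping, ncol(tpm)))
  groups <- unique(grouping)
  out <- vapply(groups, function(g) {
    cols <- which(grouping == g)
    if (!length(cols)) stop("group with zero member libraries: ", g)
    rowMeans(tpm[, cols, drop = FALSE])
  }, numeric(nrow(tpm)))
  dimnames(out) <- list(rownames(tpm), groups)
  out
}

#' Detection at a TPM threshold
#'
#' A feature is detected in a compartment when its TPM exceeds the threshold
#' (strictly) in at least one replicate (`method = "any-replicate"`, the
#' operational rule; `"mean"` instead requires the replicate-mean TPM to
#' exceed the threshold). Raising the threshold can never add detected
#' features.
#'
#' @param expr a [MiRNAExperiment-class] or a replicate-level TPM matrix.
#' @param threshold detection threshold in TPM (default 5, strict `>`).
#' @param method `"any-replicate"` (default) or `"mean"`.
#' @param grouping per-library group labels (default
#'   `<cellLine>-<compartment>` for a `MiRNAExperiment`).
#' @return logical matrix, features x groups, with attributes `threshold`
#'   and `method`.
#' @examples
#' m <- cbind(R1 = c(a = 6, b = 4.9), R2 = c(a = 0, b = 4.9))
#' detectFeatures(m, grouping = c("CL", "CL"))  # a TRUE, b FALSE
#' @export
detectFeatures <- function(expr, threshold = 5,
                           method = c("any-replicate", "mean"),
                           grouping = NULL) {
  method <- match.arg(method)
  if (threshold < 0) stop("detection threshold must be non-negative")
  tpm <- .tpmOf(expr)
  if (is.null(grouping)) {
    if (!methods::is(expr, "MiRNAExperiment"))
      stop("'grouping' is required for matrix input")
    grouping <- libraryGroups(expr)
  }
  grouping <- as.character(rep_len(grouping, ncol(tpm)))
  groups <- unique(grouping)
  det <- vapply(groups, function(g) {
    sub <- tpm[, grouping == g, drop = FALSE]
    if (method == "any-replicate") apply(sub > threshold, 1, any)
    else rowMeans(sub) > threshold
  }, logical(nrow(tpm)))
  dimnames(det) <- list(rownames(tpm), groups)
  attr(det, "threshold") <- threshold
  attr(det, "method") <- method
  det
}

#' Detected feature sets
#'
#' Convenience wrapper turning a detection matrix into a named list of
#' feature sets, one per group, ready for [vennPartition()].
#'
#' @inheritParams detectFeatures
#' @param ... passed to [detectFeatures()].
#' @return named list of character vectors.
#' @export
detectedSets <- function(expr, ...) {
  det <- detectFeatures(expr, ...)
  lapply(stats::setNames(colnames(det), colnames(det)),
         function(g) rownames(det)[det[, g]])
}
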