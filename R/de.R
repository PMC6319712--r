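#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: adjusted values are monotone in p-value rank,
#' clipped at 1, and equal the raw p-value when only one test is supplied.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values of the same length.
#' @examples
#' adjustFDR(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjustFDR <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Threshold-based dysregulation calls
#'
#' A feature is called `up` when `log2fc > log2fcCut`, `pvalue < pCut` and
#' `fdr < fdrCut`; `down` symmetrically with `log2fc < -log2fcCut`;
#' otherwise `ns`. The defaults are the strict criteria used for cellular
#' dysregulation (|log2FC| > 1, p < 0.05, FDR < 0.05); pass
#' `log2fcCut = log2(1.5)` for the milder fold-change screen used with
#' plasma-style panels.
#'
#' @param result a [DifferentialResult-class].
#' @param log2fcCut,pCut,fdrCut thresholds (strict inequalities).
#' @return the result with its `call` column and thresholds updated.
#' @export
classifyDysregulated <- function(result, log2fcCut = 1, pCut = 0.05,
                                 fdrCut = 0.05) {
  stopifnot(methods::is(result, "DifferentialResult"))
  if (log2fcCut < 0 || pCut <= 0 || fdrCut <= 0)
    stop("thresholds must be positive")
  tab <- result@table
  sig <- tab$pvalue < pCut & tab$fdr < fdrCut
  tab$call <- ifelse(sig & tab$log2fc > log2fcCut, "up",
              ifelse(sig & tab$log2fc < -log2fcCut, "down", "ns"))
  result@table <- tab
  result@thresholds <- list(log2fc = log2fcCut, p = pCut, fdr = fdrCut)
  methods::validObject(result)
  result
}

#' @describeIn resultTable Per-feature result table of a contrast (feature,
#'   group mean TPM, log2fc, pvalue, fdr, call).
#' @param object a [DifferentialResult-class].
#' @export
setMethod("resultTable", "DifferentialResult", function(object, ...) object@table)

#' @describeIn deCalls Dysregulation calls of a contrast as a named
#'   character vector (`up`/`down`/`ns`).
#' @param object a [DifferentialResult-class].
#' @export
setMethod("deCalls", "DifferentialResult", function(object, ...) {
  stats::setNames(object@table$call, object@table$feature)
})

setMethod("show", "DifferentialResult", function(object) {
  tab <- object@table
  cat(sprintf("DifferentialResult: %s (A) vs %s (B), %d features\n",
              paste(object@groupA, collapse = "+"),
              paste(object@groupB, collapse = "+"), nrow(tab)))
  cat(sprintf("dispersion: %s | thresholds: |log2FC| > %g, p < %g, FDR < %g\n",
              paste(format(unique(round(object@dispersion, 4))), collapse = ","),
              object@thresholds$log2fc, object@thresholds$p,
              object@thresholds$fdr))
  cat(sprintf("calls: %d up, %d down, %d ns\n",
              sum(tab$call == "up"), sum(tab$call == "down"),
              sum(tab$call == "ns")))
})

#' Full differential-expression contrast
#'
#' Convenience wrapper running the complete engine for a two-group contrast
#' of a [MiRNAExperiment-class]: restrict to a feature set (typically the
#' detected features), compute TMM factors, estimate the common qCML
#' dispersion, run the NB exact test, adjust by Benjamini-Hochberg and call
#' dysregulation at the given thresholds.
#'
#' @param object a [MiRNAExperiment-class].
#' @param groupA,groupB library name sets, e.g. from [selectLibraries()].
#' @param features optional feature subset.
#' @param ... forwarded to [nbExactTest()].
#' @return A [DifferentialResult-class].
#' @export
differentialExpression <- function(object, groupA, groupB, features = NULL, ...) {
  nbExactTest(object, groupA = groupA, groupB = groupB, features = features, ...)
}
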