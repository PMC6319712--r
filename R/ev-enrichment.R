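#' EV-enrichment labels from two EV-versus-lysate contrasts
#'
#' Combines the up-calls of the sMV-vs-CL and Exo-vs-CL contrasts of one
#' cell line into per-feature enrichment labels: `both` when up in both EV
#' subtypes, `sMV_only` / `Exo_only` when up in exactly one, otherwise
#' `none`. The three enriched labels partition the enriched set.
#'
#' @param deSMV,deExo [DifferentialResult-class] objects for the sMV-vs-CL
#'   and Exo-vs-CL contrasts (CL as group A), computed on the same feature
#'   universe.
#' @return named factor with levels `none`, `sMV_only`, `Exo_only`, `both`.
#' @export
evEnrichmentCall <- function(deSMV, deExo) {
  stopifnot(methods::is(deSMV, "DifferentialResult"),
            methods::is(deExo, "DifferentialResult"))
  fa <- deSMV@table$feature
  fb <- deExo@table$feature
  if (!setequal(fa, fb))
    stop("the two contrasts must cover the same feature universe")
  upS <- fa[deSMV@table$call == "up"]
  upE <- fb[deExo@table$call == "up"]
  lab <- ifelse(fa %in% upS & fa %in% upE, "both",
         ifelse(fa %in% upS, "sMV_only",
         ifelse(fa %in% upE, "Exo_only", "none")))
  factor(stats::setNames(lab, fa),
         levels = c("none", "sMV_only", "Exo_only", "both"))
}

#' Screen for cell-silent but EV-enriched miRNAs
#'
#' Features that fail the lysate detection rule (not detected in CL) yet are
#' EV-enriched, partitioned by the EV subtype(s) carrying the enrichment.
#' The total is the sum of the three parts by construction.
#'
#' @param clDetected named logical vector: detection status in the cell
#'   lysate (e.g. one column of [detectFeatures()]).
#' @param enrichment named factor from [evEnrichmentCall()] over the same
#'   features.
#' @return list with members `sMV_only`, `Exo_only`, `both` (feature
#'   vectors), their `counts`, and `total`.
#' @export
cellSilentEvScreen <- function(clDetected, enrichment) {
  feats <- names(enrichment)
  if (is.null(feats) || is.null(names(clDetected)))
    stop("both inputs must be named by feature")
  common <- intersect(feats, names(clDetected))
  silent <- common[!clDetected[common] & enrichment[common] != "none"]
  parts <- lapply(c(sMV_only = "sMV_only", Exo_only = "Exo_only", both = "both"),
                  function(lv) silent[enrichment[silent] == lv])
  counts <- vapply(parts, length, integer(1))
  c(parts, list(counts = counts, total = sum(counts)))
}
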