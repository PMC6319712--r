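#' Pearson correlation over a shared feature set
#'
#' Product-moment correlation of two named expression profiles over the
#' intersection of their features. Requires >= 3 shared features and
#' non-zero variance in both vectors (a constant profile has no defined
#' correlation and raises an error rather than returning 0).
#'
#' @param x,y named numeric profiles.
#' @return correlation coefficient in \[-1, 1\].
#' @examples
#' pearsonCC(c(a = 1, b = 2, c = 3), c(a = 2, b = 1, c = 4))
#' @export
pearsonCC <- function(x, y) {
  if (is.null(names(x)) || is.null(names(y)))
    stop("profiles must be named by feature")
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3L)
    stop("fewer than 3 shared features")
  xs <- x[shared]
  ys <- y[shared]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("undefined correlation: zero-variance profile")
  stats::cor(xs, ys, method = "pearson")
}

#' Build an expression signature from pipeline results
#'
#' Restricts a compartment-mean TPM profile to a chosen feature set:
#' everything detected (`all_detected`), the dysregulated miRNAs
#' (`dysregulated`: up or down calls of a lysate contrast), or the
#' EV-enriched miRNAs (`ev_enriched`: any non-`none` enrichment label).
#'
#' @param exprMeans named numeric vector (or one column of
#'   [averageReplicates()]): mean TPM per feature of the source compartment.
#' @param selection feature-selection mode.
#' @param detected named logical detection vector (for `all_detected`).
#' @param deResult a [DifferentialResult-class] (for `dysregulated`).
#' @param enrichment named factor from [evEnrichmentCall()], or a list of
#'   them whose enriched sets are unioned (for `ev_enriched`).
#' @return named numeric signature profile.
#' @export
buildSignature <- function(exprMeans,
                           selection = c("all_detected", "dysregulated",
                                         "ev_enriched"),
                           detected = NULL, deResult = NULL,
                           enrichment = NULL) {
  selection <- match.arg(selection)
  feats <- switch(selection,
    all_detected = {
      if (is.null(detected)) stop("'detected' is required for all_detected")
      names(detected)[detected]
    },
    dysregulated = {
      if (is.null(deResult)) stop("'deResult' is required for dysregulated")
      calls <- deCalls(deResult)
      names(calls)[calls %in% c("up", "down")]
    },
    ev_enriched = {
      if (is.null(enrichment)) stop("'enrichment' is required for ev_enriched")
      if (!is.list(enrichment)) enrichment <- list(enrichment)
      unique(unlist(lapply(enrichment, function(e)
        names(e)[e != "none"]), use.names = FALSE))
    })
  feats <- intersect(feats, names(exprMeans))
  if (!length(feats)) stop("empty signature selection")
  exprMeans[feats]
}

#' Predict tumour/normal labels by signature correlation
#'
#' Correlates the signature with every panel sample (over the intersection
#' of their features; features absent from the panel are dropped, not
#' zero-filled) and predicts `tumour` when the coefficient exceeds the
#' decision threshold. Under the default `max-normal` rule the threshold is
#' the largest coefficient among the calibration normals, so specificity on
#' those normals is 100% by construction; held-out normals estimate true
#' specificity. Alternative rules: a `fixed` threshold, or `mean-sd`
#' (normal mean + k standard deviations).
#'
#' @param panel a [LabeledPanel-class].
#' @param signature named numeric profile (>= 3 features overlapping the
#'   panel).
#' @param rule decision rule.
#' @param tau fixed threshold (rule `"fixed"`).
#' @param k multiplier for rule `"mean-sd"`.
#' @param transform correlate raw TPM (`"none"`, default) or
#'   `log2(TPM + 1)`.
#' @param calibration sample names (or indices) of the normals used to set
#'   the threshold; defaults to every normal in the panel.
#' @return A [ClassificationReport-class]; per-sample rows carry the
#'   coefficient, prediction and a `calibration` flag, and the stage summary
#'   gives min/max/mean correlation per label.
#' @export
predictSamples <- function(panel, signature,
                           rule = c("max-normal", "fixed", "mean-sd"),
                           tau = NULL, k = 2,
                           transform = c("none", "log2"),
                           calibration = NULL) {
  stopifnot(methods::is(panel, "LabeledPanel"))
  rule <- match.arg(rule)
  transform <- match.arg(transform)
  exprs <- panelExprs(panel)
  labels <- panelLabels(panel)
  sig <- signature
  if (transform == "log2") {
    sig <- log2(sig + 1)
    exprs <- log2(exprs + 1)
  }
  r <- vapply(seq_len(ncol(exprs)), function(j) {
    pearsonCC(sig, exprs[, j])
  }, numeric(1))
  names(r) <- colnames(exprs)

  normals <- colnames(exprs)[labels == "normal"]
  if (is.null(calibration)) {
    calibration <- if (rule == "max-normal" || rule == "mean-sd") normals
                   else character(0)
  } else if (is.numeric(calibration)) {
    calibration <- colnames(exprs)[calibration]
  }
  threshold <- switch(rule,
    "max-normal" = {
      if (!length(calibration))
        stop("the max-normal rule needs >= 1 calibration normal")
      max(r[calibration])
    },
    "fixed" = {
      if (is.null(tau)) stop("rule 'fixed' needs 'tau'")
      tau
    },
    "mean-sd" = {
      if (length(calibration) < 2L)
        stop("the mean-sd rule needs >= 2 calibration normals")
      mean(r[calibration]) + k * stats::sd(r[calibration])
    })

  predicted <- ifelse(r > threshold, "tumour", "normal")
  samples <- data.frame(
    sample = colnames(exprs),
    label = as.character(labels),
    r = unname(r),
    predicted = unname(predicted),
    calibration = colnames(exprs) %in% calibration,
    row.names = NULL, stringsAsFactors = FALSE)

  stageSummary <- do.call(rbind, lapply(levels(labels), function(lv) {
    rs <- r[labels == lv]
    if (!length(rs)) return(NULL)
    data.frame(label = lv, n = length(rs), min = min(rs), max = max(rs),
               mean = mean(rs), stringsAsFactors = FALSE)
  }))
  methods::new("ClassificationReport",
    samples = samples, threshold = threshold, rule = rule,
    stageSummary = stageSummary, signatureSize = length(signature))
}

#' @describeIn predictions Per-sample prediction table of a classification
#'   report.
#' @param object a [ClassificationReport-class].
#' @export
setMethod("predictions", "ClassificationReport", function(object, ...) {
  object@samples
})

setMethod("show", "ClassificationReport", function(object) {
  cat(sprintf(
    "ClassificationReport: %d samples, rule '%s', threshold r > %.4f, %d signature features\n",
    nrow(object@samples), object@rule, object@threshold,
    object@signatureSize))
  print(object@stageSummary, row.names = FALSE)
})

#' Sensitivity and specificity of tumour/normal predictions
#'
#' `sensSpec()` computes the two rates from predicted and true label
#' vectors; `evaluateClassifier()` applies it to a
#' [ClassificationReport-class], excluding the calibration normals (whose
#' specificity is 100% by construction under the max-normal rule) unless
#' `includeCalibration = TRUE`. Percentages are rounded half-up to one
#' decimal; a metric without any eligible sample is `NA` (flagged
#' undefined).
#'
#' @param predicted character vector of `"tumour"`/`"normal"` predictions.
#' @param truth true labels; anything other than `"normal"` counts as
#'   tumour.
#' @return list with `nTumour`, `nNormal`, `tumourDetected`,
#'   `normalDetected`, `sensitivity` and `specificity` (percent, 1 d.p.).
#' @examples
#' sensSpec(rep(c("tumour", "normal"), c(564, 30)),
#'          rep("tumour", 594))$sensitivity  # 94.9
#' @export
sensSpec <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  isTumour <- truth != "normal"
  nT <- sum(isTumour)
  nN <- sum(!isTumour)
  tp <- sum(predicted == "tumour" & isTumour)
  tn <- sum(predicted == "normal" & !isTumour)
  list(nTumour = nT, nNormal = nN, tumourDetected = tp, normalDetected = tn,
       sensitivity = if (nT) .roundHalfUp(100 * tp / nT, 1) else NA_real_,
       specificity = if (nN) .roundHalfUp(100 * tn / nN, 1) else NA_real_)
}

#' @rdname sensSpec
#' @param report a [ClassificationReport-class].
#' @param includeCalibration evaluate calibration normals too?
#' @export
evaluateClassifier <- function(report, includeCalibration = FALSE) {
  stopifnot(methods::is(report, "ClassificationReport"))
  tab <- report@samples
  if (!includeCalibration) tab <- tab[!tab$calibration, , drop = FALSE]
  metrics <- sensSpec(tab$predicted, tab$label)
  stages <- setdiff(unique(tab$label), "normal")
  metrics$perStage <- do.call(rbind, lapply(stages, function(st) {
    sub <- tab[tab$label == st, , drop = FALSE]
    data.frame(stage = st, n = nrow(sub),
               detected = sum(sub$predicted == "tumour"),
               sensitivity = .roundHalfUp(
                 100 * mean(sub$predicted == "tumour"), 1),
               stringsAsFactors = FALSE)
  }))
  metrics
}
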