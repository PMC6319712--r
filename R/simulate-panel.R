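#' Simulate a labelled tumour/normal expression panel
#'
#' Generates per-sample expression profiles over the feature universe of a
#' signature. Normal samples are multiplicative log-normal perturbations of a
#' shared baseline profile; tumour samples blend the baseline toward the
#' signature, `(1 - w) * baseline + w * signature`, before the same noise is
#' applied, so tumours correlate with the signature more strongly than
#' normals do. Default sample counts follow a typical clinical cohort: 11
#' normals and stage I--IV tumour groups of 103/223/179/89.
#'
#' @param signature named numeric signature profile (TPM scale, >= 3
#'   features), e.g. from [buildSignature()].
#' @param baseline optional named baseline (normal-tissue) profile over the
#'   same universe; by default an independent log-normal profile is drawn,
#'   which decorrelates normals from the signature.
#' @param nNormals number of normal samples (>= 1).
#' @param nPerStage named integer vector of tumour counts for stages I--IV.
#' @param signatureWeight mixture weight w in \[0, 1\]; a scalar, or one value
#'   per stage to let the blend increase with stage.
#' @param noiseSd standard deviation of the log-normal noise (natural-log
#'   scale).
#' @param seed integer random seed.
#' @return A [LabeledPanel-class].
#' @examples
#' sig <- stats::setNames(10^rnorm(50, 2, 1), sprintf("miR-%03d-5p", 1:50))
#' panel <- simulateTumourPanel(sig, nNormals = 5,
#'                              nPerStage = c(I = 5, II = 5, III = 5, IV = 5))
#' table(panelLabels(panel))
#' @export
simulateTumourPanel <- function(signature,
                                baseline = NULL,
                                nNormals = 11L,
                                nPerStage = c(I = 103L, II = 223L,
                                              III = 179L, IV = 89L),
                                signatureWeight = 0.6,
                                noiseSd = 0.3,
                                seed = 1L) {
  if (length(signature) < 3L || is.null(names(signature)))
    stop("signature must be a named numeric vector with >= 3 features")
  if (any(signature < 0)) stop("signature values must be non-negative")
  if (nNormals < 1L) stop("at least one normal sample is required")
  stages <- c("I", "II", "III", "IV")
  nPerStage <- stats::setNames(as.integer(rep_len(nPerStage, 4L)), stages)
  w <- rep_len(signatureWeight, 4L)
  if (any(w < 0 | w > 1)) stop("signatureWeight must lie in [0, 1]")
  .assertScalarNumber(noiseSd, "noiseSd", lower = 0)

  set.seed(as.integer(seed))
  features <- names(signature)
  if (is.null(baseline)) {
    baseline <- stats::setNames(10^stats::rnorm(length(features), 2, 1), features)
  } else {
    if (!all(features %in% names(baseline)))
      stop("baseline must cover the signature's feature universe")
    baseline <- baseline[features]
  }

  nTum <- sum(nPerStage)
  labels <- factor(c(rep("normal", nNormals),
                     rep(stages, times = nPerStage)),
                   levels = c("normal", stages))
  nSamp <- length(labels)
  exprs <- matrix(0, nrow = length(features), ncol = nSamp,
                  dimnames = list(features,
                                  sprintf("%s-%03d", labels, seq_len(nSamp))))
  for (j in seq_len(nSamp)) {
    mean_j <- if (labels[j] == "normal") baseline
              else {
                wj <- w[match(as.character(labels[j]), stages)]
                (1 - wj) * baseline + wj * signature
              }
    noise <- if (noiseSd > 0) exp(stats::rnorm(length(features), 0, noiseSd))
             else 1
    exprs[, j] <- mean_j * noise
  }
  methods::new("LabeledPanel", exprs = exprs, labels = labels)
}

#' @describeIn panelExprs Expression matrix (features x samples) of a panel.
#' @param object a [LabeledPanel-class].
#' @export
setMethod("panelExprs", "LabeledPanel", function(object, ...) object@exprs)

#' @describeIn panelLabels Sample labels of a panel.
#' @param object a [LabeledPanel-class].
#' @export
setMethod("panelLabels", "LabeledPanel", function(object, ...) object@labels)

setMethod("show", "LabeledPanel", function(object) {
  cat(sprintf("LabeledPanel: %d features x %d samples\n",
              nrow(object@exprs), ncol(object@exprs)))
  print(table(object@labels))
})
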