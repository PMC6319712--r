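# Two-group negative-binomial exact test, conditional on the group totals of
# libraries equalized to a common effective size.

# Unnormalized log conditional probability of splitting total s into (a, s-a)
# between groups of rA = nA/phi and rB = nB/phi NB units, for a = 0..s.
# Written via lgamma rather than dnbinom so the test stays independent of the
# distribution functions used by the enumeration oracle in the test-suite.
# Built from per-group half-terms so that exchangeable groups (rA == rB) give
# a bitwise-symmetric pmf: near-tie splits must not flip with group order.
.splitLogPmfNB <- function(s, rA, rB) {
  a <- 0:s
  tA <- lgamma(a + rA) - lgamma(a + 1)
  tB <- if (rB == rA) tA else lgamma(a + rB) - lgamma(a + 1)
  tA + rev(tB)
}

# phi = 0: conditional distribution is Binomial(s, nA / (nA + nB)).
.splitLogPmfPois <- function(s, nA, nB) {
  a <- 0:s
  tA <- a * log(nA / (nA + nB)) - lgamma(a + 1)
  tB <- if (nB == nA) tA else a * log(nB / (nA + nB)) - lgamma(a + 1)
  tA + rev(tB)
}

# Exact two-sided p for one feature: sum of conditional probabilities of all
# splits no more likely than the observed one (ties within 1e-12 relative
# probability included). For totals above maxExact an analytic tail
# approximation is used: conditional beta (gamma representation of NB group
# sums) for phi > 0, binomial double tail for phi = 0.
.exactPval <- function(sA, sB, nA, nB, phi, maxExact = 20000L) {
  s <- sA + sB
  if (s == 0) return(1)
  if (s <= maxExact) {
    lp <- if (phi > 0) .splitLogPmfNB(s, nA / phi, nB / phi)
          else .splitLogPmfPois(s, nA, nB)
    lp <- lp - .logSumExp(lp)
    lobs <- lp[sA + 1L]
    min(1, sum(exp(lp[lp <= lobs + log1p(1e-12)])))
  } else if (phi > 0) {
    x <- (sA + 0.5) / (s + 1)
    pl <- stats::pbeta(x, nA / phi, nB / phi)
    min(1, 2 * min(pl, 1 - pl))
  } else {
    pA <- nA / (nA + nB)
    pl <- stats::pbinom(sA, s, pA)
    pu <- stats::pbinom(sA - 1, s, pA, lower.tail = FALSE)
    min(1, 2 * min(pl, pu))
  }
}

#' Negative-binomial exact test for a two-group contrast
#'
#' For each feature, libraries are equalized to a common effective size
#' (raw size times TMM factor, proportionally rescaled), the equalized
#' counts are summed within each group, and a two-sided exact p-value is
#' computed from the conditional distribution of the group-A sum given the
#' total under NB sampling with dispersion phi: the p-value is the summed
#' probability of all splits as likely or less likely than the observed one.
#' phi = 0 reduces to a conditional binomial (Poisson) test. Swapping the
#' groups negates the log2 fold change and leaves p unchanged.
#'
#' Log2 fold changes are computed from the equalized group means augmented
#' by a prior count of 0.5, so features observed in only one group get large
#' but finite values; the sign is group B relative to group A.
#'
#' @param object a [MiRNAExperiment-class] or count matrix.
#' @param groupA,groupB disjoint sets of library names (or column indices).
#' @param dispersion NB dispersion phi: a scalar or per-feature vector; by
#'   default the common qCML estimate from the two groups.
#' @param normFactors per-library normalization factors covering both
#'   groups; by default TMM factors computed on the contrast's libraries.
#' @param features optional subset of features to test (e.g. the detected
#'   set); defaults to all.
#' @param priorCount prior count added to each equalized group mean for the
#'   fold-change computation.
#' @param log2fcCut,pCut,fdrCut thresholds forwarded to
#'   [classifyDysregulated()] for the initial calls.
#' @param maxExact largest conditional total enumerated exactly; beyond it
#'   the analytic tail approximation is used.
#' @return A [DifferentialResult-class]; FDR is Benjamini-Hochberg across
#'   the tested features.
#' @seealso [estimateCommonDispersion()], [tmmFactors()],
#'   [classifyDysregulated()]
#' @export
nbExactTest <- function(object, groupA, groupB,
                        dispersion = NULL, normFactors = NULL,
                        features = NULL, priorCount = 0.5,
                        log2fcCut = 1, pCut = 0.05, fdrCut = 0.05,
                        maxExact = 20000L) {
  cts <- if (methods::is(object, "MiRNAExperiment")) mirCounts(object)
         else as.matrix(object)
  if (is.null(colnames(cts)))
    colnames(cts) <- sprintf("lib%d", seq_len(ncol(cts)))
  groupA <- .resolveLibs(cts, groupA, "groupA")
  groupB <- .resolveLibs(cts, groupB, "groupB")
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  cols <- c(groupA, groupB)
  sub <- cts[, cols, drop = FALSE]
  if (!is.null(features)) sub <- sub[features, , drop = FALSE]

  if (is.null(normFactors)) {
    normFactors <- if (ncol(sub) >= 2) tmmFactors(sub) else rep(1, ncol(sub))
  } else {
    if (!is.null(names(normFactors))) normFactors <- normFactors[cols]
    if (length(normFactors) != ncol(sub) || any(normFactors <= 0))
      stop("normFactors must be positive and cover both groups")
  }
  if (is.null(dispersion)) {
    grp <- rep(c("A", "B"), c(length(groupA), length(groupB)))
    dispersion <- if (max(table(grp)) >= 2)
      estimateCommonDispersion(sub, grp, normFactors = normFactors)
    else stop("no replicates in either group: supply 'dispersion'")
  }
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  phi <- rep_len(dispersion, nrow(sub))

  eq <- .pseudoCounts(sub, normFactors)
  pseudo <- eq$pseudo
  iA <- seq_along(groupA)
  iB <- length(groupA) + seq_along(groupB)
  nA <- length(groupA)
  nB <- length(groupB)
  sAraw <- rowSums(pseudo[, iA, drop = FALSE])
  sBraw <- rowSums(pseudo[, iB, drop = FALSE])
  sA <- round(sAraw)
  sB <- round(sBraw)

  pvals <- vapply(seq_len(nrow(sub)), function(f) {
    .exactPval(sA[f], sB[f], nA, nB, phi[f], maxExact = maxExact)
  }, numeric(1))

  mA <- sAraw / nA + priorCount
  mB <- sBraw / nB + priorCount
  log2fc <- log2(mB / mA)
  tab <- data.frame(
    feature = rownames(sub),
    meanA_tpm = (sAraw / nA) / eq$commonSize * 1e6,
    meanB_tpm = (sBraw / nB) / eq$commonSize * 1e6,
    log2fc = log2fc,
    pvalue = pvals,
    fdr = adjustFDR(pvals),
    call = "ns",
    row.names = NULL, stringsAsFactors = FALSE
  )
  res <- methods::new("DifferentialResult",
    table = tab,
    groupA = groupA, groupB = groupB,
    dispersion = unname(dispersion),
    normFactors = stats::setNames(normFactors, cols),
    thresholds = list(log2fc = log2fcCut, p = pCut, fdr = fdrCut))
  classifyDysregulated(res, log2fcCut = log2fcCut, pCut = pCut, fdrCut = fdrCut)
}

.resolveLibs <- function(cts, libs, what) {
  if (is.numeric(libs)) libs <- colnames(cts)[libs]
  if (is.null(libs) || !length(libs))
    stop(sprintf("'%s' must name at least one library", what))
  miss <- setdiff(libs, colnames(cts))
  if (length(miss))
    stop(sprintf("unknown libraries in '%s': %s", what,
                 paste(miss, collapse = ", ")))
  libs
}
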