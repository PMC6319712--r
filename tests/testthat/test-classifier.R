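test_that("Pearson coefficient matches hand-expanded sums and is affine
           invariant", {
  x <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  y <- c(a = 2, b = 1, c = 4, d = 3, e = 6)
  # hand-expanded product-moment arithmetic
  n <- 5
  num <- sum(x * y) - sum(x) * sum(y) / n
  den <- sqrt((sum(x^2) - sum(x)^2 / n) * (sum(y^2) - sum(y)^2 / n))
  expect_equal(pearsonCC(x, y), num / den, tolerance = 1e-12)

  expect_equal(pearsonCC(x, x), 1)
  expect_equal(pearsonCC(x, -2 * x + 7), -1)
  expect_equal(pearsonCC(x, 3 * y + 10), pearsonCC(x, y), tolerance = 1e-12)

  expect_error(pearsonCC(x, c(a = 1, b = 1, c = 1, d = 1, e = 1)),
               "zero-variance")
  expect_error(pearsonCC(c(a = 1, b = 2), c(a = 1, b = 2)), "3 shared")
  # correlation is computed over the name intersection only
  expect_equal(pearsonCC(x, c(y, zz = 99)), num / den, tolerance = 1e-12)
})

test_that("signatures restrict to the selected feature set", {
  means <- setNames(c(10, 20, 30, 40, 50), sprintf("m%d", 1:5))
  det <- setNames(c(TRUE, TRUE, FALSE, TRUE, FALSE), names(means))
  sig <- buildSignature(means, "all_detected", detected = det)
  expect_setequal(names(sig), c("m1", "m2", "m4"))
  expect_equal(unname(sig["m4"]), 40)

  tab <- data.frame(feature = names(means), meanA_tpm = 1, meanB_tpm = 1,
                    log2fc = c(2, -2, 0, 0, 2), pvalue = 1e-4, fdr = 1e-4,
                    call = c("up", "down", "ns", "ns", "up"),
                    stringsAsFactors = FALSE)
  de <- methods::new("DifferentialResult", table = tab, groupA = "A",
                     groupB = "B", dispersion = 0.1,
                     normFactors = c(A = 1, B = 1),
                     thresholds = list(log2fc = 1, p = 0.05, fdr = 0.05))
  expect_setequal(names(buildSignature(means, "dysregulated", deResult = de)),
                  c("m1", "m2", "m5"))

  lab <- factor(setNames(c("both", "none", "sMV_only", "none", "Exo_only"),
                         names(means)),
                levels = c("none", "sMV_only", "Exo_only", "both"))
  expect_setequal(names(buildSignature(means, "ev_enriched",
                                       enrichment = lab)),
                  c("m1", "m3", "m5"))
  expect_error(buildSignature(means, "all_detected",
                              detected = setNames(rep(FALSE, 5), names(means))),
               "empty")
})

test_that("max-normal rule calibrates specificity by construction", {
  set.seed(121)
  sig <- setNames(10^rnorm(80, 2, 1), sprintf("miR-%03d", 1:80))
  panel <- simulateTumourPanel(sig, nNormals = 8,
                               nPerStage = c(4, 4, 4, 4),
                               signatureWeight = 0.7, noiseSd = 0.3,
                               seed = 21)
  rep <- predictSamples(panel, sig)
  tab <- predictions(rep)
  calib <- tab[tab$calibration, ]
  expect_true(all(calib$predicted == "normal"))   # tau = their max r
  expect_equal(rep@threshold, max(calib$r))
  # per-stage summary covers every label present
  expect_setequal(rep@stageSummary$label,
                  c("normal", "I", "II", "III", "IV"))

  # samples identical to the signature correlate perfectly and are tumours
  exprs <- cbind(panelExprs(panel)[, 1:3],
                 T1 = sig[rownames(panelExprs(panel))],
                 T2 = sig[rownames(panelExprs(panel))])
  ident <- methods::new("LabeledPanel", exprs = exprs,
                        labels = factor(c("normal", "normal", "normal",
                                          "II", "III"),
                                        levels = c("normal", "I", "II",
                                                   "III", "IV")))
  rep2 <- predictSamples(ident, sig)
  tab2 <- predictions(rep2)
  expect_equal(tab2$r[4:5], c(1, 1))
  expect_true(all(tab2$predicted[4:5] == "tumour"))
})

test_that("raising the threshold never increases sensitivity", {
  set.seed(122)
  sig <- setNames(10^rnorm(60, 2, 1), sprintf("miR-%03d", 1:60))
  panel <- simulateTumourPanel(sig, nNormals = 5, nPerStage = c(10, 10, 10, 10),
                               signatureWeight = 0.5, noiseSd = 0.4, seed = 22)
  taus <- seq(-0.5, 1, by = 0.1)
  sens <- vapply(taus, function(tau) {
    m <- evaluateClassifier(predictSamples(panel, sig, rule = "fixed",
                                           tau = tau))
    m$tumourDetected
  }, numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("sensitivity and specificity follow the confusion arithmetic", {
  m <- sensSpec(rep(c("tumour", "normal"), c(564, 30)), rep("tumour", 594))
  expect_equal(m$sensitivity, 94.9)
  m2 <- sensSpec(rep(c("tumour", "normal"), c(572, 22)), rep("tumour", 594))
  expect_equal(m2$sensitivity, 96.3)

  perfect <- sensSpec(c("tumour", "tumour", "normal"),
                      c("II", "IV", "normal"))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)

  none <- sensSpec(rep("normal", 3), rep("normal", 3))
  expect_true(is.na(none$sensitivity))   # undefined without tumours

  # random predictions on a balanced panel sit near 50%
  set.seed(23)
  truth <- rep(c("tumour", "normal"), each = 2000)
  pred <- sample(c("tumour", "normal"), 4000, replace = TRUE)
  m3 <- sensSpec(pred, truth)
  expect_lt(abs(m3$sensitivity - 50), 5)
  expect_lt(abs(m3$specificity - 50), 5)
})

test_that("synthetic panels are classified with high sensitivity and
           held-out specificity", {
  set.seed(123)
  sig <- setNames(10^rnorm(97, 2, 1), sprintf("miR-%03d", 1:97))
  tp <- fn <- tn <- fp <- 0
  for (s in 1:5) {
    panel <- simulateTumourPanel(sig, nNormals = 31,
                                 nPerStage = c(10, 10, 10, 10),
                                 signatureWeight = 0.6, noiseSd = 0.3,
                                 seed = 40 + s)
    calib <- colnames(panelExprs(panel))[
      which(panelLabels(panel) == "normal")[1:11]]
    m <- evaluateClassifier(predictSamples(panel, sig, calibration = calib))
    tp <- tp + m$tumourDetected; fn <- fn + m$nTumour - m$tumourDetected
    tn <- tn + m$normalDetected; fp <- fp + m$nNormal - m$normalDetected
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_gte(tn / (tn + fp), 0.85)   # full 20-seed sweep in the acceptance suite
})
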