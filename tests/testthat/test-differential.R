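test_that("TMM factors are 1 for scaled or identical libraries", {
  set.seed(3)
  base <- rpois(200, 100)
  cts <- cbind(L1 = base, L2 = base * 3, L3 = base)
  rownames(cts) <- sprintf("f%03d", 1:200)
  f <- tmmFactors(cts, reference = 1)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-12)
})

test_that("TMM matches an independent direct implementation and edgeR", {
  set.seed(4)
  cts <- matrix(rnbinom(20 * 2, mu = 10^runif(20, 1, 3), size = 5), 20, 2,
                dimnames = list(sprintf("f%02d", 1:20), c("L1", "L2")))
  cts[cts == 0] <- 1
  f <- tmmFactors(cts, reference = 1)
  raw <- oracleTMMPair(cts[, 2], cts[, 1])   # unnormalized pair factor
  expect_equal(unname(f[2] / f[1]), raw, tolerance = 1e-10)

  big <- matrix(rnbinom(1000 * 5, mu = rep(10^rnorm(1000, 2, 1), 5), size = 5),
                ncol = 5, dimnames = list(sprintf("g%04d", 1:1000), NULL))
  expect_equal(unname(tmmFactors(big, reference = 1)),
               unname(edgeR::calcNormFactors(big, refColumn = 1)),
               tolerance = 1e-10)

  disjoint <- cbind(L1 = c(5, 5, 0, 0), L2 = c(0, 0, 5, 5))
  rownames(disjoint) <- letters[1:4]
  expect_error(tmmFactors(disjoint, reference = 1), "no non-zero features")
})

test_that("qCML dispersion recovers the truth and matches edgeR", {
  set.seed(5)
  grp <- c("A", "A", "B", "B")

  # Poisson data: estimate collapses toward zero
  yp <- matrix(rpois(200 * 4, rep(10^rnorm(200, 2, 0.5), 4)), ncol = 4,
               dimnames = list(sprintf("f%03d", 1:200), NULL))
  expect_lte(estimateCommonDispersion(yp, grp, normFactors = rep(1, 4)), 0.05)

  # NB truth 0.2 recovered within 25%
  yn <- matrix(rnbinom(500 * 4, mu = rep(10^rnorm(500, 2, 0.5), 4),
                       size = 1 / 0.2), ncol = 4,
               dimnames = list(sprintf("f%03d", 1:500), NULL))
  phi <- estimateCommonDispersion(yn, grp, normFactors = rep(1, 4))
  expect_lt(abs(phi - 0.2) / 0.2, 0.25)

  d <- edgeR::estimateCommonDisp(edgeR::DGEList(yn, group = grp))
  expect_lt(abs(phi - d$common.dispersion) / d$common.dispersion, 0.05)

  # no excess variance at all
  same <- matrix(rep(c(3, 10, 40, 100), each = 4), ncol = 4, byrow = TRUE,
                 dimnames = list(letters[1:4], NULL))
  expect_equal(estimateCommonDispersion(same, grp, normFactors = rep(1, 4)), 0)

  expect_error(estimateCommonDispersion(yn[, c(1, 3)], c("A", "B")),
               "replicates")
})

test_that("tagwise dispersions shrink toward the common value", {
  set.seed(6)
  mu <- rep(100, 4)
  y <- rbind(
    matrix(rnbinom(50 * 4, mu = 100, size = 1 / 0.05), ncol = 4),
    matrix(rnbinom(50 * 4, mu = 100, size = 1 / 0.6), ncol = 4))
  rownames(y) <- sprintf("f%03d", 1:100)
  est <- estimateCommonDispersion(y, c("A", "A", "B", "B"),
                                  normFactors = rep(1, 4), tagwise = TRUE)
  expect_length(est$tagwise, 100)
  expect_true(all(est$tagwise >= 0))
  # the high-dispersion block ends up above the low-dispersion block
  expect_gt(mean(est$tagwise[51:100]), mean(est$tagwise[1:50]))
})

test_that("exact test equals the enumeration oracle for all small totals", {
  for (phi in c(0, 0.1, 0.5)) {
    for (design in list(c(2, 2), c(3, 2))) {
      nA <- design[1]; nB <- design[2]
      for (s in 0:30) {
        for (sA in 0:s) {
          p <- vesiclemiR:::.exactPval(sA, s - sA, nA, nB, phi)
          expect_equal(p, oracleExactP(sA, s - sA, nA, nB, phi),
                       tolerance = 1e-10,
                       label = sprintf("phi=%g nA=%d nB=%d sA=%d sB=%d",
                                       phi, nA, nB, sA, s - sA))
        }
      }
    }
  }
})

test_that("symmetric splits give p = 1 and log2FC 0; swaps negate log2FC", {
  core <- matrix(c(8, 8, 8, 8), 1, dimnames = list("f1", NULL))
  res <- nbExactTest(rbind(core, filler = c(100, 100, 100, 100)),
                     groupA = 1:2, groupB = 3:4,
                     dispersion = 0.1, normFactors = rep(1, 4))
  tab <- resultTable(res)
  expect_equal(tab$pvalue[1], 1)
  expect_equal(tab$log2fc[1], 0)

  set.seed(7)
  cts <- equalTotalMatrix(matrix(rnbinom(50 * 4, mu = 40, size = 10), ncol = 4,
                                 dimnames = list(sprintf("f%02d", 1:50), NULL)))
  a <- nbExactTest(cts, 1:2, 3:4, dispersion = 0.2, normFactors = rep(1, 4))
  b <- nbExactTest(cts, 3:4, 1:2, dispersion = 0.2, normFactors = rep(1, 4))
  expect_equal(resultTable(a)$pvalue, resultTable(b)$pvalue, tolerance = 1e-12)
  expect_equal(resultTable(a)$log2fc, -resultTable(b)$log2fc,
               tolerance = 1e-12)
})

test_that("exact test agrees with edgeR's on equalized libraries", {
  set.seed(8)
  core <- matrix(rnbinom(300 * 4, mu = rep(10^rnorm(300, 1.5, 0.5), 4),
                         size = 1 / 0.1), ncol = 4,
                 dimnames = list(sprintf("f%03d", 1:300), NULL))
  cts <- equalTotalMatrix(core)
  mine <- resultTable(nbExactTest(cts, 1:2, 3:4, dispersion = 0.1,
                                  normFactors = rep(1, 4)))$pvalue[1:300]
  d <- edgeR::DGEList(cts, group = c("A", "A", "B", "B"))
  d$samples$norm.factors <- 1
  ref <- edgeR::exactTest(d, dispersion = 0.1)$table$PValue[1:300]
  expect_equal(mine, ref, tolerance = 1e-4)
})

test_that("null simulations keep the empirical size near nominal", {
  # quick two-seed version; the full three-phi sweep runs in the acceptance
  # suite
  sizes <- vapply(1:2, function(s) {
    cfg <- simulationConfig(nMirnas = 1000, dispersion = 0.1,
                            fracDysregulated = 0, fracEvEnriched = 0,
                            fracCellSilentEv = 0, seed = 30 + s)
    se <- simulateMirCounts(cfg)
    A <- selectLibraries(se, cellLine = "lineA", compartment = "CL")
    B <- selectLibraries(se, cellLine = "lineB", compartment = "CL")
    mean(resultTable(nbExactTest(se, A, B, dispersion = 0.1))$pvalue < 0.05)
  }, numeric(1))
  expect_true(all(abs(sizes - 0.05) < 0.02))
})

test_that("BH adjustment follows the step-up procedure", {
  expect_equal(adjustFDR(0.04), 0.04)                       # m = 1 identity
  expect_equal(adjustFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustFDR(rep(1, 5)), rep(1, 5))
  expect_error(adjustFDR(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  p <- runif(50)
  fdr <- adjustFDR(p)
  ord <- order(p)
  expect_true(all(diff(fdr[ord]) >= -1e-12))                # monotone in rank
  expect_true(all(fdr <= 1) && all(fdr >= p - 1e-12))
})

test_that("dysregulation calls respect all three strict thresholds", {
  tab <- data.frame(
    feature = c("a", "b", "c", "d", "e"),
    meanA_tpm = 1, meanB_tpm = 1,
    log2fc = c(0.5, 2, -2, 2, 2),
    pvalue = c(0.001, 0.001, 0.001, 0.2, 0.001),
    fdr = c(0.001, 0.001, 0.001, 0.2, 0.3),
    call = "ns", stringsAsFactors = FALSE)
  res <- methods::new("DifferentialResult", table = tab,
                      groupA = "A", groupB = "B", dispersion = 0.1,
                      normFactors = c(A = 1, B = 1),
                      thresholds = list(log2fc = 1, p = 0.05, fdr = 0.05))
  calls <- deCalls(classifyDysregulated(res))
  expect_equal(unname(calls), c("ns", "up", "down", "ns", "ns"))

  # milder fold-change screen used for plasma-style panels
  milder <- deCalls(classifyDysregulated(res, log2fcCut = log2(1.5)))
  expect_equal(unname(milder["a"]), "ns")   # 2^0.5 = 1.41 < 1.5

  expect_error(classifyDysregulated(res, pCut = 0), "positive")
})

test_that("planted dysregulation is recovered at the stated power", {
  cfg <- simulationConfig(nMirnas = 400, nReplicates = 3, dispersion = 0.1,
                          deLog2FC = 2, fracDysregulated = 0.2, seed = 11)
  se <- computeTPM(simulateMirCounts(cfg))
  det <- detectFeatures(se)
  feats <- rownames(det)[det[, "lineA-CL"] | det[, "lineB-CL"]]
  A <- selectLibraries(se, cellLine = "lineA", compartment = "CL")
  B <- selectLibraries(se, cellLine = "lineB", compartment = "CL")
  res <- differentialExpression(se, A, B, features = feats)
  truth <- syntheticTruth(se)
  calls <- deCalls(res)
  planted <- truth$feature[truth$class %in% c("up", "down")]
  called <- names(calls)[calls != "ns"]
  expect_gte(mean(planted %in% called), 0.8)
  expect_lte(mean(!(called %in% planted)), 0.1)
  # direction of the calls matches the planted sign
  up <- intersect(truth$feature[truth$class == "up"], called)
  expect_true(all(calls[up] == "up"))
})
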