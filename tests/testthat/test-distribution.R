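test_that("Venn partitions reproduce inclusion-exclusion arithmetic", {
  # two lysate sets of 292 and 315 with union 345 -> 262 common
  feats <- sprintf("miR-%04d", 1:345)
  rep1 <- vennPartition(list(A = feats[1:292], B = feats[31:345]))
  expect_equal(commonCount(rep1), 262L)
  expect_equal(exclusiveCount(rep1, "B"), 53L)
  expect_equal(exclusiveCount(rep1, "A"), 30L)
  expect_equal(unionCount(rep1), 345L)

  # EV subtype sets 227 / 222 with 214 common -> exclusives 13 and 8
  ev <- sprintf("miR-%04d", 1:235)
  rep2 <- vennPartition(list(sMV = ev[1:227], Exo = ev[14:235]))
  expect_equal(commonCount(rep2), 214L)
  expect_equal(exclusiveCount(rep2, "sMV"), 13L)
  expect_equal(exclusiveCount(rep2, "Exo"), 8L)

  # union by inclusion-exclusion: 261 + 242 - 227 = 276
  ev2 <- sprintf("miR-%04d", 1:276)
  rep3 <- vennPartition(list(sMV = ev2[1:261], Exo = ev2[35:276]))
  expect_equal(unionCount(rep3), 276L)
  expect_equal(exclusiveCount(rep3, "sMV"), 34L)

  # disjoint sets have an empty intersection cell
  rep4 <- vennPartition(list(X = c("a", "b"), Y = c("c")))
  expect_equal(unname(vennCounts(rep4)["X&Y"]), 0L)
  expect_error(vennPartition(list(A = "a", A = "b")), "unique")
  expect_error(vennPartition(list(A = "a")), "two sets")
})

test_that("partition cells are disjoint, cover the union, and match a
           brute-force tabulation", {
  set.seed(12)
  universe <- sprintf("f%03d", 1:120)
  for (rep in 1:5) {
    sets <- lapply(setNames(1:4, c("w", "x", "y", "z")),
                   function(i) sample(universe, sample(20:80, 1)))
    report <- vennPartition(sets)
    cells <- report@cells
    expect_equal(anyDuplicated(unlist(cells)), 0L)
    expect_setequal(unlist(cells), unique(unlist(sets)))
    # brute-force membership signature per feature
    for (f in unique(unlist(sets))) {
      sig <- paste(names(sets)[vapply(sets, function(s) f %in% s,
                                      logical(1))], collapse = "&")
      expect_true(f %in% cells[[sig]])
    }
    # pairwise inclusion-exclusion on derived counts
    expect_equal(intersectionCount(report, c("w", "x")),
                 length(intersect(sets$w, sets$x)))
  }
})

test_that("cross-cell-line overlap reports the common-to-all cell", {
  s <- sprintf("m%02d", 1:30)
  same <- list(a = s, b = s, c = s, d = s)
  rep <- crossCellLineOverlap(same)
  expect_equal(commonCount(rep), 30L)
  expect_true(all(vennCounts(rep)[names(vennCounts(rep)) != "a&b&c&d"] == 0))
  expect_error(crossCellLineOverlap(same[1:3]), "four")
})

test_that("EV-enrichment labels partition the enriched set", {
  mkres <- function(features, up) {
    tab <- data.frame(feature = features, meanA_tpm = 1, meanB_tpm = 1,
                      log2fc = ifelse(features %in% up, 2, 0),
                      pvalue = ifelse(features %in% up, 1e-4, 0.8),
                      fdr = ifelse(features %in% up, 1e-4, 0.9),
                      call = ifelse(features %in% up, "up", "ns"),
                      stringsAsFactors = FALSE)
    methods::new("DifferentialResult", table = tab, groupA = "CL",
                 groupB = "EV", dispersion = 0.1,
                 normFactors = c(CL = 1, EV = 1),
                 thresholds = list(log2fc = 1, p = 0.05, fdr = 0.05))
  }
  feats <- sprintf("miR-%03d", 1:214)
  # 32 enriched in both, 1 sMV-only, 15 Exo-only -> 48 enriched
  lab <- evEnrichmentCall(mkres(feats, feats[1:33]),
                          mkres(feats, feats[c(1:32, 34:48)]))
  expect_equal(sum(lab == "both"), 32)
  expect_equal(sum(lab == "sMV_only"), 1)
  expect_equal(sum(lab == "Exo_only"), 15)
  expect_equal(sum(lab != "none"), 48)

  # no up-calls anywhere -> everything none
  lab0 <- evEnrichmentCall(mkres(feats, character(0)),
                           mkres(feats, character(0)))
  expect_true(all(lab0 == "none"))

  expect_error(evEnrichmentCall(mkres(feats, feats[1]),
                                mkres(feats[-1], character(0))),
               "universe")
})

test_that("the cell-silent screen partitions by EV subtype and totals add", {
  feats <- sprintf("miR-%03d", 1:120)
  lab <- factor(setNames(
    c(rep("sMV_only", 9), rep("Exo_only", 7), rep("both", 19),
      rep("none", 85)), feats),
    levels = c("none", "sMV_only", "Exo_only", "both"))
  detected <- setNames(rep(FALSE, 120), feats)
  scr <- cellSilentEvScreen(detected, lab)
  expect_equal(unname(scr$counts), c(9L, 7L, 19L))
  expect_equal(scr$total, 35L)

  # detected-in-CL features never enter the screen
  det2 <- detected; det2[feats[1:9]] <- TRUE
  expect_equal(cellSilentEvScreen(det2, lab)$total, 26L)
})

test_that("planted cell-silent EV features are recovered completely", {
  cfg <- simulationConfig(nMirnas = 300, fracCellSilentEv = 0.1, seed = 13)
  se <- computeTPM(simulateMirCounts(cfg))
  det <- detectFeatures(se)
  cl <- selectLibraries(se, cellLine = "lineA", compartment = "CL")
  feats <- rownames(se)
  deS <- differentialExpression(se, cl,
    selectLibraries(se, cellLine = "lineA", compartment = "sMV"),
    features = feats)
  deE <- differentialExpression(se, cl,
    selectLibraries(se, cellLine = "lineA", compartment = "Exo"),
    features = feats)
  scr <- cellSilentEvScreen(det[, "lineA-CL"], evEnrichmentCall(deS, deE))
  planted <- syntheticTruth(se)
  planted <- planted$feature[planted$class == "cell_silent_ev"]
  got <- unlist(scr[c("sMV_only", "Exo_only", "both")], use.names = FALSE)
  expect_true(all(planted %in% got))
})
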