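#' Pipeline configuration
#'
#' Bundles thresholds, stage options and the random seed for
#' [runPipeline()]. Inputs default to the synthetic generators; paths to a
#' count TSV ([readCounts()]) or precursor FASTA may be supplied instead.
#'
#' @param simulation a [simulationConfig()] used when `countsPath` is NULL.
#' @param countsPath optional count TSV (with `.meta.json` sidecar).
#' @param precursorsPath optional precursor FASTA.
#' @param tpmDetect detection threshold in TPM (strict `>`).
#' @param log2fcCut,pCut,fdrCut dysregulation thresholds.
#' @param signatureSelection which signature feeds the classifier.
#' @param classifierRule decision rule of [predictSamples()].
#' @param transform correlation transform (`"none"` or `"log2"`).
#' @param motif motif scanned over the precursors.
#' @param nPrecursors,precursorPlantedFraction simulated precursor set.
#' @param panelNormals,panelPerStage,panelWeight,panelNoiseSd simulated
#'   tumour/normal panel.
#' @param seed master seed; the count, panel and precursor generators run on
#'   independent sub-streams derived from it.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(simulation = simulationConfig(),
                           countsPath = NULL,
                           precursorsPath = NULL,
                           tpmDetect = 5,
                           log2fcCut = 1, pCut = 0.05, fdrCut = 0.05,
                           signatureSelection = c("ev_enriched",
                                                  "all_detected",
                                                  "dysregulated"),
                           classifierRule = "max-normal",
                           transform = "none",
                           motif = "CUGU",
                           nPrecursors = 334L,
                           precursorPlantedFraction = 0.527,
                           panelNormals = 11L,
                           panelPerStage = c(I = 103L, II = 223L,
                                             III = 179L, IV = 89L),
                           panelWeight = 0.6,
                           panelNoiseSd = 0.3,
                           seed = 1L) {
  if (tpmDetect < 0 || log2fcCut <= 0 || pCut <= 0 || fdrCut <= 0)
    stop("thresholds must be positive")
  structure(list(
    simulation = simulation, countsPath = countsPath,
    precursorsPath = precursorsPath,
    tpmDetect = tpmDetect, log2fcCut = log2fcCut, pCut = pCut,
    fdrCut = fdrCut,
    signatureSelection = match.arg(signatureSelection),
    classifierRule = classifierRule, transform = transform,
    motif = motif, nPrecursors = as.integer(nPrecursors),
    precursorPlantedFraction = precursorPlantedFraction,
    panelNormals = as.integer(panelNormals),
    panelPerStage = panelPerStage,
    panelWeight = panelWeight, panelNoiseSd = panelNoiseSd,
    seed = as.integer(seed)
  ), class = "pipelineConfig")
}

#' Run the complete analysis pipeline
#'
#' Executes the full inference chain on one experiment:
#' quantify (TPM) -> detect -> lysate differential expression -> EV-vs-CL
#' enrichment (both lines, both EV subtypes) -> distribution report ->
#' cell-silent EV screen -> signature build -> tumour/normal classification
#' on a simulated panel -> precursor motif scan. Every stage's output is
#' written under `outDir` (TSV/JSON), and a `manifest.json` records the
#' completed stages, seed and thresholds. Re-running with the same
#' configuration reproduces byte-identical outputs. Any stage failure
#' aborts with the stage name.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param verbose log stage progress to stderr?
#' @return (invisibly) a list with every stage's in-memory result and the
#'   manifest.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("evmir"),
                        verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  note <- function(stage) {
    if (verbose) message("[", stage, "] done")
    stages <<- c(stages, stage)
  }
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  ## 1. counts (simulate or load)
  se <- run("counts", {
    if (!is.null(config$countsPath)) readCounts(config$countsPath)
    else {
      sim <- config$simulation
      sim$seed <- .subSeed(config$seed, 1L)
      simulateMirCounts(sim)
    }
  })
  writeCounts(se, file.path(outDir, "counts.tsv"))
  note("counts")

  lines <- unique(SummarizedExperiment::colData(se)$cellLine)
  evComps <- setdiff(unique(SummarizedExperiment::colData(se)$compartment),
                     "CL")

  ## 2. quantify
  se <- run("quantify", computeTPM(se))
  meansTab <- averageReplicates(se)
  .writeTable(data.frame(feature = rownames(meansTab), meansTab,
                         check.names = FALSE),
              file.path(outDir, "tpm_means.tsv"))
  note("quantify")

  ## 3. detect
  det <- run("detect", detectFeatures(se, threshold = config$tpmDetect))
  .writeTable(data.frame(feature = rownames(det), det, check.names = FALSE),
              file.path(outDir, "detection.tsv"))
  note("detect")

  ## 4. lysate contrast (line A vs line B)
  clA <- selectLibraries(se, cellLine = lines[1], compartment = "CL")
  clB <- selectLibraries(se, cellLine = lines[2], compartment = "CL")
  clFeatures <- rownames(det)[det[, paste0(lines[1], "-CL")] |
                              det[, paste0(lines[2], "-CL")]]
  deCL <- run("de_lysate",
    differentialExpression(se, clA, clB, features = clFeatures,
                           log2fcCut = config$log2fcCut, pCut = config$pCut,
                           fdrCut = config$fdrCut))
  .writeTable(resultTable(deCL), file.path(outDir, "de_lysate.tsv"))
  note("de_lysate")

  ## 5. EV-vs-CL enrichment per line
  enrichment <- list()
  deEV <- list()
  for (ln in lines) {
    cl <- selectLibraries(se, cellLine = ln, compartment = "CL")
    feats <- rownames(det)[rowSums(
      det[, paste(ln, c("CL", evComps), sep = "-"), drop = FALSE]) > 0]
    per <- lapply(evComps, function(comp) {
      ev <- selectLibraries(se, cellLine = ln, compartment = comp)
      run(paste0("de_ev_", ln, "_", comp),
          differentialExpression(se, cl, ev, features = feats,
                                 log2fcCut = config$log2fcCut,
                                 pCut = config$pCut, fdrCut = config$fdrCut))
    })
    names(per) <- evComps
    deEV[[ln]] <- per
    enrichment[[ln]] <- evEnrichmentCall(per[["sMV"]], per[["Exo"]])
    for (comp in evComps)
      .writeTable(resultTable(per[[comp]]),
                  file.path(outDir, sprintf("de_ev_%s_%s.tsv", ln, comp)))
  }
  note("de_ev")

  ## 6. distribution report (detected sets, cross-line EV overlap)
  dist <- run("distribution", {
    sets <- detectedSets(se, threshold = config$tpmDetect)
    clVenn <- vennPartition(sets[paste0(lines, "-CL")])
    evSets <- sets[as.vector(outer(lines, evComps, paste, sep = "-"))]
    evVenn <- crossCellLineOverlap(evSets)
    list(cl = clVenn, ev = evVenn)
  })
  jsonlite::write_json(
    list(cl_cells = dist$cl@cells, ev_cells = dist$ev@cells,
         enrichment = lapply(enrichment, function(e)
           split(names(e), e)[c("sMV_only", "Exo_only", "both")])),
    file.path(outDir, "distribution.json"), digits = NA, pretty = TRUE)
  note("distribution")

  ## 7. cell-silent EV screen per line
  silent <- run("cell_silent", lapply(stats::setNames(lines, lines),
    function(ln) cellSilentEvScreen(det[, paste0(ln, "-CL")],
                                    enrichment[[ln]])))
  jsonlite::write_json(silent, file.path(outDir, "cell_silent.json"),
                       digits = NA, pretty = TRUE)
  note("cell_silent")

  ## 8. signature
  signature <- run("signature", {
    evMeans <- rowMeans(meansTab[, as.vector(outer(lines, evComps, paste,
                                                   sep = "-")), drop = FALSE])
    switch(config$signatureSelection,
      ev_enriched = buildSignature(evMeans, "ev_enriched",
                                   enrichment = enrichment),
      all_detected = buildSignature(meansTab[, paste0(lines[1], "-CL")],
                                    "all_detected",
                                    detected = det[, paste0(lines[1], "-CL")]),
      dysregulated = buildSignature(meansTab[, paste0(lines[1], "-CL")],
                                    "dysregulated", deResult = deCL))
  })
  .writeTable(data.frame(feature = names(signature), tpm = signature),
              file.path(outDir, "signature.tsv"))
  note("signature")

  ## 9. classification on a simulated panel
  classif <- run("classify", {
    panel <- simulateTumourPanel(signature,
                                 nNormals = config$panelNormals,
                                 nPerStage = config$panelPerStage,
                                 signatureWeight = config$panelWeight,
                                 noiseSd = config$panelNoiseSd,
                                 seed = .subSeed(config$seed, 2L))
    writePanel(panel, file.path(outDir, "panel.tsv"))
    rep <- predictSamples(panel, signature, rule = config$classifierRule,
                          transform = config$transform)
    list(report = rep, metrics = evaluateClassifier(rep))
  })
  .writeTable(predictions(classif$report),
              file.path(outDir, "classification.tsv"))
  jsonlite::write_json(
    list(threshold = classif$report@threshold, rule = classif$report@rule,
         sensitivity = classif$metrics$sensitivity,
         specificity = classif$metrics$specificity),
    file.path(outDir, "classification_metrics.json"), digits = NA,
    auto_unbox = TRUE, pretty = TRUE)
  note("classify")

  ## 10. motif scan
  motifRep <- run("motif", {
    pre <- if (!is.null(config$precursorsPath))
      Biostrings::readRNAStringSet(config$precursorsPath)
    else
      simulatePrecursors(config$nPrecursors,
                         plantedFraction = config$precursorPlantedFraction,
                         motif = config$motif,
                         seed = .subSeed(config$seed, 3L))
    scanMotif(pre, config$motif)
  })
  jsonlite::write_json(
    list(motif = motifRep@motif, n_sequences = motifRep@nSequences,
         n_with_motif = motifRep@nWithMotif,
         fraction_pct = motifFraction(motifRep)),
    file.path(outDir, "motif.json"), digits = NA, auto_unbox = TRUE,
    pretty = TRUE)
  note("motif")

  manifest <- list(
    package = "vesiclemiR",
    version = as.character(utils::packageVersion("vesiclemiR")),
    seed = config$seed,
    thresholds = list(tpmDetect = config$tpmDetect,
                      log2fc = config$log2fcCut, p = config$pCut,
                      fdr = config$fdrCut),
    stages = stages)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(experiment = se, detection = det, deLysate = deCL,
                 deEV = deEV, enrichment = enrichment,
                 distribution = dist, cellSilent = silent,
                 signature = signature, classification = classif,
                 motif = motifRep, manifest = manifest, outDir = outDir))
}
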