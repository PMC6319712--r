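#' Simulation settings for synthetic miRNA count data
#'
#' Collects the parameters of the negative-binomial count simulator. Defaults
#' emulate the study design the package targets: two isogenic cell lines, a
#' cell-lysate (CL) compartment plus two secreted EV compartments (sMV, Exo),
#' two biological replicates per compartment, and an average sequencing depth
#' of 12.77 million miRNA-mapped reads per library.
#'
#' Planted feature classes are disjoint: `fracDysregulated` of the features
#' carry a |log2FC| > 1 difference between the two cell lines' lysates
#' (half up, half down, magnitude `deLog2FC`); `fracEvEnriched` carry an
#' EV-over-CL enrichment of magnitude `evLog2FC` (split evenly across
#' sMV-only / Exo-only / both); `fracCellSilentEv` are "cell-silent but
#' EV-abundant": their lysate abundance is pinned at 1 TPM-equivalent while
#' EV abundance is drawn from \[2000, 6000\] TPM-equivalents, guaranteeing the
#' < 5 TPM (CL) versus > 1000 TPM (EV) pattern after sampling noise.
#' `fracPassenger` of the features are annotated as passenger (star) strands
#' (default 0.296, the fraction observed in colorectal cell-line lysates).
#'
#' @param nMirnas number of miRNA features.
#' @param nReplicates biological replicates per compartment (>= 2).
#' @param cellLines,compartments library design labels.
#' @param librarySizeMean expected miRNA-mapped reads per library; actual
#'   depths are drawn uniformly within +/-20%.
#' @param dispersion NB dispersion phi >= 0 (variance mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param fracDysregulated,fracEvEnriched,fracCellSilentEv planted class
#'   fractions; must sum to <= 1.
#' @param fracPassenger fraction annotated as passenger strands.
#' @param deLog2FC,evLog2FC planted log2 fold-change magnitudes (> 1).
#' @param seed integer random seed.
#' @return a `simulationConfig` list.
#' @export
simulationConfig <- function(nMirnas = 500L,
                             nReplicates = 2L,
                             cellLines = c("lineA", "lineB"),
                             compartments = c("CL", "sMV", "Exo"),
                             librarySizeMean = 12.77e6,
                             dispersion = 0.1,
                             fracDysregulated = 0.2,
                             fracEvEnriched = 0.1,
                             fracCellSilentEv = 0.05,
                             fracPassenger = 0.296,
                             deLog2FC = 2,
                             evLog2FC = 3,
                             seed = 1L) {
  .assertScalarNumber(nMirnas, "nMirnas", lower = 1)
  if (nReplicates < 2)
    stop("nReplicates must be >= 2 (duplicate libraries at minimum)")
  .assertScalarNumber(dispersion, "dispersion", lower = 0)
  for (nm in c("fracDysregulated", "fracEvEnriched", "fracCellSilentEv",
               "fracPassenger"))
    .assertScalarNumber(get(nm), nm, lower = 0, upper = 1)
  if (fracDysregulated + fracEvEnriched + fracCellSilentEv > 1)
    stop("planted class fractions must be disjoint: ",
         "fracDysregulated + fracEvEnriched + fracCellSilentEv > 1")
  if (deLog2FC <= 1 || evLog2FC <= 1)
    stop("planted log2 fold changes must exceed 1 (the dysregulation cut)")
  if (!"CL" %in% compartments)
    stop("a 'CL' (cell lysate) compartment is required")
  structure(list(
    nMirnas = as.integer(nMirnas), nReplicates = as.integer(nReplicates),
    cellLines = cellLines, compartments = compartments,
    librarySizeMean = librarySizeMean, dispersion = dispersion,
    fracDysregulated = fracDysregulated, fracEvEnriched = fracEvEnriched,
    fracCellSilentEv = fracCellSilentEv, fracPassenger = fracPassenger,
    deLog2FC = deLog2FC, evLog2FC = evLog2FC, seed = as.integer(seed)
  ), class = "simulationConfig")
}

# Planted class assignment: exact integer counts per class (round()), classes
# disjoint, order shuffled so class is independent of feature index.
.assignClasses <- function(config) {
  n <- config$nMirnas
  nDys <- round(n * config$fracDysregulated)
  nEv <- round(n * config$fracEvEnriched)
  nSil <- round(n * config$fracCellSilentEv)
  nUp <- floor(nDys / 2)
  nDown <- nDys - nUp
  nEvBoth <- nEv - 2 * floor(nEv / 3)
  nEvSMV <- floor(nEv / 3)
  nEvExo <- floor(nEv / 3)
  cls <- c(rep("up", nUp), rep("down", nDown),
           rep("ev_enriched_both", nEvBoth),
           rep("ev_enriched_sMV", nEvSMV),
           rep("ev_enriched_Exo", nEvExo),
           rep("cell_silent_ev", nSil))
  cls <- c(cls, rep("null", n - length(cls)))
  sample(cls)
}

#' Simulate a miRNA count experiment with recorded ground truth
#'
#' Draws negative-binomial counts per feature x library. Baseline relative
#' abundances are log-normal (log10 mean 2, sd 1), spanning the heavy-tailed
#' TPM range observed in real miRNA libraries (~0.1 to > 300,000 TPM).
#' Per-compartment expected abundances apply the planted fold changes
#' (dysregulation to all compartments of the second cell line, since a
#' cellular change propagates to its vesicles; EV enrichment to the EV
#' compartments of both lines), are renormalized within each library to
#' relative proportions, and scaled by the library depth. Identical seeds
#' give identical output.
#'
#' @param config a [simulationConfig()].
#' @return A [MiRNAExperiment-class] whose `rowData` records the planted
#'   class, planted log2 fold changes and passenger flag; retrieve them with
#'   [syntheticTruth()].
#' @examples
#' se <- simulateMirCounts(simulationConfig(nMirnas = 50, librarySizeMean = 1e5))
#' table(syntheticTruth(se)$class)
#' @export
simulateMirCounts <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed)

  n <- config$nMirnas
  cls <- .assignClasses(config)
  baseline <- 10^stats::rnorm(n, mean = 2, sd = 1)

  lineB <- config$cellLines[2L]
  evComps <- setdiff(config$compartments, "CL")

  # planted log2FC between the two lysates (sign: lineB relative to lineA)
  log2fcPlanted <- ifelse(cls == "up", config$deLog2FC,
                   ifelse(cls == "down", -config$deLog2FC, 0))
  evLog2fcPlanted <- ifelse(startsWith(cls, "ev_enriched"), config$evLog2FC, 0)

  silent <- cls == "cell_silent_ev"
  silentEv <- stats::runif(sum(silent), 2000, 6000)

  groups <- expand.grid(compartment = config$compartments,
                        cellLine = config$cellLines,
                        stringsAsFactors = FALSE)
  abundance <- matrix(baseline, nrow = n, ncol = nrow(groups))
  colnames(abundance) <- paste(groups$cellLine, groups$compartment, sep = "-")
  for (g in seq_len(nrow(groups))) {
    a <- abundance[, g]
    if (groups$cellLine[g] == lineB) a <- a * 2^log2fcPlanted
    comp <- groups$compartment[g]
    if (comp %in% evComps) {
      hit <- cls == "ev_enriched_both" |
        (cls == "ev_enriched_sMV" & comp == "sMV") |
        (cls == "ev_enriched_Exo" & comp == "Exo")
      a[hit] <- a[hit] * 2^config$evLog2FC
    }
    # cell-silent features are pinned to exact expected TPM targets: 1 TPM
    # in the lysate, thousands of TPM in the vesicles. Solving
    # a_i = t_i * B / (1e6 - T) (B = non-silent abundance mass, T = sum of
    # targets) makes the expected TPM equal the target exactly.
    if (any(silent)) {
      target <- if (comp %in% evComps) silentEv else rep(1, sum(silent))
      B <- sum(a[!silent])
      a[silent] <- target * B / (1e6 - sum(target))
    }
    abundance[, g] <- a
  }

  nLibs <- nrow(groups) * config$nReplicates
  libGroup <- rep(seq_len(nrow(groups)), each = config$nReplicates)
  libSizes <- stats::runif(nLibs, 0.8, 1.2) * config$librarySizeMean

  counts <- matrix(0L, nrow = n, ncol = nLibs)
  phi <- config$dispersion
  for (l in seq_len(nLibs)) {
    a <- abundance[, libGroup[l]]
    mu <- a / sum(a) * libSizes[l]
    counts[, l] <- if (phi > 0)
      stats::rnbinom(n, size = 1 / phi, mu = mu)
    else
      stats::rpois(n, lambda = mu)
  }

  passenger <- stats::runif(n) < config$fracPassenger
  rownames(counts) <- sprintf("miR-%04d-%s", seq_len(n),
                              ifelse(passenger, "3p", "5p"))
  se <- MiRNAExperiment(
    counts,
    cellLine = rep(groups$cellLine, each = config$nReplicates),
    compartment = rep(groups$compartment, each = config$nReplicates),
    replicate = rep(seq_len(config$nReplicates), nrow(groups)),
    passenger = passenger,
    rowData = S4Vectors::DataFrame(class = cls,
                                   log2fcPlanted = log2fcPlanted,
                                   evLog2fcPlanted = evLog2fcPlanted)
  )
  S4Vectors::metadata(se)$config <- config
  se
}
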