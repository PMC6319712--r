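#' Construct a MiRNAExperiment
#'
#' Bundle a raw miRNA count matrix with its library annotations. Library
#' identifiers default to `<cellLine>-<compartment>-R<replicate>`.
#'
#' @param counts integer matrix, features x libraries; rownames are mature
#'   miRNA names.
#' @param cellLine,compartment,replicate per-library annotation vectors,
#'   recycled to `ncol(counts)`.
#' @param passenger optional logical vector flagging passenger (star) strands.
#' @param rowData optional extra per-feature annotation (`DataFrame` or
#'   data.frame); `passenger` is added to it.
#'
#' @return A [MiRNAExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(40, 50), 10,
#'               dimnames = list(sprintf("miR-%02d-5p", 1:10), NULL))
#' se <- MiRNAExperiment(cts,
#'                       cellLine = "SW480",
#'                       compartment = rep(c("CL", "Exo"), each = 2),
#'                       replicate = rep(1:2, 2))
#' se
#' @export
MiRNAExperiment <- function(counts, cellLine, compartment, replicate,
                            passenger = NULL, rowData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("count matrix must have feature (miRNA) rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  n <- ncol(counts)
  cd <- S4Vectors::DataFrame(
    cellLine = as.character(rep_len(cellLine, n)),
    compartment = as.character(rep_len(compartment, n)),
    replicate = as.integer(rep_len(replicate, n))
  )
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("%s-%s-R%d", cd$cellLine, cd$compartment,
                                cd$replicate)
  rownames(cd) <- colnames(counts)
  rd <- if (is.null(rowData)) S4Vectors::DataFrame(row.names = rownames(counts))
        else S4Vectors::DataFrame(rowData, row.names = rownames(counts))
  if (!is.null(passenger))
    rd$passenger <- as.logical(rep_len(passenger, nrow(counts)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, rowData = rd)
  methods::new("MiRNAExperiment", se)
}

#' Access the raw count matrix
#'
#' @param object a [MiRNAExperiment-class].
#' @return integer matrix of counts.
#' @export
mirCounts <- function(object) {
  SummarizedExperiment::assay(object, "counts")
}

#' Library grouping helpers
#'
#' `libraryGroups()` returns the `<cellLine>-<compartment>` group of each
#' library; `selectLibraries()` returns the library names matching a cell
#' line and/or compartment.
#'
#' @param object a [MiRNAExperiment-class].
#' @param cellLine,compartment optional filters.
#' @return character vector.
#' @export
libraryGroups <- function(object) {
  cd <- SummarizedExperiment::colData(object)
  paste(cd$cellLine, cd$compartment, sep = "-")
}

#' @rdname libraryGroups
#' @export
selectLibraries <- function(object, cellLine = NULL, compartment = NULL) {
  cd <- SummarizedExperiment::colData(object)
  keep <- rep(TRUE, ncol(object))
  if (!is.null(cellLine)) keep <- keep & cd$cellLine %in% cellLine
  if (!is.null(compartment)) keep <- keep & cd$compartment %in% compartment
  colnames(object)[keep]
}

#' @describeIn syntheticTruth Planted ground truth of a simulated experiment,
#'   as a data.frame (feature, class, planted log2 fold changes, passenger
#'   flag); errors when the object carries no truth annotation.
#' @export
setMethod("syntheticTruth", "MiRNAExperiment", function(object, ...) {
  rd <- SummarizedExperiment::rowData(object)
  if (!"class" %in% colnames(rd))
    stop("object carries no planted ground truth (not simulated?)")
  data.frame(feature = rownames(object),
             class = rd$class,
             log2fcPlanted = rd$log2fcPlanted,
             evLog2fcPlanted = rd$evLog2fcPlanted,
             passenger = rd$passenger,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Passenger-strand fraction
#'
#' Fraction of features flagged as passenger (star) strands, as a percentage
#' rounded half-up to one decimal (the reporting convention for such
#' fractions, e.g. 102/345 -> 29.6).
#'
#' @param x a [MiRNAExperiment-class] with a `passenger` rowData column, or a
#'   logical vector of flags.
#' @return numeric percentage (one decimal place).
#' @export
passengerFraction <- function(x) {
  flags <- if (methods::is(x, "MiRNAExperiment")) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"passenger" %in% colnames(rd))
      stop("no 'passenger' annotation present")
    rd$passenger
  } else as.logical(x)
  if (!length(flags)) stop("no features")
  .roundHalfUp(100 * mean(flags), 1)
}

setMethod("show", "MiRNAExperiment", function(object) {
  methods::callNextMethod()
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("libraries: %d (%s x %s)\n", ncol(object),
              paste(unique(cd$cellLine), collapse = "/"),
              paste(unique(cd$compartment), collapse = "/")))
  rd <- SummarizedExperiment::rowData(object)
  if ("class" %in% colnames(rd))
    cat("planted truth classes:",
        paste(names(table(rd$class)), table(rd$class), sep = "=", collapse = ", "),
        "\n")
})
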