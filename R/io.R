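# Plain-text readers/writers: counts as TSV + sidecar JSON metadata, panels
# as TSV with a label row, reports as JSON/TSV.

#' Write and read a count experiment
#'
#' `writeCounts()` writes the raw counts as a TSV (first column `feature`,
#' one column per library) plus a sidecar JSON with the per-library
#' annotation (and planted truth, when present). `readCounts()` restores a
#' validated [MiRNAExperiment-class]; non-integer or negative entries are
#' rejected with the offending cell named.
#'
#' @param object a [MiRNAExperiment-class].
#' @param path TSV path; the metadata sidecar defaults to
#'   `<path>.meta.json`.
#' @param metadataPath sidecar JSON path.
#' @return `readCounts()` returns a [MiRNAExperiment-class];
#'   `writeCounts()` returns `path` invisibly.
#' @export
writeCounts <- function(object, path,
                        metadataPath = paste0(path, ".meta.json")) {
  stopifnot(methods::is(object, "MiRNAExperiment"))
  cts <- mirCounts(object)
  tab <- data.frame(feature = rownames(cts), cts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(object)
  meta <- list(libraries = data.frame(
    id = colnames(object),
    cellLine = cd$cellLine,
    compartment = cd$compartment,
    replicate = cd$replicate,
    stringsAsFactors = FALSE))
  rd <- SummarizedExperiment::rowData(object)
  if ("passenger" %in% colnames(rd)) {
    meta$features <- data.frame(feature = rownames(object),
                                passenger = rd$passenger,
                                stringsAsFactors = FALSE)
    if ("class" %in% colnames(rd)) {
      meta$features$class <- rd$class
      meta$features$log2fcPlanted <- rd$log2fcPlanted
      meta$features$evLog2fcPlanted <- rd$evLog2fcPlanted
    }
  }
  jsonlite::write_json(meta, metadataPath, dataframe = "rows",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeCounts
#' @export
readCounts <- function(path, metadataPath = paste0(path, ".meta.json")) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "feature")
    stop("first column of a count TSV must be 'feature'")
  if (anyDuplicated(tab$feature))
    stop("duplicate feature IDs: ",
         paste(unique(tab$feature[duplicated(tab$feature)]), collapse = ", "))
  cts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cts) <- tab$feature
  bad <- which(!is.finite(cts) | cts < 0 | abs(cts - round(cts)) > 1e-8)
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(cts))
    stop(sprintf(
      "invalid count at feature '%s', library '%s': %s (must be a non-negative integer)",
      rownames(cts)[idx[1L]], colnames(cts)[idx[2L]], format(cts[bad[1L]])))
  }
  if (!file.exists(metadataPath))
    stop("missing metadata sidecar: ", metadataPath)
  meta <- jsonlite::read_json(metadataPath, simplifyVector = TRUE)
  libs <- as.data.frame(meta$libraries)
  if (is.null(libs) ||
      !all(c("id", "cellLine", "compartment", "replicate") %in% colnames(libs)))
    stop("metadata must provide libraries with id/cellLine/compartment/replicate")
  if (!setequal(libs$id, colnames(cts)))
    stop("metadata library ids do not match the count columns")
  ord <- match(colnames(cts), libs$id)
  rowData <- NULL
  passenger <- NULL
  if (!is.null(meta$features)) {
    ft <- as.data.frame(meta$features)
    fo <- match(rownames(cts), ft$feature)
    passenger <- ft$passenger[fo]
    extra <- setdiff(colnames(ft), c("feature", "passenger"))
    if (length(extra))
      rowData <- S4Vectors::DataFrame(ft[fo, extra, drop = FALSE])
  }
  MiRNAExperiment(cts,
                  cellLine = libs$cellLine[ord],
                  compartment = libs$compartment[ord],
                  replicate = libs$replicate[ord],
                  passenger = passenger, rowData = rowData)
}

#' Write and read a labelled expression panel
#'
#' The panel TSV carries a header of sample names, then a `label` row with
#' the per-sample labels, then one row per feature.
#'
#' @param panel a [LabeledPanel-class].
#' @param path TSV path.
#' @return `readPanel()` returns a [LabeledPanel-class].
#' @export
writePanel <- function(panel, path) {
  stopifnot(methods::is(panel, "LabeledPanel"))
  exprs <- panelExprs(panel)
  head <- data.frame(feature = "label",
                     t(as.character(panelLabels(panel))),
                     stringsAsFactors = FALSE)
  colnames(head) <- c("feature", colnames(exprs))
  body <- data.frame(feature = rownames(exprs),
                     format(exprs, digits = 15, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
  colnames(body) <- colnames(head)
  utils::write.table(rbind(head, body), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (tab$feature[1] != "label")
    stop("panel TSV must start with a 'label' row")
  labels <- factor(unlist(tab[1, -1], use.names = FALSE),
                   levels = c("normal", "I", "II", "III", "IV"))
  exprs <- apply(as.matrix(tab[-1, -1, drop = FALSE]), c(1, 2), as.numeric)
  rownames(exprs) <- tab$feature[-1]
  methods::new("LabeledPanel", exprs = exprs, labels = labels)
}

# Deterministic TSV writer for result tables.
.writeTable <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x)
    format(x, digits = 15, trim = TRUE, scientific = TRUE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
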