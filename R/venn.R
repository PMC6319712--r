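#' Venn partition of named feature sets
#'
#' Computes every exclusive region of k >= 2 named sets: each feature of the
#' union is assigned to the cell named by the sets containing it (e.g.
#' `"sMV&Exo"`). Cells are disjoint and cover the union, so every
#' inclusion-exclusion identity (|A intersect B| = |A| + |B| - |A union B|,
#' and the k-way analogues) holds exactly on the reported counts.
#'
#' @param sets named list (unique names) of >= 2 character vectors.
#' @return A [DistributionReport-class].
#' @examples
#' rep <- vennPartition(list(sMV = c("a", "b", "c"), Exo = c("b", "c", "d")))
#' vennCounts(rep)            # sMV=1, sMV&Exo=2, Exo=1
#' commonCount(rep)           # 2
#' @export
vennPartition <- function(sets) {
  if (length(sets) < 2L) stop("at least two sets are required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) ||
      anyDuplicated(names(sets)))
    stop("sets must have unique non-empty names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- unique(unlist(sets, use.names = FALSE))

  k <- length(sets)
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)

  combos <- .vennSignatures(names(sets))
  cells <- lapply(combos, function(cmb) {
    inAll <- rep(TRUE, length(universe))
    for (nm in names(sets)) {
      want <- nm %in% cmb
      inAll <- inAll & (member[, nm] == want)
    }
    universe[inAll]
  })
  names(cells) <- vapply(combos, paste, character(1), collapse = "&")
  counts <- stats::setNames(vapply(cells, length, integer(1)), names(cells))
  methods::new("DistributionReport", sets = sets, cells = cells,
               counts = counts)
}

# All 2^k - 1 non-empty subsets of the set names, in size order.
.vennSignatures <- function(nms) {
  k <- length(nms)
  out <- list()
  for (size in seq_len(k))
    out <- c(out, utils::combn(nms, size, simplify = FALSE))
  out
}

#' @describeIn vennCounts Counts of every exclusive Venn cell, named by
#'   membership signature (`"A"`, `"A&B"`, ...).
#' @param object a [DistributionReport-class].
#' @export
setMethod("vennCounts", "DistributionReport", function(object, ...) object@counts)

#' @describeIn cellMembers Features of one exclusive cell.
#' @param object a [DistributionReport-class].
#' @param cell signature name as in [vennCounts()].
#' @export
setMethod("cellMembers", "DistributionReport", function(object, cell, ...) {
  if (!cell %in% names(object@cells))
    stop("unknown cell: ", cell)
  object@cells[[cell]]
})

#' @describeIn commonCount Size of the common-to-all cell.
#' @param object a [DistributionReport-class].
#' @export
setMethod("commonCount", "DistributionReport", function(object, ...) {
  unname(object@counts[paste(names(object@sets), collapse = "&")])
})

#' Derived set quantities of a Venn partition
#'
#' `unionCount()` is the size of the union of all sets;
#' `intersectionCount()` the size of the (non-exclusive) intersection of any
#' subset of the sets; `exclusiveCount()` the features found in exactly one
#' named set.
#'
#' @param report a [DistributionReport-class].
#' @param which set names to intersect (default: all).
#' @param set one set name.
#' @return integer count.
#' @export
unionCount <- function(report) {
  sum(report@counts)
}

#' @rdname unionCount
#' @export
intersectionCount <- function(report, which = names(report@sets)) {
  miss <- setdiff(which, names(report@sets))
  if (length(miss)) stop("unknown set(s): ", paste(miss, collapse = ", "))
  keep <- vapply(names(report@cells), function(sig) {
    all(which %in% strsplit(sig, "&", fixed = TRUE)[[1]])
  }, logical(1))
  sum(report@counts[keep])
}

#' @rdname unionCount
#' @export
exclusiveCount <- function(report, set) {
  if (!set %in% names(report@sets)) stop("unknown set: ", set)
  unname(report@counts[set])
}

setMethod("show", "DistributionReport", function(object) {
  cat(sprintf("DistributionReport: %d sets (%s), union %d features\n",
              length(object@sets),
              paste(names(object@sets), collapse = ", "),
              unionCount(object)))
  nonzero <- object@counts[object@counts > 0]
  print(nonzero)
})

#' Four-way EV overlap across cell lines
#'
#' Full Venn partition of the four EV feature sets (two cell lines x two EV
#' subtypes), reporting in particular the common-to-all cell used to
#' summarize miRNAs shared by every secreted vesicle type.
#'
#' @param sets named list of exactly four feature sets.
#' @return A [DistributionReport-class]; use [commonCount()] for the
#'   common-to-all count.
#' @export
crossCellLineOverlap <- function(sets) {
  if (length(sets) != 4L)
    stop("exactly four EV feature sets are required (2 lines x 2 subtypes)")
  vennPartition(sets)
}
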