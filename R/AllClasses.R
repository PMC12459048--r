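#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#' @importFrom S4Vectors DataFrame
NULL

#' Labelled set of H2A candidate proteins
#'
#' Container for protein sequences with optional truth labels and region
#' truth, as produced by the synthetic benchmark generator or read from
#' FASTA. Sequences are stored as a [Biostrings::AAStringSet].
#'
#' @slot sequences An `AAStringSet` of mature protein sequences.
#' @slot truth Named character vector mapping record id to variant class
#'   (may be empty for unlabelled sets).
#' @slot regionTruth Named list mapping record id to a named list of
#'   `c(start, end)` 0-based half-open region coordinates.
#' @slot species Named character vector of species tags (may be empty).
#' @export
setClass("H2ASet", representation(
  sequences = "AAStringSet",
  truth = "character",
  regionTruth = "list",
  species = "character"
))

setValidity("H2ASet", function(object) {
  ids <- names(object@sequences)
  msgs <- character()
  if (length(object@sequences) > 0 && is.null(ids))
    msgs <- c(msgs, "sequences must be named")
  if (length(object@truth) > 0) {
    if (!all(names(object@truth) %in% ids))
      msgs <- c(msgs, "truth labels refer to unknown record ids")
    if (anyDuplicated(names(object@truth)))
      msgs <- c(msgs, "each record must have exactly one truth label")
  }
  for (id in names(object@regionTruth)) {
    co <- object@regionTruth[[id]]
    len <- nchar(as.character(object@sequences[[id]]))
    bounds <- unlist(co, use.names = FALSE)
    if (any(bounds < 0) || any(bounds > len))
      msgs <- c(msgs, paste0("region truth out of bounds for ", id))
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-column reference profile of the histone fold
#'
#' A position frequency matrix over the fold columns (alphaN through docking
#' domain) with region boundaries and acidic-patch column indices, used to
#' anchor query sequences and delimit their fold regions.
#'
#' @slot freqs 20 x m numeric matrix; rows are residues, columns the profile
#'   positions; every column sums to 1.
#' @slot regionMap Named list of `c(start, end)` 1-based inclusive column
#'   intervals for the fold regions, contiguous and ordered.
#' @slot patchCols Integer vector of acidic-patch column indices.
#' @slot name Character scalar.
#' @export
setClass("ReferenceProfile", representation(
  freqs = "matrix",
  regionMap = "list",
  patchCols = "integer",
  name = "character"
))

setValidity("ReferenceProfile", function(object) {
  msgs <- character()
  if (nrow(object@freqs) != 20L || !identical(rownames(object@freqs), AA20))
    msgs <- c(msgs, "freqs must have the 20 standard residues as rows")
  if (any(abs(colSums(object@freqs) - 1) > 1e-9))
    msgs <- c(msgs, "every profile column must sum to 1")
  rm_ <- object@regionMap
  if (!identical(names(rm_), FOLD_REGIONS)) {
    msgs <- c(msgs, "regionMap must cover the fold regions in order")
  } else {
    starts <- vapply(rm_, `[`, numeric(1), 1L)
    ends <- vapply(rm_, `[`, numeric(1), 2L)
    if (starts[1] != 1 || ends[length(ends)] != ncol(object@freqs) ||
        any(starts[-1] != ends[-length(ends)] + 1))
      msgs <- c(msgs, "regionMap intervals must tile the profile in order")
  }
  if (any(object@patchCols < 1L | object@patchCols > ncol(object@freqs)))
    msgs <- c(msgs, "patchCols out of range")
  if (length(msgs)) msgs else TRUE
})

#' Histone-fold annotation of one protein
#'
#' Region coordinates produced by anchoring a protein to a
#' [ReferenceProfile]. When the fold is detected, the regions (n_tail,
#' alphaN, alpha1, L1, alpha2, L2, alpha3, docking, c_tail) tile the
#' sequence exactly, in 0-based half-open coordinates.
#'
#' @slot recordId Character scalar.
#' @slot regions Named list of `c(start, end)` coordinates (empty when the
#'   fold was not detected).
#' @slot alignmentScore Numeric alignment score.
#' @slot foldDetected Logical scalar.
#' @slot patchSites Integer vector of 0-based sequence positions the profile
#'   acidic-patch columns mapped to (NA where a patch column was deleted).
#' @export
setClass("FoldAnnotation", representation(
  recordId = "character",
  regions = "list",
  alignmentScore = "numeric",
  foldDetected = "logical",
  patchSites = "integer"
))

setValidity("FoldAnnotation", function(object) {
  msgs <- character()
  if (!object@foldDetected) {
    if (length(object@regions) > 0)
      msgs <- c(msgs, "regions must be empty when the fold is not detected")
    return(if (length(msgs)) msgs else TRUE)
  }
  if (!identical(names(object@regions), REGION_ORDER)) {
    msgs <- c(msgs, "regions must be the nine fold regions in order")
  } else {
    starts <- vapply(object@regions, `[`, numeric(1), 1L)
    ends <- vapply(object@regions, `[`, numeric(1), 2L)
    if (starts[1] != 0) msgs <- c(msgs, "n_tail must start at 0")
    if (any(ends < starts)) msgs <- c(msgs, "region end before start")
    if (any(starts[-1] != ends[-length(ends)]))
      msgs <- c(msgs, "regions must tile the sequence without gaps/overlap")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "H2ASet", function(object) {
  cat("H2ASet with", length(object@sequences), "sequences\n")
  if (length(object@truth) > 0) {
    tab <- table(object@truth)
    cat("  truth labels:",
        paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

setMethod("show", "ReferenceProfile", function(object) {
  cat("ReferenceProfile", object@name, "with", ncol(object@freqs),
      "columns over", paste(names(object@regionMap), collapse = "-"), "\n")
})

setMethod("show", "FoldAnnotation", function(object) {
  cat("FoldAnnotation for", object@recordId,
      "| fold detected:", object@foldDetected,
      "| score:", round(object@alignmentScore, 2), "\n")
  if (object@foldDetected) {
    co <- vapply(object@regions, function(x)
      paste0("[", x[1], ",", x[2], ")"), character(1))
    cat(" ", paste(names(co), co, sep = "=", collapse = " "), "\n")
  }
})

#' @rdname H2ASet-class
#' @param object An `H2ASet`.
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))

#' @rdname H2ASet-class
#' @export
setMethod("sequences", "H2ASet", function(object) object@sequences)

#' @rdname H2ASet-class
#' @export
setGeneric("truthLabels", function(object) standardGeneric("truthLabels"))

#' @rdname H2ASet-class
#' @export
setMethod("truthLabels", "H2ASet", function(object) object@truth)

#' @rdname H2ASet-class
#' @export
setGeneric("regionTruth", function(object) standardGeneric("regionTruth"))

#' @rdname H2ASet-class
#' @export
setMethod("regionTruth", "H2ASet", function(object) object@regionTruth)

#' @rdname FoldAnnotation-class
#' @param object A `FoldAnnotation`.
#' @export
setGeneric("foldRegions", function(object) standardGeneric("foldRegions"))

#' @rdname FoldAnnotation-class
#' @export
setMethod("foldRegions", "FoldAnnotation", function(object) object@regions)

#' @rdname FoldAnnotation-class
#' @export
setGeneric("foldDetected", function(object) standardGeneric("foldDetected"))

#' @rdname FoldAnnotation-class
#' @export
setMethod("foldDetected", "FoldAnnotation", function(object) object@foldDetected)
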