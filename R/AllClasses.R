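#' @import S4Vectors IRanges GenomicRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowRanges colData
NULL

#' EditingExperiment: site-by-sample editing counts
#'
#' An S4 container for an RNA editing level matrix, extending
#' [SummarizedExperiment::RangedSummarizedExperiment]. Assays `edited` and
#' `coverage` hold edited-read and total-read counts per site and sample;
#' `rowRanges` carry the site coordinates with a `substitution` metadata
#' column (e.g. `"A>G"`), and `colData` must contain a `tissue` factor.
#'
#' @slot .. see [SummarizedExperiment::RangedSummarizedExperiment].
#' @export
setClass("EditingExperiment", contains = "RangedSummarizedExperiment")

setValidity("EditingExperiment", function(object) {
  msg <- NULL
  an <- assayNames(object)
  if (!all(c("edited", "coverage") %in% an))
    msg <- c(msg, "assays must include 'edited' and 'coverage'")
  else {
    ed <- assay(object, "edited"); cv <- assay(object, "coverage")
    if (any(ed < 0, na.rm = TRUE) || any(cv < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
    if (any(ed > cv, na.rm = TRUE))
      msg <- c(msg, "edited counts cannot exceed coverage")
  }
  if (!"tissue" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'tissue' column")
  if (is.null(msg)) TRUE else msg
})

#' Construct an EditingExperiment
#'
#' @param edited,coverage Integer matrices (sites x samples), same dimensions.
#' @param sites A [GenomicRanges::GRanges] of site positions (width 1), one
#'   per row, with a `substitution` metadata column.
#' @param tissue Character or factor of tissue labels, one per sample.
#' @param colData Optional extra per-sample annotation (DataFrame).
#' @return An [EditingExperiment-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1),
#'                              substitution = c("A>G", "C>T"))
#' ee <- EditingExperiment(edited = matrix(0:3, 2), coverage = matrix(10, 2, 2),
#'                         sites = gr, tissue = c("liver", "brain"))
#' editingLevels(ee)
#' @export
EditingExperiment <- function(edited, coverage, sites, tissue,
                              colData = NULL) {
  edited <- as.matrix(edited); coverage <- as.matrix(coverage)
  stopifnot(identical(dim(edited), dim(coverage)),
            length(sites) == nrow(edited),
            length(tissue) == ncol(edited))
  cd <- S4Vectors::DataFrame(tissue = as.character(tissue))
  if (!is.null(colData)) cd <- cbind(cd, colData)
  if (is.null(colnames(edited)))
    colnames(edited) <- colnames(coverage) <-
      sprintf("S%03d", seq_len(ncol(edited)))
  rownames(cd) <- colnames(edited)
  se <- SummarizedExperiment(
    assays = list(edited = edited, coverage = coverage),
    rowRanges = sites, colData = cd)
  new("EditingExperiment", se)
}

#' @describeIn EditingExperiment Editing levels (edited/coverage), `NA` where
#'   a site has zero coverage in a sample.
#' @param x An EditingExperiment.
#' @export
editingLevels <- function(x) {
  stopifnot(is(x, "EditingExperiment"))
  ed <- assay(x, "edited"); cv <- assay(x, "coverage")
  lev <- ed / cv
  lev[cv == 0] <- NA_real_
  lev
}

#' @describeIn EditingExperiment Tissue label per sample.
#' @export
tissueLabels <- function(x) as.character(colData(x)$tissue)

setMethod("show", "EditingExperiment", function(object) {
  cat(sprintf("EditingExperiment: %d sites x %d samples (%d tissues)\n",
              nrow(object), ncol(object),
              length(unique(colData(object)$tissue))))
  callNextMethod()
})

#' SimilarityMask: genome self-similarity intervals
#'
#' Holds the merged set of genomic intervals flagged as self-similar
#' (alignment-artifact prone) by the genome self-alignment scan.
#'
#' @slot ranges A reduced, sorted [GenomicRanges::GRanges].
#' @export
setClass("SimilarityMask", representation(ranges = "GRanges"))

setValidity("SimilarityMask", function(object) {
  r <- object@ranges
  if (length(r) > 1L && !identical(r, GenomicRanges::reduce(sort(r))))
    return("ranges must be sorted and merged (reduced)")
  TRUE
})

#' @describeIn SimilarityMask-class Constructor; input ranges are sorted and
#'   merged.
#' @param ranges A GRanges of self-similar intervals.
#' @export
SimilarityMask <- function(ranges = GenomicRanges::GRanges()) {
  new("SimilarityMask", ranges = GenomicRanges::reduce(sort(ranges)))
}

#' @describeIn SimilarityMask-class The underlying GRanges.
#' @param mask A SimilarityMask.
#' @export
maskRanges <- function(mask) mask@ranges

setMethod("show", "SimilarityMask", function(object) {
  cat(sprintf("SimilarityMask: %d intervals, %d bp masked\n",
              length(object@ranges), sum(IRanges::width(object@ranges))))
})

setMethod("length", "SimilarityMask", function(x) length(x@ranges))

#' Test positions against a similarity mask
#'
#' @param positions A GRanges (or an EditingExperiment, whose site ranges are
#'   used).
#' @param mask A [SimilarityMask-class].
#' @return Logical vector, `TRUE` where the position overlaps a masked
#'   interval.
#' @export
isMasked <- function(positions, mask) {
  stopifnot(is(mask, "SimilarityMask"))
  if (is(positions, "EditingExperiment")) positions <- rowRanges(positions)
  if (length(mask@ranges) == 0L) return(rep(FALSE, length(positions)))
  ovAny(positions, mask@ranges)
}

#' Export a similarity mask as BED
#'
#' @param mask A [SimilarityMask-class].
#' @param file Output BED path.
#' @export
writeMaskBed <- function(mask, file) {
  rtracklayer::export(mask@ranges, file, format = "BED")
  invisible(file)
}

#' Read a similarity mask from BED
#'
#' @param file BED path.
#' @export
readMaskBed <- function(file) {
  SimilarityMask(rtracklayer::import(file, format = "BED"))
}
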