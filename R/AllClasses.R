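#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand findOverlaps
#' @importFrom IRanges IRanges
NULL

#' Transposon terminal motif
#'
#' A transposon terminal motif together with its reverse complement, which is
#' derived automatically so that junction reads sequenced off either strand
#' can be recognised.
#'
#' @slot label short name for the motif, used in logs and read provenance.
#' @slot sequence uppercase DNA string over A/C/G/T.
#' @slot revcomp reverse complement of \code{sequence} (derived, never set
#'   by the user).
#'
#' @seealso [motifSpec()] for the constructor, [findMotif()] for searching.
#' @export
setClass("MotifSpec",
  representation(label = "character", sequence = "character",
                 revcomp = "character"))

setValidity("MotifSpec", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "motif sequence must be a single non-empty string")
  else {
    if (grepl("[^ACGT]", object@sequence))
      msg <- c(msg, sprintf("motif contains non-ACGT character: '%s'",
                            gsub("[ACGT]", "", object@sequence)))
    if (!identical(object@revcomp, revComp(object@sequence)))
      msg <- c(msg, "revcomp slot is not the reverse complement of sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Create a transposon motif specification
#'
#' Validates the motif as uppercase DNA and derives its reverse complement.
#'
#' @param sequence DNA string over A/C/G/T (lowercase accepted, stored
#'   uppercase).
#' @param label short name; defaults to the sequence itself.
#' @return A [MotifSpec-class] object.
#' @examples
#' motifSpec("TCAG")
#' @export
motifSpec <- function(sequence, label = sequence) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence))
    stop(sprintf("motif '%s' contains non-DNA character '%s'", sequence,
                 substring(gsub("[ACGT]", "", sequence), 1L, 1L)))
  new("MotifSpec", label = as.character(label), sequence = sequence,
      revcomp = revComp(sequence))
}

#' @exportMethod show
setMethod("show", "MotifSpec", function(object) {
  cat("MotifSpec '", object@label, "': ", object@sequence,
      " (revcomp ", object@revcomp, ")\n", sep = "")
})

#' @describeIn MotifSpec-class motif sequence accessor
#' @param x,object a \code{MotifSpec}
#' @export
motifSequence <- function(x) x@sequence

#' @describeIn MotifSpec-class reverse-complement accessor
#' @export
motifRevcomp <- function(x) x@revcomp

#' @describeIn MotifSpec-class label accessor
#' @export
motifLabel <- function(x) x@label

#' Table of unique insertion positions
#'
#' Maps (reference, 1-based position) to the read depth observed at that
#' unique insertion position, for one mutant pool. Positions are held as
#' width-1 \code{GRanges} with a \code{depth} metadata column; the pool
#' totals (mapped reads, unique positions) are derived, never stored.
#'
#' @slot sites width-1 [GenomicRanges::GRanges] with integer metadata
#'   column \code{depth} (all values >= 1); positions unique per reference.
#'
#' @seealso [insertionTable()], [callInsertions()], [collapseSites()],
#'   [coverageFilter()].
#' @export
setClass("InsertionTable", representation(sites = "GRanges"))

setValidity("InsertionTable", function(object) {
  s <- object@sites
  msg <- character()
  if (!"depth" %in% colnames(mcols(s)))
    return("sites must carry a 'depth' metadata column")
  d <- mcols(s)$depth
  if (length(s)) {
    if (!is.numeric(d) || anyNA(d) || any(d < 1))
      msg <- c(msg, "all depths must be >= 1")
    if (any(GenomicRanges::width(s) != 1L))
      msg <- c(msg, "sites must have width 1")
    key <- paste(seqnames(s), start(s))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (reference, position) keys")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an insertion table
#'
#' @param reference character vector of reference (chromosome/contig) names.
#' @param position integer vector of 1-based insertion positions.
#' @param depth integer vector of read depths (>= 1).
#' @return An [InsertionTable-class].
#' @examples
#' insertionTable("chr", c(100L, 200L), c(5L, 3L))
#' @export
insertionTable <- function(reference, position, depth) {
  reference <- rep_len(as.character(reference), length(position))
  o <- order(reference, position)
  gr <- GRanges(reference[o], IRanges(as.integer(position)[o], width = 1L))
  mcols(gr)$depth <- as.integer(depth)[o]
  new("InsertionTable", sites = gr)
}

setMethod("show", "InsertionTable", function(object) {
  cat("InsertionTable:", nSites(object), "unique positions,",
      totalReads(object), "mapped reads on",
      length(unique(as.character(seqnames(object@sites)))), "reference(s)\n")
})

#' @describeIn InsertionTable-class the site positions as a `GRanges`
#' @param x an `InsertionTable`
#' @export
insertionSites <- function(x) x@sites

#' @describeIn InsertionTable-class number of unique insertion positions
#' @export
nSites <- function(x) length(x@sites)

#' @describeIn InsertionTable-class total mapped reads (sum of depths)
#' @export
totalReads <- function(x) sum(mcols(x@sites)$depth)

#' @export
#' @method as.data.frame InsertionTable
as.data.frame.InsertionTable <- function(x, ...) {
  data.frame(reference = as.character(seqnames(x@sites)),
             position = start(x@sites),
             depth = mcols(x@sites)$depth,
             stringsAsFactors = FALSE)
}

#' @exportMethod as.data.frame
setMethod("as.data.frame", "InsertionTable",
          function(x, ...) as.data.frame.InsertionTable(x, ...))
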