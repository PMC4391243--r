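#' Count mismatched bases from a SAM MD tag
#'
#' The MD tag encodes the reference bases at mismatched and deleted
#' positions of an alignment. This counts substituted bases only: letters
#' inside a \code{^}-prefixed deletion run are reference bases deleted from
#' the read and are not mismatches, and insertions are invisible to MD, so
#' neither indel type contributes. Strict substitution counting keeps the
#' filter reproducible across aligners.
#'
#' @param md character vector of MD tag values (without the \code{MD:Z:}
#'   prefix).
#' @return integer vector of substitution counts.
#' @examples
#' countMismatches(c("50", "10A5C3", "3^AC10T5"))  # 0, 2, 1
#' @export
countMismatches <- function(md) {
  vapply(md, function(x) {
    if (is.na(x)) return(NA_integer_)
    toks <- regmatches(x, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", x))[[1]]
    if (paste(toks, collapse = "") != x || !nzchar(x))
      stop(sprintf("malformed MD tag: '%s'", x))
    sum(grepl("^[A-Z]$", toks))
  }, integer(1), USE.NAMES = FALSE)
}

#' Apply mismatch and alignment-score filters
#'
#' A mapped record passes when its substitution count does not exceed the
#' mismatch threshold and its AS tag meets the minimum alignment score.
#' \code{maxMismatch} may be a whole number of bases, or a fraction strictly
#' between 0 and 1 of the read length (e.g. 0.1 allows 10\% of bases to
#' mismatch); the fractional threshold is \code{floor(frac * readLen)},
#' reading the fraction as an upper bound. A record with no AS tag fails the
#' score filter.
#'
#' @param mismatches integer vector of substitution counts
#'   ([countMismatches()]).
#' @param alignScore integer vector of AS tag values (NA when absent).
#' @param maxMismatch mismatch threshold (count, or fraction in (0,1)).
#' @param minAlignScore minimum alignment score (aligner scale; may be
#'   negative, e.g. for bowtie2).
#' @param readLen integer vector of read lengths (needed for the fractional
#'   form).
#' @return logical vector.
#' @examples
#' passesFilters(0, 50, 0, 50, 30)          # TRUE
#' passesFilters(3, 50, 0.1, 0, 30)         # TRUE: floor(0.1*30) = 3
#' @export
passesFilters <- function(mismatches, alignScore, maxMismatch, minAlignScore,
                          readLen) {
  stopifnot(maxMismatch >= 0)
  thr <- if (maxMismatch > 0 && maxMismatch < 1)
    floor(maxMismatch * readLen)
  else
    maxMismatch
  okScore <- !is.na(alignScore) & alignScore >= minAlignScore
  mismatches <= thr & okScore
}

#' Insertion position of a filtered alignment
#'
#' The insertion site is the reference base immediately adjacent to the
#' transposon, which is the first base of the genomic fragment. On the +
#' strand that is the leftmost aligned base (SAM POS); on the - strand the
#' fragment's 5' end maps rightmost, so the site is
#' POS + reference span of the CIGAR - 1. Reference span counts
#' M/D/N/=/X operations; soft clips consume no reference.
#'
#' @param pos integer vector of 1-based leftmost mapping positions.
#' @param cigar character vector of CIGAR strings.
#' @param strand character vector, \code{"+"} or \code{"-"}.
#' @return integer vector of 1-based insertion positions.
#' @examples
#' insertionPosition(100, "30M", "-")       # 129
#' insertionPosition(100, "10M2D20M", "-")  # 131
#' @export
#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace
insertionPosition <- function(pos, cigar, strand) {
  span <- cigarWidthAlongReferenceSpace(cigar)
  as.integer(ifelse(strand == "-", pos + span - 1L, pos))
}

# Read a SAM file into a data.frame of per-record fields via Rsamtools
# (SAM -> temporary BAM -> scanBam), keeping unmapped records and flagging
# secondary/supplementary alignments.
#' @importFrom Rsamtools asBam scanBam ScanBamParam
readSamRecords <- function(samPath) {
  bam <- Rsamtools::asBam(samPath,
                          destination = tempfile("tnseqr_"),
                          overwrite = TRUE, indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "qwidth", "cigar"),
    tag = c("MD", "AS"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  getTag <- function(tag) {
    v <- res$tag[[tag]]
    if (is.null(v)) rep(NA, n) else v
  }
  data.frame(qname = res$qname,
             flag = res$flag,
             rname = as.character(res$rname),
             strand = as.character(res$strand),
             pos = res$pos,
             qwidth = res$qwidth,
             cigar = res$cigar,
             md = as.character(getTag("MD")),
             as = as.integer(getTag("AS")),
             stringsAsFactors = FALSE)
}

#' Call insertion positions from a SAM file
#'
#' The central post-alignment step: primary mapped records are filtered by
#' MD-tag mismatch count and AS-tag alignment score, the strand-aware
#' insertion position of each surviving read is recorded, positions exactly
#' \code{collapseDistance} apart are merged (the target-site duplication of
#' the mutagen; 8 bp for ISS1-type elements), and a depth table of unique
#' insertion positions is returned. Secondary and supplementary alignments
#' are ignored so each read contributes at most once.
#'
#' @param sam path to a SAM file with MD and AS tags.
#' @param maxMismatch,minAlignScore see [passesFilters()]. Defaults are the
#'   recommended stringent setting (0 mismatches, score >= 50 on the bwa
#'   scale).
#' @param collapseDistance merge sites exactly this many bp apart
#'   (0 = off); see [collapseSites()].
#' @param minDepth drop sites below this read depth after collapsing
#'   (1 = off); see [coverageFilter()].
#' @param logPath optional path for the run log (parameters plus every
#'   conservation count).
#' @return an [InsertionTable-class]; the count ledger is attached as
#'   attribute \code{"counts"} (nRecords = nPassed + nFailMismatch +
#'   nFailScore + nUnmapped + nSecondary).
#' @export
callInsertions <- function(sam, maxMismatch = 0, minAlignScore = 50,
                           collapseDistance = 0L, minDepth = 1L,
                           logPath = NULL) {
  rec <- readSamRecords(sam)
  secondary <- bitwAnd(rec$flag, 0x100L) != 0L | bitwAnd(rec$flag, 0x800L) != 0L
  unmapped <- !secondary & bitwAnd(rec$flag, 0x4L) != 0L
  primary <- !secondary & !unmapped
  mm <- rep(NA_integer_, nrow(rec))
  mm[primary] <- countMismatches(rec$md[primary])
  thr <- if (maxMismatch > 0 && maxMismatch < 1)
    floor(maxMismatch * rec$qwidth) else rep(maxMismatch, nrow(rec))
  failMis <- primary & !is.na(mm) & mm > thr
  failMis <- failMis | (primary & is.na(mm))  # missing MD cannot be assessed
  failScore <- primary & !failMis & (is.na(rec$as) | rec$as < minAlignScore)
  passed <- primary & !failMis & !failScore
  counts <- list(nRecords = nrow(rec), nPassed = sum(passed),
                 nFailMismatch = sum(failMis), nFailScore = sum(failScore),
                 nUnmapped = sum(unmapped), nSecondary = sum(secondary))
  tab <- if (any(passed)) {
    ip <- insertionPosition(rec$pos[passed], rec$cigar[passed],
                            rec$strand[passed])
    agg <- stats::aggregate(list(depth = ip),
                            by = list(reference = rec$rname[passed],
                                      position = ip),
                            FUN = length)
    insertionTable(agg$reference, agg$position, agg$depth)
  } else {
    insertionTable(character(), integer(), integer())
  }
  if (collapseDistance > 0L) tab <- collapseSites(tab, collapseDistance)
  if (minDepth > 1L) tab <- coverageFilter(tab, minDepth)
  counts$nUniquePositions <- nSites(tab)
  counts$nMappedReadsKept <- totalReads(tab)
  if (!is.null(logPath))
    writeRunLog(c(list(stage = "process_sam", sam = sam,
                       max_mismatch = maxMismatch,
                       min_align_score = minAlignScore,
                       collapse_distance = collapseDistance,
                       min_depth = minDepth), counts), logPath)
  attr(tab, "counts") <- counts
  tab
}

#' Collapse insertion sites a fixed distance apart
#'
#' Transposons that create a target-site duplication on insertion produce
#' two junction sites exactly the duplication length apart (8 bp for
#' pGhost9::ISS1). For each pair of sites on the same reference at positions
#' p and p + d, the pair is merged into the lower position with summed
#' depth. The merge is a single left-to-right pass without re-chaining: in
#' \{100, 108, 116\} with d = 8, 108 merges into 100 and 116 stands alone,
#' because the duplication produces exactly one partner site and longer
#' chains are artifacts. Only sites exactly d apart merge; d = 0 is the
#' identity.
#'
#' @param x an [InsertionTable-class].
#' @param d collapse distance in bp (>= 0).
#' @return a new [InsertionTable-class].
#' @examples
#' collapseSites(insertionTable("c", c(100L, 108L), c(5L, 3L)), 8)
#' @export
collapseSites <- function(x, d) {
  stopifnot(is(x, "InsertionTable"), d >= 0)
  if (d == 0L || nSites(x) == 0L) return(x)
  df <- as.data.frame(x)
  out <- do.call(rbind, lapply(split(df, df$reference), function(g) {
    g <- g[order(g$position), ]
    consumed <- rep(FALSE, nrow(g))
    idx <- match(g$position + d, g$position)
    for (i in seq_len(nrow(g))) {
      if (consumed[i]) next
      j <- idx[i]
      if (!is.na(j) && !consumed[j]) {
        g$depth[i] <- g$depth[i] + g$depth[j]
        consumed[j] <- TRUE
      }
    }
    g[!consumed, ]
  }))
  insertionTable(out$reference, out$position, out$depth)
}

#' Filter insertion sites by read depth
#'
#' Removes positions supported by fewer than \code{minDepth} reads. The
#' recommended setting for real libraries is 2, dropping single-read
#' positions, which are enriched for alignment noise.
#'
#' @param x an [InsertionTable-class].
#' @param minDepth minimum read depth to retain (>= 1; 1 is the identity).
#' @return a new [InsertionTable-class]; totals are recomputed.
#' @export
coverageFilter <- function(x, minDepth) {
  stopifnot(is(x, "InsertionTable"), minDepth >= 1)
  keep <- mcols(x@sites)$depth >= minDepth
  if (!any(keep))
    warning("coverage filter removed every site")
  new("InsertionTable", sites = x@sites[keep])
}

#' Sweep mismatch and alignment-score thresholds over a SAM file
#'
#' Runs the filter + position-calling pass once per grid cell and tabulates
#' the number of unique insertion positions and the mean read depth per
#' position. Unique positions are non-increasing as either threshold
#' tightens, and at high score stringency the mismatch columns converge
#' (alignments passing a maximal score filter have no mismatches to filter).
#'
#' @param sam path to a SAM file.
#' @param mismatchGrid numeric vector of mismatch thresholds.
#' @param scoreGrid numeric vector of minimum alignment scores.
#' @param collapseDistance passed through to the position-calling pass.
#' @return data.frame with columns \code{maxMismatch}, \code{minAlignScore},
#'   \code{uniquePositions}, \code{meanDepth}.
#' @export
parameterSweep <- function(sam, mismatchGrid, scoreGrid,
                           collapseDistance = 0L) {
  rec <- readSamRecords(sam)
  secondary <- bitwAnd(rec$flag, 0x100L) != 0L | bitwAnd(rec$flag, 0x800L) != 0L
  primary <- !secondary & bitwAnd(rec$flag, 0x4L) == 0L
  rec <- rec[primary, , drop = FALSE]
  mm <- countMismatches(rec$md)
  ip <- insertionPosition(rec$pos, rec$cigar, rec$strand)
  grid <- expand.grid(maxMismatch = mismatchGrid, minAlignScore = scoreGrid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    mis <- grid$maxMismatch[i]
    thr <- if (mis > 0 && mis < 1) floor(mis * rec$qwidth) else mis
    keep <- !is.na(mm) & mm <= thr & !is.na(rec$as) &
      rec$as >= grid$minAlignScore[i]
    if (!any(keep))
      return(data.frame(uniquePositions = 0L, meanDepth = NA_real_))
    tab <- stats::aggregate(list(depth = ip[keep]),
                            by = list(r = rec$rname[keep], p = ip[keep]),
                            FUN = length)
    it <- insertionTable(tab$r, tab$p, tab$depth)
    if (collapseDistance > 0L) it <- collapseSites(it, collapseDistance)
    data.frame(uniquePositions = nSites(it),
               meanDepth = totalReads(it) / nSites(it))
  })
  cbind(grid, do.call(rbind, res))
}
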