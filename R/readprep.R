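#' Locate a transposon motif within a read sequence
#'
#' Searches a read for the motif in both orientations: the motif sequence
#' itself (forward) and its reverse complement (a junction read sequenced
#' off the opposite strand). Matching is exact; an N in the read never
#' matches. When both orientations occur the forward match wins, and within
#' an orientation the leftmost occurrence wins, so the result is
#' deterministic.
#'
#' @param sequence read sequence (character; uppercased before search).
#' @param motif a [MotifSpec-class].
#' @return list with elements \code{found} (logical), \code{orientation}
#'   (\code{"forward"} or \code{"revcomp"}), \code{matchStart} and
#'   \code{matchEnd} (1-based inclusive coordinates of the matched motif in
#'   the read; \code{NA} when not found).
#' @examples
#' findMotif("AAATCAGGGCCTT", motifSpec("TCAG"))
#' @export
findMotif <- function(sequence, motif) {
  stopifnot(is(motif, "MotifSpec"))
  seq <- toupper(sequence)
  f <- regexpr(motif@sequence, seq, fixed = TRUE)
  r <- regexpr(motif@revcomp, seq, fixed = TRUE)
  if (f > 0L) {
    list(found = TRUE, orientation = "forward", matchStart = as.integer(f),
         matchEnd = as.integer(f) + nchar(motif@sequence) - 1L)
  } else if (r > 0L) {
    list(found = TRUE, orientation = "revcomp", matchStart = as.integer(r),
         matchEnd = as.integer(r) + nchar(motif@revcomp) - 1L)
  } else {
    list(found = FALSE, orientation = NA_character_,
         matchStart = NA_integer_, matchEnd = NA_integer_)
  }
}

#' Extract the genomic fragment downstream of a transposon motif
#'
#' The junction read consists of (possibly) vector or transposon sequence,
#' the transposon terminal motif, and then genomic DNA starting at the base
#' adjacent to the insertion. This function extracts that genomic fragment
#' and its quality string, re-oriented so that the emitted fragment always
#' reads 5'->3' away from the transposon: for a forward motif match the
#' bases after the motif are taken as-is; for a reverse-complement match the
#' bases before the match are reverse-complemented (qualities reversed).
#' Truncation to \code{maxLen} keeps the bases closest to the junction,
#' since the junction-proximal base defines the insertion site.
#'
#' @param sequence,quality read sequence and phred string (equal length).
#' @param motifs a [MotifSpec-class] or list of them, tried in order.
#' @param minLen,maxLen fragment retention bounds in bp (defaults 20/50).
#' @param id read id, used in error messages and provenance.
#' @return list with \code{status} one of \code{"ok"}, \code{"no_motif"},
#'   \code{"too_short"}; when ok, also \code{sequence}, \code{quality},
#'   \code{orientation}, \code{motifLabel}.
#' @examples
#' m <- motifSpec("TCAG")
#' extractFragment("AAATCAGGGCCTT", "FFFFFFFFFFFFF", m, minLen = 2)
#' @export
extractFragment <- function(sequence, quality, motifs, minLen = 20L,
                            maxLen = 50L, id = "read") {
  if (is(motifs, "MotifSpec")) motifs <- list(motifs)
  stopifnot(minLen >= 1L, minLen <= maxLen)
  if (nchar(quality) != nchar(sequence))
    stop(sprintf("malformed FASTQ record '%s': %d bases but %d quality values",
                 id, nchar(sequence), nchar(quality)))
  seq <- toupper(sequence)
  for (m in motifs) {
    hit <- findMotif(seq, m)
    if (!hit$found) next
    if (hit$orientation == "forward") {
      from <- hit$matchEnd + 1L
      to <- min(nchar(seq), hit$matchEnd + maxLen)
      frag <- substr(seq, from, to)
      fq <- substr(quality, from, to)
    } else {
      to <- hit$matchStart - 1L
      from <- max(1L, hit$matchStart - maxLen)
      frag <- if (to >= from) revComp(substr(seq, from, to)) else ""
      fq <- if (to >= from)
        paste(rev(strsplit(substr(quality, from, to), "")[[1]]), collapse = "")
      else ""
    }
    if (nchar(frag) < minLen)
      return(list(status = "too_short", motifLabel = m@label,
                  orientation = hit$orientation))
    return(list(status = "ok", sequence = frag, quality = fq,
                orientation = hit$orientation, motifLabel = m@label))
  }
  list(status = "no_motif")
}

# Vectorized fragment extraction over character vectors; same semantics as
# extractFragment() but one pass per motif with regexpr(). Returns a list of
# parallel vectors with status/sequence/quality/orientation/motif.
.extractFragmentsVec <- function(seqs, quals, motifs, minLen, maxLen) {
  n <- length(seqs)
  status <- rep("no_motif", n)
  frag <- character(n); fq <- character(n)
  orient <- rep(NA_character_, n); mlab <- rep(NA_character_, n)
  unclaimed <- rep(TRUE, n)
  seqs <- toupper(seqs)
  for (m in motifs) {
    mw <- nchar(m@sequence)
    fpos <- regexpr(m@sequence, seqs, fixed = TRUE)
    rpos <- regexpr(m@revcomp, seqs, fixed = TRUE)
    isF <- unclaimed & fpos > 0L
    isR <- unclaimed & !isF & rpos > 0L
    if (any(isF)) {
      from <- as.integer(fpos[isF]) + mw
      to <- pmin(nchar(seqs[isF]), from + maxLen - 1L)
      frag[isF] <- substr(seqs[isF], from, to)
      fq[isF] <- substr(quals[isF], from, to)
      orient[isF] <- "forward"
    }
    if (any(isR)) {
      to <- as.integer(rpos[isR]) - 1L
      from <- pmax(1L, to - maxLen + 1L)
      up <- substr(seqs[isR], from, to)
      uq <- substr(quals[isR], from, to)
      nonempty <- to >= from
      rcseq <- character(sum(isR)); rcq <- character(sum(isR))
      if (any(nonempty)) {
        rcseq[nonempty] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(up[nonempty])))
        rcq[nonempty] <- as.character(Biostrings::reverse(
          Biostrings::BStringSet(uq[nonempty])))
      }
      frag[isR] <- rcseq
      fq[isR] <- rcq
      orient[isR] <- "revcomp"
    }
    hitM <- isF | isR
    status[hitM] <- ifelse(nchar(frag[hitM]) >= minLen, "ok", "too_short")
    mlab[hitM] <- m@label
    unclaimed <- unclaimed & !hitM
  }
  list(status = status, sequence = frag, quality = fq,
       orientation = orient, motif = mlab)
}

#' Per-position base composition and quality quartiles
#'
#' QC tables for a set of reads: percent nucleotide distribution at each
#' read position (over A/C/G/T/N, summing to 100 per position) and the
#' quartiles (Q1, median, Q3) of the phred quality at each position. These
#' are the plot data for raw-vs-processed read QC; rendering is left to the
#' user.
#'
#' @param fastq path to a FASTQ file (plain or gzipped), or a
#'   [ShortRead::ShortReadQ] object.
#' @return list of two data frames, \code{basecomp} (columns position,
#'   A, C, G, T, N as percentages, n) and \code{qualquartile} (columns
#'   position, q1, median, q3, n). Empty input yields empty tables with a
#'   warning.
#' @export
#' @importFrom ShortRead readFastq sread alphabetByCycle
#' @importFrom Biostrings quality
qcSummaries <- function(fastq) {
  fq <- if (is.character(fastq)) ShortRead::readFastq(fastq) else fastq
  if (length(fq) == 0L) {
    warning("no reads; QC tables are empty")
    return(list(
      basecomp = data.frame(position = integer(), A = numeric(),
                            C = numeric(), G = numeric(), T = numeric(),
                            N = numeric(), n = integer()),
      qualquartile = data.frame(position = integer(), q1 = numeric(),
                                median = numeric(), q3 = numeric(),
                                n = integer())))
  }
  abc <- ShortRead::alphabetByCycle(sread(fq))
  bases <- c("A", "C", "G", "T", "N")
  counts <- t(abc[bases, , drop = FALSE])
  nAt <- rowSums(t(abc))  # reads covering each cycle
  basecomp <- data.frame(position = seq_len(nrow(counts)),
                         100 * counts / nAt, n = as.integer(nAt),
                         check.names = FALSE)
  qm <- as(Biostrings::quality(fq), "matrix")
  qs <- apply(qm, 2L, stats::quantile, probs = c(.25, .5, .75), na.rm = TRUE)
  qualquartile <- data.frame(position = seq_len(ncol(qm)),
                             q1 = qs[1L, ], median = qs[2L, ], q3 = qs[3L, ],
                             n = colSums(!is.na(qm)))
  list(basecomp = basecomp, qualquartile = qualquartile)
}

#' Extract transposon-junction fragments from raw FASTQ
#'
#' Scans single- or paired-end FASTQ for transposon terminal motifs and
#' writes a FASTQ of the genomic fragments adjacent to the junction (see
#' [extractFragment()] for the per-read rule). For paired-end input, when
#' both mates of a pair yield a fragment only mate 1's is kept -- both mates
#' observe the same junction, so keeping both would double-count the
#' insertion. QC tables for raw and processed reads and a run log with full
#' conservation counts are written alongside.
#'
#' @param fastq1 path to the (mate-1) FASTQ, plain or gzipped (auto-detected).
#' @param fastq2 optional mate-2 FASTQ for paired-end data.
#' @param motifs a [MotifSpec-class] or list of 1-2 of them.
#' @param minLen,maxLen fragment retention bounds in bp.
#' @param outFastq output path for the fragment FASTQ.
#' @param qcPrefix if non-NULL, path prefix for the QC tables
#'   (\code{<prefix>.raw.basecomp.tsv} etc.) and the run log
#'   (\code{<prefix>.prep.log}).
#' @return invisibly, a list with the output path and the count ledger:
#'   \code{nInput}, \code{nEmitted}, \code{nNoMotif}, \code{nTooShort},
#'   \code{nMateDiscarded}; conservation holds:
#'   \code{nInput == nEmitted + nNoMotif + nTooShort + nMateDiscarded}.
#' @export
#' @importFrom ShortRead ShortReadQ writeFastq
#' @importFrom Biostrings DNAStringSet BStringSet PhredQuality
prepReads <- function(fastq1, fastq2 = NULL, motifs, minLen = 20L,
                      maxLen = 50L, outFastq, qcPrefix = NULL) {
  if (is(motifs, "MotifSpec")) motifs <- list(motifs)
  stopifnot(length(motifs) >= 1L, all(vapply(motifs, is, TRUE, "MotifSpec")))
  fq1 <- openFastq(fastq1)
  ids1 <- as.character(ShortRead::id(fq1))
  res1 <- .extractFragmentsVec(as.character(sread(fq1)),
                               as.character(Biostrings::quality(Biostrings::quality(fq1))),
                               motifs, minLen, maxLen)
  paired <- !is.null(fastq2)
  nMateDiscarded <- 0L
  if (paired) {
    fq2 <- openFastq(fastq2)
    ids2 <- as.character(ShortRead::id(fq2))
    base1 <- sub("[/ ].*$", "", ids1)
    base2 <- sub("[/ ].*$", "", ids2)
    if (length(base1) != length(base2) || !all(base1 == base2))
      stop("paired FASTQ files are desynchronized (read ids do not match)")
    res2 <- .extractFragmentsVec(as.character(sread(fq2)),
                                 as.character(Biostrings::quality(Biostrings::quality(fq2))),
                                 motifs, minLen, maxLen)
    bothOk <- res1$status == "ok" & res2$status == "ok"
    nMateDiscarded <- sum(bothOk)
    res2$status[bothOk] <- "mate_discarded"
    keep1 <- res1$status == "ok"
    keep2 <- res2$status == "ok"
    outSeq <- c(res1$sequence[keep1], res2$sequence[keep2])
    outQual <- c(res1$quality[keep1], res2$quality[keep2])
    outId <- c(sprintf("%s TN:%s OR:%s", ids1[keep1], res1$motif[keep1],
                       res1$orientation[keep1]),
               sprintf("%s TN:%s OR:%s", ids2[keep2], res2$motif[keep2],
                       res2$orientation[keep2]))
    nInput <- length(fq1) + length(fq2)
    nNoMotif <- sum(res1$status == "no_motif") + sum(res2$status == "no_motif")
    nTooShort <- sum(res1$status == "too_short") + sum(res2$status == "too_short")
  } else {
    keep1 <- res1$status == "ok"
    outSeq <- res1$sequence[keep1]
    outQual <- res1$quality[keep1]
    outId <- sprintf("%s TN:%s OR:%s", ids1[keep1], res1$motif[keep1],
                     res1$orientation[keep1])
    nInput <- length(fq1)
    nNoMotif <- sum(res1$status == "no_motif")
    nTooShort <- sum(res1$status == "too_short")
  }
  out <- ShortRead::ShortReadQ(
    sread = DNAStringSet(outSeq),
    quality = Biostrings::PhredQuality(BStringSet(outQual)),
    id = BStringSet(outId))
  if (file.exists(outFastq)) file.remove(outFastq)
  ShortRead::writeFastq(out, outFastq, compress = grepl("\\.gz$", outFastq))
  counts <- list(nInput = nInput, nEmitted = length(out),
                 nNoMotif = nNoMotif, nTooShort = nTooShort,
                 nMateDiscarded = nMateDiscarded)
  if (!is.null(qcPrefix)) {
    raw <- qcSummaries(fq1)
    writeTsv(raw$basecomp, paste0(qcPrefix, ".raw.basecomp.tsv"))
    writeTsv(raw$qualquartile, paste0(qcPrefix, ".raw.qualquartile.tsv"))
    if (length(out)) {
      proc <- qcSummaries(out)
      writeTsv(proc$basecomp, paste0(qcPrefix, ".processed.basecomp.tsv"))
      writeTsv(proc$qualquartile, paste0(qcPrefix, ".processed.qualquartile.tsv"))
    }
    writeRunLog(c(list(stage = "readprep",
                       motifs = paste(vapply(motifs, motifSequence, ""), collapse = ","),
                       min_len = minLen, max_len = maxLen,
                       paired = paired), counts),
                paste0(qcPrefix, ".prep.log"))
  }
  invisible(c(list(outFastq = outFastq), counts))
}
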