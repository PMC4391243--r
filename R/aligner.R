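#' Assemble an external aligner command line
#'
#' Builds the argument vector for mapping fragment FASTQ against a reference
#' with a supported aligner. Defaults follow common practice for short
#' junction fragments: \code{bwa} runs \code{mem -t 2}; \code{bowtie2} runs
#' \code{--end-to-end --very-sensitive}. A program other than these two is
#' refused unless \code{allowNonstandard = TRUE}, so a typo cannot silently
#' launch an arbitrary binary.
#'
#' @param program aligner executable name (\code{"bwa"} or \code{"bowtie2"},
#'   or anything with \code{allowNonstandard}).
#' @param reference path to the reference FASTA.
#' @param fragments path to the fragment FASTQ.
#' @param options character vector of aligner options; \code{NULL} uses the
#'   per-program default.
#' @param allowNonstandard allow a program other than bwa/bowtie2.
#' @return list with \code{program}, \code{args} (character vector) and
#'   \code{display} (the full command as one string).
#' @examples
#' alignerCommand("bwa", "ref.fa", "fragments.fastq")$display
#' @export
alignerCommand <- function(program, reference, fragments, options = NULL,
                           allowNonstandard = FALSE) {
  standard <- c("bwa", "bowtie2")
  if (!program %in% standard && !allowNonstandard)
    stop(sprintf(paste("aligner '%s' is not one of %s; pass",
                       "allowNonstandard = TRUE to confirm you want it"),
                 program, paste(standard, collapse = "/")))
  if (is.null(options))
    options <- switch(program,
                      bwa = c("mem", "-t", "2"),
                      bowtie2 = c("--end-to-end", "--very-sensitive"),
                      character())
  args <- if (program == "bowtie2")
    c(options, "-x", reference, "-U", fragments)
  else
    c(options, reference, fragments)
  list(program = program, args = args,
       display = paste(c(program, args), collapse = " "))
}

#' Run an external aligner and capture SAM
#'
#' Invokes the aligner built by [alignerCommand()], indexing the reference
#' first if no index is present, and writes SAM. If the aligner did not emit
#' MD tags they are recomputed from the reference with
#' \code{samtools calmd}, since the downstream mismatch filter depends on
#' them. Any SAM produced elsewhere can be used instead of this function;
#' the pipeline only requires standard SAM with MD and AS tags.
#'
#' @inheritParams alignerCommand
#' @param outSam output SAM path.
#' @return \code{outSam}, invisibly.
#' @export
runAligner <- function(program, reference, fragments, outSam, options = NULL,
                       allowNonstandard = FALSE) {
  cmd <- alignerCommand(program, reference, fragments, options,
                        allowNonstandard)
  if (Sys.which(cmd$program) == "")
    stop(sprintf("aligner executable '%s' not found on PATH", cmd$program))
  if (cmd$program == "bwa" && !file.exists(paste0(reference, ".bwt"))) {
    idx <- system2("bwa", c("index", reference), stdout = TRUE,
                   stderr = TRUE)
    if (!is.null(attr(idx, "status")))
      stop("bwa index failed: ", paste(idx, collapse = "\n"))
  }
  err <- tempfile("aligner_stderr_")
  status <- system2(cmd$program, cmd$args, stdout = outSam, stderr = err)
  if (status != 0L)
    stop(sprintf("%s exited with status %d:\n%s", cmd$program, status,
                 paste(readLines(err, warn = FALSE), collapse = "\n")))
  if (!.samHasMD(outSam)) {
    if (Sys.which("samtools") == "")
      stop("aligner omitted MD tags and samtools is not available to add them")
    tmp <- tempfile(fileext = ".sam")
    status <- system2("samtools", c("calmd", outSam, reference),
                      stdout = tmp, stderr = FALSE)
    if (status != 0L) stop("samtools calmd failed")
    file.copy(tmp, outSam, overwrite = TRUE)
  }
  invisible(outSam)
}

# TRUE if the first mapped record of the SAM carries an MD tag.
.samHasMD <- function(samPath) {
  con <- file(samPath, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return(TRUE)  # no mapped records: nothing to fix
    if (startsWith(line, "@")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (bitwAnd(as.integer(f[2]), 4L) != 0L) next
    return(any(startsWith(f[-(1:11)], "MD:Z:")))
  }
}

#' Exact-match oracle aligner
#'
#' A deterministic reference aligner for testing: each fragment is placed by
#' exhaustive exact-substring search against the reference and its reverse
#' complement. A fragment with exactly one placement across both strands is
#' reported mapped with a full-match CIGAR, \code{MD} equal to its length
#' and \code{AS} equal to its length; fragments with zero or multiple
#' placements are reported unmapped. Intended for simulator output, where
#' fragments are exact substrings by construction; it performs no mismatch
#' tolerance whatsoever.
#'
#' @param fragments path to a fragment FASTQ.
#' @param reference path to the reference FASTA.
#' @param outSam output SAM path.
#' @return \code{outSam}, invisibly.
#' @export
#' @importFrom Biostrings readDNAStringSet DNAStringSet PDict matchPDict
#'   reverseComplement
oracleAlign <- function(fragments, reference, outSam) {
  fq <- ShortRead::readFastq(fragments)
  ref <- Biostrings::readDNAStringSet(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  seqs <- as.character(sread(fq))
  quals <- as.character(Biostrings::quality(Biostrings::quality(fq)))
  ids <- sub("\\s.*$", "", as.character(ShortRead::id(fq)))
  useq <- unique(seqs)
  hit <- .oraclePlaceUnique(useq, ref)
  idx <- match(seqs, useq)
  mapped <- hit$n[idx] == 1L
  w <- nchar(seqs)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(ref), Biostrings::width(ref)),
              "@PG\tID:oracleAlign\tPN:tnseqr")
  neg <- !is.na(hit$strand[idx]) & hit$strand[idx] == "-"
  outSeq <- seqs
  outQual <- quals
  if (any(mapped & neg)) {
    i <- which(mapped & neg)
    outSeq[i] <- as.character(reverseComplement(DNAStringSet(seqs[i])))
    outQual[i] <- as.character(Biostrings::reverse(Biostrings::BStringSet(quals[i])))
  }
  rec <- ifelse(mapped,
    sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s\tNM:i:0\tMD:Z:%d\tAS:i:%d",
            ids, ifelse(neg, 16L, 0L), hit$rname[idx], hit$pos[idx], w,
            outSeq, outQual, w, w),
    sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", ids, seqs, quals))
  writeLines(c(header, rec), outSam)
  invisible(outSam)
}

# Place unique fragment sequences by exact search on both strands of every
# reference sequence. Returns parallel vectors: n (total placements), rname,
# pos (1-based leftmost on + reference coordinates), strand.
.oraclePlaceUnique <- function(useq, ref) {
  n <- integer(length(useq))
  rname <- rep(NA_character_, length(useq))
  pos <- rep(NA_integer_, length(useq))
  strand <- rep(NA_character_, length(useq))
  widths <- nchar(useq)
  for (w in unique(widths)) {
    grp <- which(widths == w)
    fw <- DNAStringSet(useq[grp])
    rv <- reverseComplement(fw)
    for (r in seq_along(ref)) {
      subject <- ref[[r]]
      for (str in c("+", "-")) {
        pats <- if (str == "+") fw else rv
        m <- tryCatch(matchPDict(PDict(pats), subject), error = function(e) NULL)
        if (is.null(m)) {  # e.g. ambiguity letters: per-pattern fallback
          starts <- lapply(seq_along(pats), function(k)
            BiocGenerics::start(Biostrings::matchPattern(pats[[k]], subject)))
        } else {
          starts <- Biostrings::startIndex(m)
        }
        cnt <- vapply(starts, length, integer(1))
        n[grp] <- n[grp] + cnt
        first <- vapply(starts, function(s) if (length(s)) s[1] else NA_integer_,
                        integer(1))
        new <- cnt > 0L & is.na(pos[grp])
        rname[grp][new] <- names(ref)[r]
        pos[grp][new] <- first[new]
        strand[grp][new] <- str
      }
    }
  }
  list(n = n, rname = rname, pos = pos, strand = strand)
}
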