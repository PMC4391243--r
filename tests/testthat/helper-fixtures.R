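# Fixture builders shared across the suite. Everything is generated in
# code at test time; nothing binary ships with the package.

# Write a SAM file from a data.frame of records. Columns: qname, flag,
# rname, pos, cigar, seq, md (NA = omit tag), as (NA = omit tag).
writeSamFixture <- function(records, refLengths, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(refLengths),
                      as.integer(refLengths)))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    tags <- character()
    if (!is.na(r$md)) tags <- c(tags, paste0("MD:Z:", r$md))
    if (!is.na(r$as)) tags <- c(tags, paste0("AS:i:", r$as))
    paste(c(r$qname, r$flag, r$rname, r$pos, 60, r$cigar, "*", 0, 0,
            r$seq, strrep("I", nchar(r$seq)), tags), collapse = "\t")
  }, character(1))
  writeLines(c(header, lines), path)
  path
}

# A mapped 30M record with given mismatch count encoded in the MD tag.
samRecord <- function(qname, pos, depthAS, nMismatch = 0L, flag = 0L,
                      rname = "chr", len = 30L) {
  md <- if (nMismatch == 0L) as.character(len) else {
    run <- (len - nMismatch) %/% (nMismatch + 1L)
    paste0(paste(rep(paste0(run, "A"), nMismatch), collapse = ""),
           len - nMismatch * (run + 1L))
  }
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             cigar = paste0(len, "M"), seq = strrep("A", len),
             md = md, as = depthAS, stringsAsFactors = FALSE)
}

# The noisy-SAM sweep fixture: 10 true sites (depth 5, perfect, AS 50),
# 10 clean noise sites (depth 1, AS 10), 10 mismatching noise sites
# (depth 1, 2 mismatches, AS 10).
noisySamFixture <- function(path) {
  recs <- list()
  for (i in 1:10)
    for (j in 1:5)
      recs[[length(recs) + 1L]] <-
        samRecord(sprintf("true%d_%d", i, j), 1000L + i * 100L, 50L)
  for (i in 1:10)
    recs[[length(recs) + 1L]] <-
      samRecord(sprintf("noiseA%d", i), 5000L + i * 100L, 10L)
  for (i in 1:10)
    recs[[length(recs) + 1L]] <-
      samRecord(sprintf("noiseB%d", i), 8000L + i * 100L, 10L,
                nMismatch = 2L)
  writeSamFixture(do.call(rbind, recs), c(chr = 20000L), path)
}

# Write a FASTQ from parallel character vectors.
writeFastqFixture <- function(ids, seqs, quals, path, compress = FALSE) {
  fq <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(seqs),
    quality = Biostrings::PhredQuality(Biostrings::BStringSet(quals)),
    id = Biostrings::BStringSet(ids))
  if (file.exists(path)) file.remove(path)
  ShortRead::writeFastq(fq, path, compress = compress)
  path
}

# Independent alignment-reconstruction oracle: walk read and reference
# through a CIGAR and return the substitution count and the MD tag it
# implies. Used to cross-check MD parsing against first principles.
alignmentOracle <- function(read, ref, refStart, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ri <- 1L  # read cursor
  gi <- refStart  # reference cursor
  nSub <- 0L
  md <- character()
  run <- 0L
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    type <- sub("^[0-9]+", "", op)
    if (type %in% c("M", "=", "X")) {
      for (k in seq_len(n)) {
        rb <- substr(read, ri, ri); gb <- substr(ref, gi, gi)
        if (rb == gb) run <- run + 1L
        else {
          nSub <- nSub + 1L
          md <- c(md, as.character(run), gb); run <- 0L
        }
        ri <- ri + 1L; gi <- gi + 1L
      }
    } else if (type == "I") {
      ri <- ri + n
    } else if (type %in% c("D", "N")) {
      md <- c(md, as.character(run),
              paste0("^", substr(ref, gi, gi + n - 1L)))
      run <- 0L
      gi <- gi + n
    } else if (type %in% c("S", "H")) {
      if (type == "S") ri <- ri + n
    }
  }
  md <- c(md, as.character(run))
  list(nSub = nSub, md = paste(md, collapse = ""))
}

# Reference span of a CIGAR by direct enumeration (independent of the
# implementation's CIGAR machinery).
cigarRefSpanOracle <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  sum(vapply(ops, function(op) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    if (sub("^[0-9]+", "", op) %in% c("M", "D", "N", "=", "X")) n else 0L
  }, integer(1)))
}
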