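test_that("motif search finds both orientations with deterministic priority", {
  m <- motifSpec("TCAG")
  expect_equal(motifRevcomp(m), "CTGA")

  hit <- findMotif("AAATCAGGGCCTT", m)
  expect_true(hit$found)
  expect_equal(hit$orientation, "forward")
  expect_equal(hit$matchEnd, 7L)  # 0-based end offset 7 = 1-based end 7

  hit <- findMotif("GGCCTTCTGAAAA", m)
  expect_equal(hit$orientation, "revcomp")
  expect_equal(hit$matchStart, 7L)  # 0-based start index 6

  expect_false(findMotif("AAAAAAA", m)$found)
  # leftmost occurrence wins within an orientation
  hit <- findMotif("TCAGAATCAGAA", m)
  expect_equal(hit$matchStart, 1L)
  # forward beats revcomp when both occur
  hit <- findMotif("CTGAAATCAG", m)
  expect_equal(hit$orientation, "forward")
  # N in the read never matches a motif position
  expect_false(findMotif("AATCNGAA", m)$found)
})

test_that("motif validation rejects non-DNA characters", {
  expect_error(motifSpec("TCAX"), "X")
  expect_error(motifSpec(""), "")
})

test_that("fragment extraction follows the junction in both orientations", {
  m <- motifSpec("TCAG")
  r <- extractFragment("AAATCAGGGCCTT", "FFFFFFFFFFFFF", m, minLen = 2)
  expect_equal(r$status, "ok")
  expect_equal(r$sequence, "GGCCTT")
  expect_equal(r$quality, "FFFFFF")
  expect_equal(r$orientation, "forward")

  # same read at the default minimum is too short
  r <- extractFragment("AAATCAGGGCCTT", "FFFFFFFFFFFFF", m, minLen = 20)
  expect_equal(r$status, "too_short")

  # revcomp orientation: bases before the match, reverse-complemented,
  # qualities reversed
  r <- extractFragment("GGCCTTCTGAAAA", "123456FFFFFFF", m, minLen = 2)
  expect_equal(r$sequence, "AAGGCC")
  expect_equal(r$quality, "654321")
  expect_equal(r$orientation, "revcomp")

  expect_equal(extractFragment("AAAAAAA", "FFFFFFF", m)$status, "no_motif")
  # motif at the very end yields a zero-length fragment -> too_short
  expect_equal(extractFragment("AAATCAG", "FFFFFFF", m, minLen = 1)$status,
               "too_short")
  # malformed record is a hard error naming the read
  expect_error(extractFragment("ACGT", "FFF", m, id = "bad_read"), "bad_read")
})

test_that("both orientations of a junction recover the same fragment", {
  # the emitted fragment must map to the same junction regardless of the
  # strand the read was sequenced from
  m <- motifSpec("TCAG")
  genome <- "TTGACCAGGCATCAAGGCCTTACCAGTT"
  junction <- substr(genome, 12, 22)  # fragment adjacent to the insertion
  fwdRead <- paste0("AA", motifSequence(m), junction)
  revRead <- revComp(fwdRead)
  rf <- extractFragment(fwdRead, strrep("I", nchar(fwdRead)), m, minLen = 5)
  rr <- extractFragment(revRead, strrep("I", nchar(revRead)), m, minLen = 5)
  expect_equal(rf$sequence, junction)
  expect_equal(rr$sequence, junction)
  expect_equal(rr$orientation, "revcomp")
})

test_that("maxLen truncation keeps the junction-proximal bases", {
  m <- motifSpec("TCAG")
  r <- extractFragment("TCAGAACCGGTT", strrep("I", 12), m, minLen = 2,
                       maxLen = 4)
  expect_equal(r$sequence, "AACC")  # bases nearest the motif end
  rv <- extractFragment("AACCGGTTCTGA", strrep("I", 12), m, minLen = 2,
                        maxLen = 4)
  expect_equal(rv$sequence, revComp("GGTT"))  # nearest the revcomp match
})

test_that("paired-end processing keeps mate 1 when both mates survive", {
  m <- motifSpec("TCAG")
  dir <- withr::local_tempdir()
  frag1 <- "ACCGGTTAACCGGTTAACCGGTTAA"
  frag2 <- "TGGCCAATTGGCCAATTGGCCAATT"
  mk <- function(frag) paste0("TCAG", frag)
  # pair 1: both mates carry the motif; pair 2: only mate 1; pair 3: neither
  f1 <- writeFastqFixture(c("p1/1", "p2/1", "p3/1"),
                          c(mk(frag1), mk(frag1), strrep("A", 29)),
                          rep(strrep("I", 29), 3),
                          file.path(dir, "r1.fastq"))
  f2 <- writeFastqFixture(c("p1/2", "p2/2", "p3/2"),
                          c(mk(frag2), strrep("G", 29), strrep("A", 29)),
                          rep(strrep("I", 29), 3),
                          file.path(dir, "r2.fastq"))
  out <- file.path(dir, "frags.fastq")
  res <- prepReads(f1, f2, m, minLen = 10, maxLen = 50, outFastq = out)
  emitted <- ShortRead::readFastq(out)
  expect_equal(res$nEmitted, 2L)
  expect_equal(res$nMateDiscarded, 1L)
  ids <- as.character(ShortRead::id(emitted))
  expect_true(any(grepl("^p1/1", ids)))   # mate 1 won for pair 1
  expect_false(any(grepl("^p1/2", ids)))
  # conservation over all input reads
  expect_equal(res$nInput,
               res$nEmitted + res$nNoMotif + res$nTooShort +
                 res$nMateDiscarded)
  # desynchronized pairs are a hard error
  f3 <- writeFastqFixture("other/2", mk(frag2), strrep("I", 29),
                          file.path(dir, "r3.fastq"))
  expect_error(prepReads(f1, f3, m, outFastq = out), "desynchronized")
})

test_that("file-level extraction conserves reads and is deterministic", {
  dir <- withr::local_tempdir()
  set.seed(11)
  n <- 200
  bases <- c("A", "C", "G", "T")
  frags <- vapply(seq_len(n), function(i)
    paste(sample(bases, 30, replace = TRUE), collapse = ""), character(1))
  hasMotif <- seq_len(n) %% 4 != 0
  seqs <- ifelse(hasMotif, paste0("TCAG", frags), paste0("AAAA", frags))
  seqs[1:10] <- "TCAGAC"  # motif present but fragment below minimum
  fq <- writeFastqFixture(sprintf("r%03d", seq_len(n)), seqs,
                          strrep("I", nchar(seqs)),
                          file.path(dir, "in.fastq"))
  out <- file.path(dir, "out.fastq")
  res <- prepReads(fq, motifs = motifSpec("TCAG"), minLen = 20,
                   outFastq = out, qcPrefix = file.path(dir, "qc"))
  expect_equal(res$nInput,
               res$nEmitted + res$nNoMotif + res$nTooShort +
                 res$nMateDiscarded)
  # the vectorized file path agrees read-for-read with the per-read rule
  perRead <- vapply(seq_len(n), function(i)
    extractFragment(seqs[i], strrep("I", nchar(seqs[i])),
                    motifSpec("TCAG"), minLen = 20)$status, character(1))
  expect_equal(res$nTooShort, sum(perRead == "too_short"))
  expect_equal(res$nNoMotif, sum(perRead == "no_motif"))
  expect_equal(res$nEmitted, sum(perRead == "ok"))
  # every emitted fragment is a substring (or the reverse complement of a
  # substring) of its source read
  emitted <- ShortRead::readFastq(out)
  ids <- sub(" .*$", "", as.character(ShortRead::id(emitted)))
  srcSeq <- seqs[match(ids, sprintf("r%03d", seq_len(n)))]
  fragSeq <- as.character(ShortRead::sread(emitted))
  expect_true(all(mapply(function(f, s)
    grepl(f, s, fixed = TRUE) || grepl(revComp(f), s, fixed = TRUE),
    fragSeq, srcSeq)))
  # re-running on identical input is byte-identical
  out2 <- file.path(dir, "out2.fastq")
  prepReads(fq, motifs = motifSpec("TCAG"), minLen = 20, outFastq = out2)
  expect_identical(readLines(out), readLines(out2))
  # run log was written with the same ledger
  log <- tnseqr:::readRunLog(file.path(dir, "qc.prep.log"))
  expect_equal(log$nInput, log$nEmitted + log$nNoMotif + log$nTooShort +
                 log$nMateDiscarded)
})

test_that("gzipped FASTQ is detected by content, not extension", {
  dir <- withr::local_tempdir()
  plain <- writeFastqFixture("r1", "TCAGACCGGTTAACCGGTTAACCGGTT",
                             strrep("I", 27), file.path(dir, "a.fastq"))
  gzNoExt <- file.path(dir, "b.fastq")  # gzip content, plain name
  writeFastqFixture("r1", "TCAGACCGGTTAACCGGTTAACCGGTT", strrep("I", 27),
                    file.path(dir, "tmp.fastq.gz"), compress = TRUE)
  file.copy(file.path(dir, "tmp.fastq.gz"), gzNoExt)
  for (f in c(plain, gzNoExt)) {
    out <- file.path(dir, paste0(basename(f), ".out"))
    res <- prepReads(f, motifs = motifSpec("TCAG"), minLen = 10,
                     outFastq = out)
    expect_equal(res$nEmitted, 1L)
  }
})

test_that("QC tables report composition percentages and quality quartiles", {
  dir <- withr::local_tempdir()
  fq <- writeFastqFixture(c("a", "b"), c("AA", "AC"), c("II", "II"),
                          file.path(dir, "two.fastq"))
  qc <- qcSummaries(fq)
  expect_equal(qc$basecomp$A, c(100, 50))
  expect_equal(qc$basecomp$C, c(0, 50))
  expect_equal(rowSums(qc$basecomp[, c("A", "C", "G", "T", "N")]),
               c(100, 100))
  # constant phred 40 -> all quartiles 40 at every position
  expect_true(all(qc$qualquartile$q1 == 40) && all(qc$qualquartile$q3 == 40))

  # 1000 uniform random reads: each base 25% +/- 5% at each position
  set.seed(3)
  seqs <- vapply(1:1000, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  fq2 <- writeFastqFixture(sprintf("u%d", 1:1000), seqs,
                           strrep("I", nchar(seqs)),
                           file.path(dir, "unif.fastq"))
  qc2 <- qcSummaries(fq2)
  comp <- as.matrix(qc2$basecomp[, c("A", "C", "G", "T")])
  expect_true(all(abs(comp - 25) < 5))
  expect_warning(qcSummaries(ShortRead::ShortReadQ()), "empty|no reads")
})
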