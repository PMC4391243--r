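test_that("MD-tag mismatch counting counts substitutions only", {
  expect_equal(countMismatches("50"), 0L)
  expect_equal(countMismatches("10A5C3"), 2L)
  # deletions (^-runs) are not mismatches
  expect_equal(countMismatches("3^AC10T5"), 1L)
  expect_equal(countMismatches(c("0A0C0", "30", "5^GATC5")), c(2L, 0L, 0L))
  expect_error(countMismatches("10a5"), "malformed")
  expect_error(countMismatches(""), "malformed")
})

test_that("MD counting agrees with a brute-force alignment reconstruction", {
  # toy case: 3 matches, 2-base deletion, 10 matches, 1 substitution, 5
  ref <- "TTACGATCAACGTACCGTTAGCATAAGGTC"
  # read: ref[3..5], skip ref[6..7] (deletion), ref[8..17],
  # mismatch at ref[18], ref[19..23]
  read <- paste0(substr(ref, 3, 5), substr(ref, 8, 17),
                 "A",  # ref has C at 18
                 substr(ref, 19, 23))
  stopifnot(substr(ref, 18, 18) != "A")
  orc <- alignmentOracle(read, ref, refStart = 3L, cigar = "3M2D16M")
  expect_match(orc$md, "\\^")  # the deletion shows up as a ^-run
  expect_equal(orc$nSub, 1L)
  expect_equal(countMismatches(orc$md), orc$nSub)

  # randomized property: reconstructed MD always re-counts to the planted
  # substitution number
  set.seed(9)
  for (i in 1:20) {
    refLen <- 60L
    r <- paste(sample(c("A", "C", "G", "T"), refLen, replace = TRUE),
               collapse = "")
    start <- sample(1:10, 1)
    len <- 30L
    read <- substr(r, start, start + len - 1L)
    nSub <- sample(0:3, 1)
    posSub <- sample(seq_len(len), nSub)
    for (p in posSub) {
      old <- substr(read, p, p)
      substr(read, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    orc <- alignmentOracle(read, r, start, paste0(len, "M"))
    expect_equal(countMismatches(orc$md), nSub)
  }
})

test_that("mismatch and score filters honor integer and fractional forms", {
  expect_true(passesFilters(0, 50, 0, 50, 30))
  expect_false(passesFilters(1, 50, 0, 50, 30))
  # fractional: 10% of a 30 bp read allows 3 mismatches
  expect_true(passesFilters(3, 0, 0.1, 0, 30))
  expect_false(passesFilters(4, 0, 0.1, 0, 30))
  # score below threshold fails; missing AS fails
  expect_false(passesFilters(0, 49, 0, 50, 30))
  expect_false(passesFilters(0, NA, 0, -100, 30))
  # negative thresholds (bowtie2 scale)
  expect_true(passesFilters(0, -5, 0, -10, 30))
  expect_false(passesFilters(0, -15, 0, -10, 30))
})

test_that("insertion position is the junction-adjacent base on each strand", {
  expect_equal(insertionPosition(100, "30M", "+"), 100L)
  expect_equal(insertionPosition(100, "30M", "-"), 129L)
  # deletions consume reference, insertions and soft clips do not
  expect_equal(insertionPosition(100, "10M2D20M", "-"), 131L)
  expect_equal(insertionPosition(100, "5S25M", "-"), 124L)
  expect_equal(insertionPosition(100, "10M3I17M", "-"), 126L)
  # cross-check the reference span against direct CIGAR enumeration
  cigars <- c("30M", "10M2D20M", "5S25M", "10M3I17M", "4M1D4M1D4M", "50M10S")
  for (cg in cigars)
    expect_equal(insertionPosition(1000, cg, "-"),
                 1000L + cigarRefSpanOracle(cg) - 1L)
})

test_that("collapse merges exact-distance pairs in a single pass", {
  t1 <- collapseSites(insertionTable("c", c(100L, 108L), c(5L, 3L)), 8)
  expect_equal(as.data.frame(t1),
               data.frame(reference = "c", position = 100L, depth = 8L))
  # no re-chaining: 116 is left alone once 108 has merged into 100
  t2 <- collapseSites(insertionTable("c", c(100L, 108L, 116L), c(5L, 3L, 2L)),
                      8)
  expect_equal(as.data.frame(t2)$position, c(100L, 116L))
  expect_equal(as.data.frame(t2)$depth, c(8L, 2L))
  # only *exactly* d apart merges
  t3 <- collapseSites(insertionTable("c", c(100L, 107L), c(5L, 3L)), 8)
  expect_equal(nSites(t3), 2L)
  # d = 0 is the identity
  t4 <- insertionTable("c", c(1L, 9L), c(1L, 1L))
  expect_identical(as.data.frame(collapseSites(t4, 0)), as.data.frame(t4))
  # different references never merge
  t5 <- collapseSites(insertionTable(c("a", "b"), c(100L, 108L), c(2L, 2L)), 8)
  expect_equal(nSites(t5), 2L)
  # depth is conserved by collapsing, for random tables
  set.seed(4)
  for (i in 1:10) {
    pos <- sort(sample.int(500, 60))
    tab <- insertionTable("c", pos, sample(1:9, 60, replace = TRUE))
    out <- collapseSites(tab, sample(0:10, 1))
    expect_equal(totalReads(out), totalReads(tab))
  }
})

test_that("coverage filter drops shallow sites and recomputes totals", {
  tab <- insertionTable("c", c(100L, 200L), c(1L, 5L))
  out <- coverageFilter(tab, 2)
  expect_equal(as.data.frame(out)$position, 200L)
  expect_equal(totalReads(out), 5L)
  expect_identical(as.data.frame(coverageFilter(tab, 1)), as.data.frame(tab))
  expect_warning(coverageFilter(insertionTable("c", 1L, 1L), 2),
                 "removed every site")
})

test_that("SAM processing filters, calls and logs with full conservation", {
  dir <- withr::local_tempdir()
  recs <- rbind(
    samRecord("pass1", 100L, 50L),
    samRecord("pass2", 100L, 50L),
    samRecord("pass3", 500L, 60L, flag = 16L),
    samRecord("mis1", 300L, 50L, nMismatch = 2L),
    samRecord("lowscore1", 400L, 10L),
    samRecord("sec1", 200L, 50L, flag = 256L),
    data.frame(qname = "unm1", flag = 4L, rname = "*", pos = 0L, cigar = "*",
               seq = strrep("A", 30), md = NA, as = NA))
  sam <- writeSamFixture(recs, c(chr = 10000L), file.path(dir, "mix.sam"))
  logPath <- file.path(dir, "process.log")
  tab <- callInsertions(sam, maxMismatch = 0, minAlignScore = 50,
                        logPath = logPath)
  cnt <- attr(tab, "counts")
  expect_equal(cnt$nRecords,
               cnt$nPassed + cnt$nFailMismatch + cnt$nFailScore +
                 cnt$nUnmapped + cnt$nSecondary)
  expect_equal(cnt$nPassed, 3L)
  expect_equal(cnt$nFailMismatch, 1L)
  expect_equal(cnt$nFailScore, 1L)
  expect_equal(cnt$nSecondary, 1L)
  expect_equal(cnt$nUnmapped, 1L)
  df <- as.data.frame(tab)
  # minus-strand read at 500 with 30M lands on its rightmost base
  expect_equal(df$position, c(100L, 529L))
  expect_equal(df$depth, c(2L, 1L))
  log <- tnseqr:::readRunLog(logPath)
  expect_equal(log$nRecords, log$nPassed + log$nFailMismatch +
                 log$nFailScore + log$nUnmapped + log$nSecondary)
})

test_that("parameter sweep is monotone and converges at top stringency", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "noisy.sam")
  noisySamFixture(sam)
  sweep <- parameterSweep(sam, mismatchGrid = c(0, 2, 5),
                          scoreGrid = c(0, 30, 50))
  # loosest cell sees every site, strictest only the true ones
  expect_equal(sweep$uniquePositions[sweep$maxMismatch == 5 &
                                       sweep$minAlignScore == 0], 30L)
  expect_equal(sweep$uniquePositions[sweep$maxMismatch == 0 &
                                       sweep$minAlignScore == 50], 10L)
  # non-increasing as the score tightens, at every mismatch level
  for (mm in unique(sweep$maxMismatch)) {
    s <- sweep[sweep$maxMismatch == mm, ]
    s <- s[order(s$minAlignScore), ]
    expect_true(all(diff(s$uniquePositions) <= 0))
  }
  # non-increasing as the mismatch allowance tightens, at every score
  for (sc in unique(sweep$minAlignScore)) {
    s <- sweep[sweep$minAlignScore == sc, ]
    s <- s[order(s$maxMismatch), ]
    expect_true(all(diff(rev(s$uniquePositions)) <= 0))
  }
  # at the top score stringency the mismatch columns agree exactly
  top <- sweep[sweep$minAlignScore == 50, ]
  expect_equal(length(unique(top$uniquePositions)), 1L)
  # true sites keep their depth-5 coverage
  expect_equal(top$meanDepth, rep(5, nrow(top)))
})
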