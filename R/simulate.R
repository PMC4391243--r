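#' Simulate a toy genome and gene annotation
#'
#' Draws a uniform-random DNA sequence and places non-overlapping coding
#' features on alternating strands along it, deterministically under the
#' seed. Genes are laid out one per equal-width slot with margins, so
#' they never overlap and leave intergenic space.
#'
#' @param genomeLength genome length in bp.
#' @param nGenes number of genes.
#' @param seed integer seed (mandatory: simulator output must be
#'   reproducible).
#' @param referenceName name of the single reference sequence.
#' @return list: \code{genome} ([Biostrings::DNAStringSet]) and
#'   \code{genes} ([GenomicRanges::GRanges] with gene_id/product).
#' @export
simulateGenome <- function(genomeLength, nGenes, seed,
                           referenceName = "sim_chr") {
  stopifnot(genomeLength > 0, nGenes > 0, !missing(seed))
  set.seed(seed)
  slot <- genomeLength %/% nGenes
  if (slot < 60L)
    stop("genes cannot fit: need at least 60 bp of genome per gene")
  genome <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), genomeLength, replace = TRUE),
    collapse = ""))
  names(genome) <- referenceName
  # each gene occupies the middle ~80% of its slot, jittered
  slotStart <- (seq_len(nGenes) - 1L) * slot + 1L
  margin <- pmax(1L, as.integer(slot * 0.1))
  gstart <- slotStart + margin + sample.int(margin, nGenes, replace = TRUE) - 1L
  gend <- slotStart + slot - margin -
    sample.int(margin, nGenes, replace = TRUE) + 1L
  gend <- pmin(gend, genomeLength)
  genes <- GRanges(referenceName, IRanges(gstart, gend),
                   strand = rep_len(c("+", "-"), nGenes))
  mcols(genes) <- DataFrame(
    gene_id = sprintf("simgene_%04d", seq_len(nGenes)),
    product = sprintf("hypothetical protein %04d", seq_len(nGenes)))
  list(genome = genome, genes = genes)
}

# Remove every occurrence of a motif (and its reverse complement) from a
# genome string by complementing the middle base of each hit, repeating
# until none remain. Deterministic (no RNG), so seeded output stays
# reproducible. Random genomes of a few hundred kb contain O(1) chance
# hits of a 10 bp motif; scrubbing them makes the transposon terminus
# unambiguous in every simulated read.
scrubMotif <- function(gseq, motif) {
  pats <- unique(c(motif, revComp(motif)))
  repeat {
    found <- FALSE
    for (pat in pats) {
      repeat {
        i <- regexpr(pat, gseq, fixed = TRUE)
        if (i < 0L) break
        found <- TRUE
        mid <- i + nchar(pat) %/% 2L
        substr(gseq, mid, mid) <- chartr("ACGT", "TGCA",
                                         substr(gseq, mid, mid))
      }
    }
    if (!found) return(gseq)
  }
}

#' Simulate a transposon mutant library
#'
#' Generates the full test bed for the pipeline: a toy genome with
#' annotation, planted insertion sites, and junction reads carrying the
#' transposon terminal motif, plus a truth table recording every planted
#' site and its read depths.
#'
#' Each read is \code{[filler] + motif + genomic fragment}. For a
#' forward-orientation junction at position p the fragment is the genome
#' starting at p; a reverse-orientation junction (the other transposon end,
#' emitted with probability \code{fracReverse}) is displaced by exactly
#' \code{tsdLength} -- the target-site duplication -- and contributes the
#' reverse-complemented genome ending at p + tsdLength, so that collapsing
#' at the duplication distance merges the two junctions back to p. Reads
#' are additionally reverse-complemented whole with probability
#' \code{fracFlippedReads} to emulate sequencing off either strand.
#' Substitution errors at \code{baseErrorRate} are applied to the genomic
#' part only, never the motif. Planted positions keep a minimum spacing of
#' \code{2 * tsdLength + 1} bp so junction sites of distinct mutants can
#' neither coincide nor collapse into each other, and the genome is
#' scrubbed of chance occurrences of the motif so that the transposon
#' terminus is unambiguous in every read.
#'
#' @param outDir output directory (created).
#' @param genomeLength,nGenes,seed see [simulateGenome()].
#' @param nInsertions number of planted insertion sites.
#' @param tsdLength target-site duplication length in bp (default 8, the
#'   ISS1-type value; 0 disables displacement).
#' @param motif a [MotifSpec-class] (default the 10 bp motif
#'   \code{TAAGAGACAG}).
#' @param readLength total read length in bp (default 60: 10 bp motif +
#'   50 bp genomic fragment).
#' @param meanReadsPerInsertion mean of the geometric (support >= 1) read
#'   count per insertion (default 5).
#' @param fracReverse probability a read comes from the reverse-orientation
#'   junction (default 0.5).
#' @param fracFlippedReads probability a read is emitted as its reverse
#'   complement (default 0.5).
#' @param baseErrorRate per-base substitution error rate on the genomic
#'   part (default 0).
#' @param fillerLength bases of random non-genomic sequence before the
#'   motif (default 0).
#' @return list with paths (\code{genomeFasta}, \code{gff}, \code{fastq},
#'   \code{truthTsv}), the in-memory \code{genome}, \code{genes} and
#'   \code{truth} (data.frame with one row per insertion: \code{reference};
#'   \code{position}, the canonical recoverable coordinate -- the forward
#'   junction when any forward-orientation read was emitted, otherwise the
#'   reverse junction displaced by \code{tsdLength}; \code{junction_fwd},
#'   the planted forward-junction coordinate; \code{planted_depth_fwd} and
#'   \code{planted_depth_rev}), and \code{nReads}.
#' @export
#' @importFrom rtracklayer export
simulateLibrary <- function(outDir, genomeLength = 5e5, nGenes = 400,
                            nInsertions = 5000, tsdLength = 8L,
                            motif = motifSpec("TAAGAGACAG"),
                            readLength = 60L, meanReadsPerInsertion = 5,
                            fracReverse = 0.5, fracFlippedReads = 0.5,
                            baseErrorRate = 0, fillerLength = 0L, seed) {
  stopifnot(!missing(seed), nInsertions > 0, readLength > nchar(motifSequence(motif)))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulateGenome(genomeLength, nGenes, seed)
  gseq <- scrubMotif(as.character(sim$genome[[1]]), motifSequence(motif))
  genome <- Biostrings::DNAStringSet(gseq)
  names(genome) <- names(sim$genome)
  refName <- names(genome)[1]
  fragLen <- readLength - fillerLength - nchar(motifSequence(motif))
  stopifnot(fragLen >= 1L)

  # planted positions: uniform with minimum spacing > 2 * tsd so that
  # fwd/rev junction sites of distinct insertions never interact
  gap <- 2L * tsdLength + 1L
  lo <- fragLen + tsdLength + 1L
  hi <- genomeLength - fragLen - tsdLength - 1L
  nSlots <- hi - lo - (nInsertions - 1L) * gap
  if (nSlots < nInsertions)
    stop("n_insertions too large for genome length at the required spacing")
  posBase <- sort(sample.int(nSlots, nInsertions))
  positions <- lo + posBase + (seq_len(nInsertions) - 1L) * gap

  nReads <- 1L + stats::rgeom(nInsertions, 1 / meanReadsPerInsertion)
  insIdx <- rep(seq_len(nInsertions), nReads)
  total <- length(insIdx)
  isRev <- stats::runif(total) < fracReverse
  flipped <- stats::runif(total) < fracFlippedReads

  p <- positions[insIdx]
  fwdFrag <- substring(gseq, p, p + fragLen - 1L)
  q <- p + tsdLength
  revFrag <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(gseq, q - fragLen + 1L, q))))
  frag <- ifelse(isRev, revFrag, fwdFrag)

  if (baseErrorRate > 0) {
    fragChars <- strsplit(frag, "")
    frag <- vapply(fragChars, function(ch) {
      err <- stats::runif(length(ch)) < baseErrorRate
      if (any(err))
        ch[err] <- vapply(ch[err], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      paste(ch, collapse = "")
    }, character(1))
  }

  filler <- if (fillerLength > 0L)
    vapply(seq_len(total), function(i)
      paste(sample(c("A", "C", "G", "T"), fillerLength, replace = TRUE),
            collapse = ""), character(1))
  else rep("", total)
  reads <- paste0(filler, motifSequence(motif), frag)
  if (any(flipped))
    reads[flipped] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[flipped])))
  quals <- strrep("I", nchar(reads))
  ids <- sprintf("simread_%06d ins:%d or:%s", seq_len(total), insIdx,
                 ifelse(isRev, "rev", "fwd"))

  depthFwd <- as.integer(tabulate(insIdx[!isRev], nInsertions))
  depthRev <- as.integer(tabulate(insIdx[isRev], nInsertions))
  # canonical recoverable coordinate: the lower (forward) junction when any
  # forward read exists; an insertion sequenced only from the reverse
  # junction is observable only at the displaced site
  truth <- data.frame(
    reference = refName,
    position = ifelse(depthFwd > 0L, positions, positions + tsdLength),
    junction_fwd = positions,
    planted_depth_fwd = depthFwd,
    planted_depth_rev = depthRev)

  genomeFasta <- file.path(outDir, "genome.fasta")
  gff <- file.path(outDir, "genes.gff3")
  fastq <- file.path(outDir, "reads.fastq")
  truthTsv <- file.path(outDir, "truth.tsv")
  Biostrings::writeXStringSet(genome, genomeFasta)
  genesOut <- sim$genes
  mcols(genesOut) <- DataFrame(type = "CDS", phase = 0L,
                               ID = sim$genes$gene_id,
                               locus_tag = sim$genes$gene_id,
                               product = sim$genes$product,
                               source = "tnseqr_sim")
  rtracklayer::export(genesOut, gff, format = "gff3")
  fq <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(reads),
    quality = Biostrings::PhredQuality(Biostrings::BStringSet(quals)),
    id = Biostrings::BStringSet(ids))
  if (file.exists(fastq)) file.remove(fastq)
  ShortRead::writeFastq(fq, fastq, compress = FALSE)
  writeLines(c(sprintf("# seed\t%d", seed),
               paste("reference", "position", "junction_fwd",
                     "planted_depth_fwd", "planted_depth_rev", sep = "\t"),
               sprintf("%s\t%d\t%d\t%d\t%d", truth$reference, truth$position,
                       truth$junction_fwd, truth$planted_depth_fwd,
                       truth$planted_depth_rev)),
             truthTsv)
  list(genomeFasta = genomeFasta, gff = gff, fastq = fastq,
       truthTsv = truthTsv, genome = genome, genes = sim$genes,
       truth = truth, nReads = total, seed = seed)
}

#' Simulate a pair of pools from one abundance distribution
#'
#' Draws shared insertion sites whose per-pool read depths come from the
#' same geometric abundance distribution, for calibrating the compare
#' stage under the null of no condition effect.
#'
#' @param nShared number of shared sites.
#' @param meanDepth mean of the geometric depth distribution (support
#'   >= 1).
#' @param seed integer seed.
#' @return list of two [InsertionTable-class]s, \code{input} and
#'   \code{output}, with identical positions.
#' @export
simulatePoolPair <- function(nShared, meanDepth = 5, seed) {
  stopifnot(!missing(seed), nShared >= 2)
  set.seed(seed)
  pos <- sort(sample.int(nShared * 100L, nShared))
  di <- 1L + stats::rgeom(nShared, 1 / meanDepth)
  do <- 1L + stats::rgeom(nShared, 1 / meanDepth)
  list(input = insertionTable(rep("sim_chr", nShared), pos, di),
       output = insertionTable(rep("sim_chr", nShared), pos, do))
}
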