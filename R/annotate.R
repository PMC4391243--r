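#' Write / read an insertion position table
#'
#' The on-disk form is a tab-delimited text file with columns
#' \code{reference}, \code{position}, \code{depth} -- the interchange
#' format between the SAM-processing, counts and compare stages.
#'
#' @param x an [InsertionTable-class].
#' @param path file path.
#' @return \code{writePositions}: the path, invisibly;
#'   \code{readPositions}: an [InsertionTable-class].
#' @export
writePositions <- function(x, path) {
  stopifnot(is(x, "InsertionTable"))
  writeTsv(as.data.frame(x), path)
}

#' @rdname writePositions
#' @export
readPositions <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("reference", "position", "depth") %in% names(df)))
  insertionTable(df$reference, df$position, df$depth)
}

#' Read gene annotation from GFF
#'
#' Imports GFF3 or GFF2, keeps coding features (type \code{CDS} when
#' present, otherwise \code{gene}), and derives a gene identifier from the
#' first available of the \code{ID}, \code{locus_tag}, \code{gene_id}
#' attributes.
#'
#' @param gff path to a GFF file.
#' @return a [GenomicRanges::GRanges] with metadata columns \code{gene_id}
#'   and \code{product}.
#' @export
#' @importFrom rtracklayer import
#' @importFrom S4Vectors subjectHits queryHits
readGeneAnnotation <- function(gff) {
  gr <- rtracklayer::import(gff, format = "gff")
  types <- as.character(gr$type)
  keep <- if (any(types == "CDS")) types == "CDS" else types == "gene"
  gr <- gr[keep]
  if (length(gr) == 0L)
    stop("annotation contains no CDS or gene features: ", gff)
  m <- mcols(gr)
  pick <- function(key) if (key %in% colnames(m)) as.character(m[[key]])
                        else rep(NA_character_, length(gr))
  gene_id <- pick("ID")
  for (key in c("locus_tag", "gene_id")) {
    miss <- is.na(gene_id)
    if (!any(miss)) break
    gene_id[miss] <- pick(key)[miss]
  }
  if (anyNA(gene_id))
    gene_id[is.na(gene_id)] <- sprintf("feature_%06d", which(is.na(gene_id)))
  product <- pick("product")
  mcols(gr) <- DataFrame(gene_id = gene_id, product = product)
  gr
}

#' Assign insertion sites to genes
#'
#' A site belongs to a gene when its position lies within the annotated
#' span, boundaries inclusive. A site inside two overlapping genes is
#' counted in both (and the overlap is reported) rather than dropped;
#' sites inside no gene are intergenic.
#'
#' @param x an [InsertionTable-class].
#' @param genes annotation from [readGeneAnnotation()].
#' @return list: \code{hits} data.frame (gene_id, reference, position,
#'   depth), \code{intergenic} data.frame of unassigned sites,
#'   \code{nSharedSites} number of sites assigned to more than one gene.
#' @export
assignSites <- function(x, genes) {
  stopifnot(is(x, "InsertionTable"))
  if (length(genes) == 0L) stop("empty gene annotation")
  s <- insertionSites(x)
  if (length(s) &&
      !any(unique(as.character(seqnames(s))) %in%
           unique(as.character(seqnames(genes)))))
    stop("reference names of sites and annotation do not overlap: sites use [",
         paste(unique(as.character(seqnames(s))), collapse = ", "),
         "], annotation uses [",
         paste(unique(as.character(seqnames(genes))), collapse = ", "), "]")
  ov <- findOverlaps(s, genes, ignore.strand = TRUE)
  hits <- data.frame(
    gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
    reference = as.character(seqnames(s))[S4Vectors::queryHits(ov)],
    position = start(s)[S4Vectors::queryHits(ov)],
    depth = mcols(s)$depth[S4Vectors::queryHits(ov)],
    stringsAsFactors = FALSE)
  assigned <- tabulate(S4Vectors::queryHits(ov), nbins = length(s))
  list(hits = hits,
       intergenic = as.data.frame(x)[assigned == 0L, , drop = FALSE],
       nSharedSites = sum(assigned > 1L))
}

#' Normalized Reads Mapped (NRM)
#'
#' \code{(gene reads / gene length in kb) / (pool total mapped reads / 1e6)}:
#' reads per kb of gene per million mapped reads, comparable between genes
#' and between sequencing runs of different depth.
#'
#' @param geneReads total reads mapped within the gene.
#' @param geneLenKb gene length in kb (> 0).
#' @param totalMappedReads pool total mapped reads (> 0).
#' @return numeric.
#' @examples
#' nrm(10, 2, 1e6)  # 5
#' @export
nrm <- function(geneReads, geneLenKb, totalMappedReads) {
  stopifnot(all(geneLenKb > 0))
  if (any(totalMappedReads <= 0)) stop("empty pool: total mapped reads is 0")
  (geneReads / geneLenKb) / (totalMappedReads / 1e6)
}

#' Normalized Insertions Mapped (NIM)
#'
#' \code{(gene unique insertions / gene length in kb) /
#' (pool total unique insertions / 1e6)}: insertion density per kb per
#' million unique insertions. A gene with NIM below 2 in a saturated
#' library is a candidate essential gene ([essentialCall()]).
#'
#' @param geneInsertions unique insertion positions within the gene.
#' @param geneLenKb gene length in kb (> 0).
#' @param totalInsertions pool total unique insertion positions (> 0).
#' @return numeric.
#' @examples
#' nim(3, 1.5, 3e5)  # 6.667
#' @export
nim <- function(geneInsertions, geneLenKb, totalInsertions) {
  stopifnot(all(geneLenKb > 0))
  if (any(totalInsertions <= 0)) stop("empty pool: total unique insertions is 0")
  (geneInsertions / geneLenKb) / (totalInsertions / 1e6)
}

#' Centile position of an insertion within a gene
#'
#' Percent position of the insertion along the coding sequence, 5' to 3':
#' \code{100 * (offset + 1) / length} where the offset is counted from the
#' annotated start on + strand genes and from the annotated end on - strand
#' genes. The first coding base of a 1 kb gene is centile 0.1, the last is
#' 100.
#'
#' @param position insertion position(s), 1-based.
#' @param start,end gene span, 1-based inclusive.
#' @param strand \code{"+"} or \code{"-"}.
#' @return numeric centile(s) in (0, 100].
#' @examples
#' insertionCentile(1, 1, 1000, "-")  # 100: last coding base
#' @export
insertionCentile <- function(position, start, end, strand) {
  len <- end - start + 1
  offset <- ifelse(strand == "-", end - position, position - start)
  100 * (offset + 1) / len
}

#' Per-gene insertion summary table
#'
#' The counts stage: joins an insertion table to gene annotation and
#' computes, per gene, the number of unique insertions, total read depth,
#' insertions per kb, the centile positions of the first and last insertion
#' within the coding sequence, NRM and NIM. Genes with no insertions stay in
#' the table with NIM 0 and absent centiles -- they are the candidate
#' essential genes. Normalization denominators are the pool-wide totals of
#' the (optionally coverage-filtered) table.
#'
#' @param x an [InsertionTable-class].
#' @param genes annotation from [readGeneAnnotation()].
#' @param minDepth coverage filter applied before summarizing (default 1 =
#'   off; 2 is recommended for real libraries to drop single-read
#'   positions).
#' @param nimThreshold NIM cutoff for the essentiality call (default 2).
#' @return data.frame with one row per gene: \code{gene_id}, \code{reference},
#'   \code{start}, \code{end}, \code{strand}, \code{length_kb},
#'   \code{unique_insertions}, \code{total_reads}, \code{insertions_per_kb},
#'   \code{first_insert_centile}, \code{last_insert_centile}, \code{NRM},
#'   \code{NIM}, \code{essential}, \code{product}. Attributes:
#'   \code{"centiles"} (data.frame gene_id/position/centile for every
#'   insertion in every gene, the histogram data), \code{"intergenic"}
#'   (unassigned sites), \code{"totals"} (denominators used).
#' @export
summarizeGenes <- function(x, genes, minDepth = 1L, nimThreshold = 2) {
  stopifnot(is(x, "InsertionTable"))
  if (minDepth > 1L) x <- coverageFilter(x, minDepth)
  totReads <- totalReads(x)
  totIns <- nSites(x)
  asg <- assignSites(x, genes)
  gdf <- data.frame(gene_id = genes$gene_id,
                    reference = as.character(seqnames(genes)),
                    start = start(genes), end = end(genes),
                    strand = as.character(strand(genes)),
                    stringsAsFactors = FALSE)
  gdf$length_kb <- (gdf$end - gdf$start + 1) / 1000
  h <- asg$hits
  gi <- match(h$gene_id, gdf$gene_id)
  h$centile <- insertionCentile(h$position, gdf$start[gi], gdf$end[gi],
                                gdf$strand[gi])
  ins <- tapply(h$position, factor(h$gene_id, levels = gdf$gene_id), length)
  rds <- tapply(h$depth, factor(h$gene_id, levels = gdf$gene_id), sum)
  cmin <- tapply(h$centile, factor(h$gene_id, levels = gdf$gene_id), min)
  cmax <- tapply(h$centile, factor(h$gene_id, levels = gdf$gene_id), max)
  gdf$unique_insertions <- as.integer(ifelse(is.na(ins), 0L, ins))
  gdf$total_reads <- as.integer(ifelse(is.na(rds), 0L, rds))
  gdf$insertions_per_kb <- gdf$unique_insertions / gdf$length_kb
  gdf$first_insert_centile <- as.numeric(cmin)
  gdf$last_insert_centile <- as.numeric(cmax)
  gdf$NRM <- nrm(gdf$total_reads, gdf$length_kb, totReads)
  gdf$NIM <- nim(gdf$unique_insertions, gdf$length_kb, totIns)
  gdf$essential <- essentialCall(gdf$NIM, nimThreshold)
  gdf$product <- genes$product
  attr(gdf, "centiles") <- h[, c("gene_id", "position", "centile")]
  attr(gdf, "intergenic") <- asg$intergenic
  attr(gdf, "totals") <- list(total_mapped_reads = totReads,
                              total_unique_insertions = totIns,
                              n_intergenic = nrow(asg$intergenic),
                              n_sites_in_overlapping_genes = asg$nSharedSites)
  gdf
}

#' Candidate-essential call from NIM
#'
#' A gene is called a candidate essential when its normalized insertion
#' density is strictly below the threshold (default NIM < 2): in a
#' saturated library, genes that cannot tolerate disruption accumulate far
#' fewer insertion mutants than expected for their length.
#'
#' @param nimValue NIM value(s).
#' @param threshold strict upper bound (default 2).
#' @return logical vector.
#' @examples
#' essentialCall(c(0, 1.99, 2))  # TRUE TRUE FALSE
#' @export
essentialCall <- function(nimValue, threshold = 2) {
  nimValue < threshold
}

#' Genome-wide insertion-density index profile
#'
#' For each unique insertion position the NIindex is the observed read
#' count minus the pool-wide expected count (total mapped reads / unique
#' positions). Positive runs mark insertion hot spots, negative runs cold
#' spots; the index sums to zero over the genome by construction. A running
#' mean over a window of consecutive sites is attached for plotting.
#'
#' @param x an [InsertionTable-class] with at least one site.
#' @param window running-mean window in sites (odd; default 201). Windows
#'   wider than the number of sites disable smoothing.
#' @return data.frame with columns \code{reference}, \code{position},
#'   \code{observed}, \code{expected}, \code{niindex}, \code{smoothed}.
#' @export
niindexProfile <- function(x, window = 201L) {
  stopifnot(is(x, "InsertionTable"), nSites(x) >= 1L)
  df <- as.data.frame(x)
  df <- df[order(df$reference, df$position), ]
  expected <- totalReads(x) / nSites(x)
  df$observed <- df$depth
  df$expected <- expected
  df$niindex <- df$observed - expected
  df$smoothed <- if (window >= 3L && nrow(df) >= window)
    as.numeric(stats::filter(df$niindex, rep(1 / window, window)))
  else NA_real_
  df[, c("reference", "position", "observed", "expected", "niindex",
         "smoothed")]
}

#' Write counts-stage outputs
#'
#' Writes the per-gene summary table, the all-insertions centile table
#' (histogram data) and the NIindex profile as tab-delimited text, plus a
#' run log.
#'
#' @param summary result of [summarizeGenes()].
#' @param profile result of [niindexProfile()], or NULL to skip.
#' @param prefix output path prefix; files are
#'   \code{<prefix>.summary.table}, \code{<prefix>.centiles.tsv},
#'   \code{<prefix>.niindex.tsv}, \code{<prefix>.counts.log}.
#' @return character vector of paths written, invisibly.
#' @export
writeGeneSummary <- function(summary, profile = NULL, prefix) {
  paths <- paste0(prefix, ".summary.table")
  writeTsv(summary, paths)
  cent <- attr(summary, "centiles")
  if (!is.null(cent)) {
    p <- paste0(prefix, ".centiles.tsv")
    writeTsv(cent, p)
    paths <- c(paths, p)
  }
  if (!is.null(profile)) {
    p <- paste0(prefix, ".niindex.tsv")
    writeTsv(profile, p)
    paths <- c(paths, p)
  }
  totals <- attr(summary, "totals")
  logPath <- paste0(prefix, ".counts.log")
  writeRunLog(c(list(stage = "counts", n_genes = nrow(summary)), totals),
              logPath)
  invisible(c(paths, logPath))
}
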