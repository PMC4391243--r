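#' Partition two pools' insertion sites
#'
#' Exact key-wise partition on (reference, position): sites seen only in
#' the input pool, only in the output pool, and shared by both.
#'
#' @param input,output [InsertionTable-class]s for the two pools.
#' @return list of three data.frames: \code{inputOnly} and
#'   \code{outputOnly} (reference, position, depth) and \code{shared}
#'   (reference, position, input_depth, output_depth).
#' @export
partitionSites <- function(input, output) {
  stopifnot(is(input, "InsertionTable"), is(output, "InsertionTable"))
  if (nSites(input) == 0L || nSites(output) == 0L)
    stop("empty pool: both insertion tables must contain sites")
  di <- as.data.frame(input)
  do <- as.data.frame(output)
  ki <- paste(di$reference, di$position)
  ko <- paste(do$reference, do$position)
  sharedIn <- ki %in% ko
  sharedOut <- ko %in% ki
  shared <- di[sharedIn, c("reference", "position")]
  shared$input_depth <- di$depth[sharedIn]
  shared$output_depth <- do$depth[match(ki[sharedIn], ko)]
  list(inputOnly = di[!sharedIn, , drop = FALSE],
       outputOnly = do[!sharedOut, , drop = FALSE],
       shared = shared)
}

#' Proportion ratio at a shared site
#'
#' The share of reads each pool maps at a location, as a ratio:
#' \code{(input depth / input total reads) / (output depth / output total
#' reads)}. Its natural logarithm over all shared sites is approximately
#' normal within an experiment, which is what the Z-score standardizes.
#'
#' @param inputDepth,outputDepth read depths at the shared site.
#' @param inputTotal,outputTotal pool total mapped reads.
#' @return numeric ratio (> 0 for shared sites).
#' @examples
#' proportionRatio(20, 10, 1000, 1000)  # 2
#' @export
proportionRatio <- function(inputDepth, outputDepth, inputTotal, outputTotal) {
  stopifnot(all(inputTotal > 0), all(outputTotal > 0))
  (inputDepth / inputTotal) / (outputDepth / outputTotal)
}

#' Significance flag from a Z-score
#'
#' Fixed two-sided standard-normal bands: \code{"***"} for |z| >= 3.291
#' (~p = 0.001), \code{"**"} for 3.291 > |z| >= 2.579 (~p = 0.01),
#' \code{"*"} for 2.579 > |z| >= 1.960 (~p = 0.05), otherwise "".
#' The 2.579 boundary is used as printed in the scheme this implements;
#' the conventional value for p = 0.01 is 2.576.
#'
#' @param z numeric Z-score vector.
#' @return character vector of flags.
#' @examples
#' zscoreFlag(c(3.291, -2.0, 1.9599))  # "***" "*" ""
#' @export
zscoreFlag <- function(z) {
  a <- abs(z)
  ifelse(a >= 3.291, "***",
         ifelse(a >= 2.579, "**",
                ifelse(a >= 1.960, "*", "")))
}

#' Compare an input and an output mutant pool
#'
#' The compare stage: partitions the two pools' sites, and for every shared
#' site computes the log proportion ratio, standardizes it against the mean
#' and sample standard deviation of the whole shared population
#' (\code{Zscore = (log(proportion ratio) - shared mean) / shared sd}), and
#' attaches the significance flag. By construction the Z-score population
#' has mean 0 and sample sd 1. Sites depleted from the output pool
#' (condition-sensitive mutants) get large positive Z-scores, enriched
#' sites large negative ones. If every shared log-ratio is identical
#' (sd = 0) the Z-scores are set to 0 with a warning.
#'
#' @param input,output [InsertionTable-class]s for the two pools.
#' @param genes optional annotation ([readGeneAnnotation()]); when given,
#'   each row is joined to the gene(s) spanning its position, or
#'   \code{"intergenic"}.
#' @return list: \code{shared} data.frame (reference, position,
#'   input_depth, output_depth, input_share, output_share,
#'   proportion_ratio, log_ratio, zscore, flag, and gene_id when annotated),
#'   \code{inputOnly}, \code{outputOnly} (same depth/annotation columns, no
#'   Z-score -- it is undefined off the shared population), and
#'   \code{stats} (shared_mean, shared_sd, n_shared, pool totals).
#' @export
comparePools <- function(input, output, genes = NULL) {
  part <- partitionSites(input, output)
  ti <- totalReads(input)
  to <- totalReads(output)
  sh <- part$shared
  stats <- list(n_shared = nrow(sh), shared_mean = NA_real_,
                shared_sd = NA_real_, input_total_reads = ti,
                output_total_reads = to)
  if (nrow(sh) == 0L) {
    warning("no shared positions between pools; Z-score stage skipped")
  } else {
    sh$input_share <- sh$input_depth / ti
    sh$output_share <- sh$output_depth / to
    sh$proportion_ratio <- proportionRatio(sh$input_depth, sh$output_depth,
                                           ti, to)
    sh$log_ratio <- log(sh$proportion_ratio)
    if (nrow(sh) >= 2L) {
      stats$shared_mean <- mean(sh$log_ratio)
      stats$shared_sd <- stats::sd(sh$log_ratio)
      if (stats$shared_sd > 0) {
        sh$zscore <- (sh$log_ratio - stats$shared_mean) / stats$shared_sd
      } else {
        warning("all shared log-ratios identical (sd = 0); Z-scores set to 0")
        sh$zscore <- 0
      }
    } else {
      stats$shared_mean <- sh$log_ratio
      stats$shared_sd <- NA_real_
      sh$zscore <- 0
      warning("fewer than 2 shared positions; Z-scores set to 0")
    }
    sh$flag <- zscoreFlag(sh$zscore)
  }
  if (!is.null(genes)) {
    sh <- .joinGenes(sh, genes)
    part$inputOnly <- .joinGenes(part$inputOnly, genes)
    part$outputOnly <- .joinGenes(part$outputOnly, genes)
  }
  list(shared = sh, inputOnly = part$inputOnly, outputOnly = part$outputOnly,
       stats = stats)
}

# Annotate comparison rows with the gene(s) spanning each position;
# a position in several overlapping genes lists them comma-separated.
.joinGenes <- function(df, genes) {
  if (nrow(df) == 0L) {
    df$gene_id <- character(0)
    return(df)
  }
  gr <- GRanges(df$reference, IRanges(df$position, width = 1L))
  ov <- findOverlaps(gr, genes, ignore.strand = TRUE)
  ids <- tapply(genes$gene_id[S4Vectors::subjectHits(ov)],
                factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(df))),
                paste, collapse = ",")
  df$gene_id <- as.character(ifelse(is.na(ids), "intergenic", ids))
  df
}

#' Write compare-stage outputs
#'
#' Writes \code{shared.tsv}, \code{input_only.tsv}, \code{output_only.tsv}
#' and a run log carrying the shared-population statistics.
#'
#' @param cmp result of [comparePools()].
#' @param dir output directory (created if needed).
#' @return character vector of paths, invisibly.
#' @export
writeComparison <- function(cmp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "shared.tsv"),
             file.path(dir, "input_only.tsv"),
             file.path(dir, "output_only.tsv"),
             file.path(dir, "compare.log"))
  writeTsv(cmp$shared, paths[1])
  writeTsv(cmp$inputOnly, paths[2])
  writeTsv(cmp$outputOnly, paths[3])
  writeRunLog(c(list(stage = "compare"), cmp$stats), paths[4])
  invisible(paths)
}
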