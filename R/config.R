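#' Parse a commands file
#'
#' Run configuration that would invite typos on a command line -- the
#' transposon terminal motifs and the aligner invocation -- lives in a
#' small \code{key = value} file instead. Recognised keys: \code{motif1}
#' (required for read preparation), \code{motif2} (optional second
#' terminus), \code{aligner}, \code{aligner_options}. \code{#} comments and
#' blank lines are ignored; unknown keys and non-DNA motifs are errors.
#'
#' @param path path to the commands file.
#' @return list: \code{motifs} (list of [MotifSpec-class]), \code{aligner}
#'   (or NULL), \code{alignerOptions} (character vector or NULL).
#' @examples
#' f <- tempfile(); writeLines(c("# termini", "motif1 = TCAG"), f)
#' parseCommandsFile(f)$motifs[[1]]
#' @export
parseCommandsFile <- function(path) {
  if (!file.exists(path)) stop("commands file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  known <- c("motif1", "motif2", "aligner", "aligner_options")
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse commands-file line: '", ln, "' (expected key = value)")
    key <- m[2]; val <- trimws(m[3])
    if (!key %in% known)
      stop("unknown commands-file key '", key, "' (known: ",
           paste(known, collapse = ", "), ")")
    kv[[key]] <- val
  }
  if (is.null(kv$motif1)) stop("commands file must define motif1")
  motifs <- list(motifSpec(kv$motif1, label = "motif1"))
  if (!is.null(kv$motif2))
    motifs <- c(motifs, list(motifSpec(kv$motif2, label = "motif2")))
  list(motifs = motifs,
       aligner = kv$aligner,
       alignerOptions = if (!is.null(kv$aligner_options))
         strsplit(kv$aligner_options, "\\s+")[[1]] else NULL)
}

#' Parse an alignment-score token
#'
#' Accepts plain integers and \code{neg<N>} tokens for negative scores
#' (bowtie2's score scale is negative; shells mangle leading minus signs,
#' so \code{neg10} means -10).
#'
#' @param token character scalar, e.g. \code{"50"}, \code{"-10"},
#'   \code{"neg10"}.
#' @return integer score.
#' @examples
#' parseAlignScore("neg30")  # -30
#' @export
parseAlignScore <- function(token) {
  token <- trimws(as.character(token))
  if (grepl("^neg[0-9]+$", token))
    return(-as.integer(sub("^neg", "", token)))
  if (grepl("^-?[0-9]+$", token))
    return(as.integer(token))
  stop("cannot parse alignment score '", token,
       "' (use an integer or negN for negative values)")
}

#' Run one pipeline mode
#'
#' Programmatic equivalent of the command-line modes; each call executes
#' one stage's module chain and writes its artifacts plus a run log under
#' \code{outDir}. Modes and their required \code{args} entries:
#' \describe{
#'   \item{mapping}{\code{fastq1} (optionally \code{fastq2}),
#'     \code{commandsFile} or \code{motifs}; optional \code{minLen},
#'     \code{maxLen}; optional \code{reference} to also run the aligner.}
#'   \item{process_sam}{\code{sam}; optional \code{mis} (count or
#'     fraction), \code{a} (score, \code{neg}-tokens accepted), \code{d}
#'     (collapse distance), \code{cov} (min depth).}
#'   \item{counts}{\code{positions} (tsv path or InsertionTable),
#'     \code{gff}; optional \code{cov}, \code{nimThreshold}.}
#'   \item{compare}{\code{inputPositions}, \code{outputPositions}; optional
#'     \code{gff}.}
#'   \item{simulate}{optional simulator parameters (see
#'     [simulateLibrary()]); \code{seed} required.}
#'   \item{sweep}{\code{sam}, \code{mismatchGrid}, \code{scoreGrid};
#'     optional \code{d}.}
#' }
#' Defaults mirror the recommended practice: fragment retention 20-50 bp,
#' mismatches 0, alignment score 50, collapse off, coverage filter off.
#'
#' @param mode one of \code{"mapping"}, \code{"process_sam"},
#'   \code{"counts"}, \code{"compare"}, \code{"simulate"}, \code{"sweep"}.
#' @param args named list of mode arguments.
#' @param outDir output directory.
#' @return invisibly, a mode-specific result list (paths and summaries).
#' @export
runMode <- function(mode, args = list(), outDir = ".") {
  mode <- match.arg(mode, c("mapping", "process_sam", "counts", "compare",
                            "simulate", "sweep"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  getArg <- function(name, default = NULL)
    if (!is.null(args[[name]])) args[[name]] else default
  switch(mode,
    mapping = {
      motifs <- if (!is.null(args$commandsFile))
        parseCommandsFile(args$commandsFile)$motifs
      else args$motifs
      if (is.null(motifs)) stop("mapping mode needs motifs or a commandsFile")
      outFastq <- file.path(outDir, "fragments.fastq")
      res <- prepReads(args$fastq1, getArg("fastq2"), motifs,
                       minLen = getArg("minLen", 20L),
                       maxLen = getArg("maxLen", 50L),
                       outFastq = outFastq,
                       qcPrefix = file.path(outDir, "mapping"))
      if (!is.null(args$reference)) {
        cf <- if (!is.null(args$commandsFile))
          parseCommandsFile(args$commandsFile) else list()
        sam <- file.path(outDir, "aligned.sam")
        runAligner(if (!is.null(cf$aligner)) cf$aligner else
                     getArg("aligner", "bwa"),
                   args$reference, outFastq, sam,
                   options = cf$alignerOptions,
                   allowNonstandard = isTRUE(args$allowNonstandard))
        res$sam <- sam
      }
      invisible(res)
    },
    process_sam = {
      tab <- callInsertions(args$sam,
                            maxMismatch = getArg("mis", 0),
                            minAlignScore = parseAlignScore(getArg("a", "50")),
                            collapseDistance = getArg("d", 0L),
                            minDepth = getArg("cov", 1L),
                            logPath = file.path(outDir, "process.log"))
      writePositions(tab, file.path(outDir, "positions.tsv"))
      invisible(list(positions = file.path(outDir, "positions.tsv"),
                     table = tab, counts = attr(tab, "counts")))
    },
    counts = {
      tab <- if (is(args$positions, "InsertionTable")) args$positions
             else readPositions(args$positions)
      genes <- readGeneAnnotation(args$gff)
      minDepth <- getArg("cov", 1L)
      summary <- summarizeGenes(tab, genes, minDepth = minDepth,
                                nimThreshold = getArg("nimThreshold", 2))
      filtered <- if (minDepth > 1L) coverageFilter(tab, minDepth) else tab
      profile <- niindexProfile(filtered)
      writeGeneSummary(summary, profile, file.path(outDir, "counts"))
      invisible(list(summary = summary, profile = profile))
    },
    compare = {
      ti <- if (is(args$inputPositions, "InsertionTable")) args$inputPositions
            else readPositions(args$inputPositions)
      to <- if (is(args$outputPositions, "InsertionTable")) args$outputPositions
            else readPositions(args$outputPositions)
      genes <- if (!is.null(args$gff)) readGeneAnnotation(args$gff) else NULL
      cmp <- comparePools(ti, to, genes)
      writeComparison(cmp, outDir)
      invisible(cmp)
    },
    simulate = {
      simArgs <- args[intersect(names(args),
        names(formals(simulateLibrary)))]
      invisible(do.call(simulateLibrary, c(list(outDir = outDir), simArgs)))
    },
    sweep = {
      res <- parameterSweep(args$sam, args$mismatchGrid, args$scoreGrid,
                            collapseDistance = getArg("d", 0L))
      writeTsv(res, file.path(outDir, "sweep.tsv"))
      invisible(res)
    })
}
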