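#' Reverse complement of a DNA string
#'
#' @param x single DNA string (A/C/G/T/N).
#' @return the reverse complement, uppercase.
#' @examples
#' revComp("TCAG")  # "CTGA"
#' @export
#' @importFrom Biostrings reverseComplement DNAString
revComp <- function(x) {
  as.character(reverseComplement(DNAString(toupper(x))))
}

# Write a named list of counts/parameters as a plain-text run log.
# Every pipeline stage records its full parameter set and conservation
# counts so runs can be audited and reproduced.
writeRunLog <- function(log, path) {
  stopifnot(is.list(log))
  lines <- c(sprintf("# tnseqr %s run log", as.character(utils::packageVersion("tnseqr"))),
             sprintf("# %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             vapply(names(log), function(k) {
               v <- log[[k]]
               sprintf("%s\t%s", k, paste(format(v, scientific = FALSE), collapse = ","))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# Read a run log back into a named list (numbers re-typed where possible).
readRunLog <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- lapply(parts, function(p) {
    v <- strsplit(p[2], ",", fixed = TRUE)[[1]]
    n <- suppressWarnings(as.numeric(v))
    if (!anyNA(n)) n else v
  })
  names(out) <- vapply(parts, `[`, character(1), 1L)
  out
}

# TRUE if the file starts with the gzip magic bytes.
isGzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

# Open a FASTQ regardless of extension: gzip is detected by magic bytes,
# not file name, and routed through a .gz-suffixed link for the reader.
openFastq <- function(path) {
  if (isGzip(path) && !grepl("\\.gz$", path)) {
    tmp <- paste0(tempfile("fastq_"), ".fastq.gz")
    file.copy(path, tmp)
    path <- tmp
  }
  ShortRead::readFastq(path)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
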