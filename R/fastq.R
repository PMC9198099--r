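#' Read amplicon reads from FASTQ
#'
#' Wrapper over \code{\link[Biostrings]{readDNAStringSet}} (gzip is handled
#' transparently) that first validates the file's 4-line record structure
#' and per-record quality widths — the underlying parser silently pads a
#' quality string that is shorter than its sequence — and reports which
#' record is malformed.
#'
#' @param path FASTQ file, optionally gzipped.
#' @return A \code{DNAStringSet} with per-record qualities in
#'   \code{mcols(x)$qualities}.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  .fastq_validate(path)
  Biostrings::readDNAStringSet(path, format = "fastq",
                               with.qualities = TRUE)
}

# structural pass: 4-line records, '+' separator, |qual| == |seq|
.fastq_validate <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- tryCatch(readLines(con, warn = FALSE), finally = close(con))
  n <- length(lines)
  rec <- 0L
  i <- 1L
  while (i <= n) {
    rec <- rec + 1L
    if (!startsWith(lines[i], "@"))
      stop("malformed FASTQ at line ", i, " (record ", rec,
           "): expected '@' header", call. = FALSE)
    id <- sub("\\s.*$", "", substring(lines[i], 2L))
    if (i + 3L > n)
      stop("truncated FASTQ record '", id, "' (record ", rec,
           ") starting at line ", i, call. = FALSE)
    if (!startsWith(lines[i + 2L], "+"))
      stop("malformed FASTQ at line ", i + 2L, " (record ", rec,
           "): expected '+' separator", call. = FALSE)
    if (nchar(lines[i + 3L]) != nchar(lines[i + 1L]))
      stop("FASTQ record '", id, "' (record ", rec, "): quality length ",
           nchar(lines[i + 3L]), " != sequence length ",
           nchar(lines[i + 1L]), call. = FALSE)
    i <- i + 4L
  }
  invisible(TRUE)
}

#' Write reads to FASTQ
#'
#' @param reads \code{DNAStringSet} (qualities taken from
#'   \code{mcols()$qualities} when present, otherwise constant Q40).
#' @param path Output path; \code{.gz} suffix triggers compression.
#' @export
writeFastq <- function(reads, path) {
  q <- S4Vectors::mcols(reads)$qualities
  if (is.null(q))
    q <- Biostrings::BStringSet(strrep("I", BiocGenerics::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
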