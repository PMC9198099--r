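#' Reference sequence with optional coding annotation
#'
#' \code{CbeReference} couples a DNA sequence with an optional set of coding
#' (CDS) intervals used for premature-STOP design and bystander-consequence
#' annotation. CDS intervals live on the forward strand, are 1-based closed,
#' non-overlapping, and carry a frame offset (0, 1, 2) giving the position
#' within a codon of the interval's first base.
#'
#' @slot id Single reference/contig identifier.
#' @slot seq A \link[Biostrings]{DNAString} over A/C/G/T/N.
#' @slot cds A data.frame with columns \code{start}, \code{end}, \code{frame}
#'   (possibly 0 rows).
#'
#' @export
setClass("CbeReference",
  representation(id = "character", seq = "DNAString", cds = "data.frame"))

setValidity("CbeReference", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "id must be a single non-empty string")
  if (length(object@seq) == 0L)
    msg <- c(msg, "seq must be non-empty")
  letters <- uniqueLetters(object@seq)
  if (length(setdiff(letters, c(DNA_BASES, "N"))))
    msg <- c(msg, "seq must only contain A/C/G/T/N")
  cds <- object@cds
  if (nrow(cds)) {
    if (!all(c("start", "end", "frame") %in% names(cds)))
      msg <- c(msg, "cds needs columns start, end, frame")
    else {
      if (any(cds$start < 1L) || any(cds$end > length(object@seq)) ||
          any(cds$start > cds$end))
        msg <- c(msg, "cds intervals out of bounds")
      if (!all(cds$frame %in% 0:2))
        msg <- c(msg, "cds frame must be 0, 1 or 2")
      o <- order(cds$start)
      if (nrow(cds) > 1L && any(cds$start[o][-1L] <= cds$end[o][-nrow(cds)]))
        msg <- c(msg, "cds intervals must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CbeReference
#'
#' @param seq DNA sequence as a character string or \code{DNAString}.
#' @param id Reference identifier.
#' @param cds Optional CDS table: data.frame with columns \code{start},
#'   \code{end} (1-based closed, forward strand) and \code{frame}.
#' @return A \code{CbeReference}.
#' @examples
#' ref <- CbeReference("ACGTACGTACGTACGTACGTACGTA", id = "toy")
#' @export
CbeReference <- function(seq, id = "ref", cds = NULL) {
  if (is.character(seq)) {
    .check_dna(toupper(seq), "reference sequence")
    seq <- Biostrings::DNAString(toupper(seq))
  }
  if (is.null(cds))
    cds <- data.frame(start = integer(0), end = integer(0), frame = integer(0))
  cds <- as.data.frame(cds)[, c("start", "end", "frame")]
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  cds$frame <- as.integer(cds$frame)
  new("CbeReference", id = as.character(id), seq = seq, cds = cds)
}

#' @describeIn CbeReference sequence accessor (returns a \code{DNAString}).
#' @param x,object A \code{CbeReference}.
#' @export
refSeq <- function(x) x@seq

#' @describeIn CbeReference identifier accessor.
#' @export
refId <- function(x) x@id

#' @describeIn CbeReference CDS table accessor.
#' @export
refCds <- function(x) x@cds

setMethod("show", "CbeReference", function(object) {
  cat("CbeReference '", object@id, "': ", length(object@seq), " bp, ",
      nrow(object@cds), " CDS interval(s)\n", sep = "")
})

#' Read references from FASTA, and CDS annotations from TSV
#'
#' \code{readReferenceFasta} loads a (multi-record) FASTA into a list of
#' \code{CbeReference}; \code{readCdsTable} reads the 4-column CDS dialect
#' (\code{contig}, \code{start}, \code{end}, \code{frame}; 1-based closed)
#' and attaches intervals to the matching references.
#'
#' @param path FASTA file (gzip supported by \pkg{Biostrings}).
#' @param cds_path Optional CDS TSV to attach.
#' @return Named list of \code{CbeReference}.
#' @export
readReferenceFasta <- function(path, cds_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  cds_all <- if (is.null(cds_path)) NULL else readCdsTable(cds_path)
  refs <- lapply(seq_along(set), function(i) {
    cds <- if (is.null(cds_all)) NULL
           else cds_all[cds_all$contig == ids[i], c("start", "end", "frame")]
    CbeReference(as.character(set[[i]]), id = ids[i], cds = cds)
  })
  names(refs) <- ids
  refs
}

#' @rdname readReferenceFasta
#' @export
readCdsTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("contig", "start", "end", "frame")
  if (!all(need %in% names(tab)))
    stop("CDS table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' Write references to FASTA
#' @param refs A \code{CbeReference} or list of them.
#' @param path Output file.
#' @export
writeReferenceFasta <- function(refs, path) {
  if (is(refs, "CbeReference")) refs <- list(refs)
  set <- Biostrings::DNAStringSet(lapply(refs, refSeq))
  names(set) <- vapply(refs, refId, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
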