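# shared low-level helpers (character-vector sequence handling)

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> set of concrete bases
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.revcomp <- function(x) {
  # character-string reverse complement; vectorised
  vapply(x, function(s) {
    ch <- rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.check_dna <- function(seq, what = "sequence", allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " must be a non-empty character string", call. = FALSE)
  allowed <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", allowed), "", seq)
  if (nzchar(bad))
    stop(what, " contains non-IUPAC characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","), call. = FALSE)
  invisible(seq)
}

.assert_scalar_int <- function(x, what, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x))
    stop(what, " must be a single integer", call. = FALSE)
  if (!is.null(min) && x < min)
    stop(what, " must be >= ", min, call. = FALSE)
  as.integer(x)
}

# translate one codon with the standard genetic code
.translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
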