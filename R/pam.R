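#' PAM pattern utilities
#'
#' A PAM pattern is a 3-character IUPAC string (\code{"NGG"}, \code{"NRN"},
#' \code{"NNN"}, ...). Matching is positionwise set membership, with one
#' deliberate exception: an \code{N} in the \emph{reference} only matches a
#' pattern position whose code is itself \code{N}. This keeps ambiguous
#' reference stretches from spawning guides against informative PAM codes.
#'
#' @param pattern A 3-character IUPAC string.
#' @return \code{validatePamPattern} returns the pattern (uppercased),
#'   invisibly erroring on invalid codes.
#' @examples
#' validatePamPattern("NRN")
#' pamMatches("AGG", "NGG")
#' pamMatches("ANG", "NNN")  # FALSE: reference N vs pattern N-G-G position
#' @export
validatePamPattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L)
    stop("PAM pattern must be a single character string", call. = FALSE)
  pattern <- toupper(pattern)
  if (nchar(pattern) != 3L)
    stop("PAM pattern must have exactly 3 characters, got '", pattern, "'",
         call. = FALSE)
  ch <- strsplit(pattern, "")[[1]]
  bad <- setdiff(ch, names(IUPAC_SETS))
  if (length(bad))
    stop("invalid IUPAC code(s) in PAM pattern: ",
         paste(bad, collapse = ","), call. = FALSE)
  pattern
}

#' @rdname validatePamPattern
#' @param pam Observed 3-mer(s) from the reference (may contain N).
#' @return \code{pamMatches} returns a logical vector.
#' @export
pamMatches <- function(pam, pattern) {
  pattern <- validatePamPattern(pattern)
  pch <- strsplit(pattern, "")[[1]]
  vapply(pam, function(p) {
    if (nchar(p) != 3L) return(FALSE)
    och <- strsplit(toupper(p), "")[[1]]
    all(vapply(seq_len(3L), function(i) {
      if (och[i] == "N") return(pch[i] == "N")
      och[i] %in% IUPAC_SETS[[pch[i]]]
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Resolve the PAM class label of an observed PAM
#'
#' Observed PAMs are binned by their informative (second) position into the
#' classes used when ranking PAM-flexible guides: \code{NGG} (canonical),
#' then \code{NAN}/\code{NGN} (purine, NRN tier) and \code{NCN}/\code{NTN}
#' (pyrimidine, NYN tier).
#'
#' @param pam Observed 3-mer(s).
#' @return Character vector of class labels (\code{NGG}, \code{NAN},
#'   \code{NGN}, \code{NCN}, \code{NTN}, or \code{NNN} for ambiguous).
#' @export
pamClass <- function(pam) {
  vapply(toupper(pam), function(p) {
    ch <- strsplit(p, "")[[1]]
    if (length(ch) != 3L || !ch[2] %in% DNA_BASES) return("NNN")
    if (ch[2] == "G" && ch[3] == "G") "NGG" else paste0("N", ch[2], "N")
  }, character(1), USE.NAMES = FALSE)
}

# tier used by rankGuides: NGG beats other NRN beats NYN
.pam_tier <- function(class) {
  ifelse(class == "NGG", 1L,
         ifelse(class %in% c("NAN", "NGN"), 2L,
                ifelse(class %in% c("NCN", "NTN"), 3L, 4L)))
}
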