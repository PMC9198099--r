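#' Scan a genome for mismatch off-target sites
#'
#' Exhaustive both-strand scan for 20-mers within a Hamming distance of the
#' protospacer (substitutions only, no bulges) whose adjacent 3-mer matches
#' the PAM pattern. The candidate search uses
#' \code{\link[Biostrings]{matchPattern}} with \code{max.mismatch}; PAM
#' filtering follows the same reference-N rule as guide calling. The
#' on-target site itself is reported with 0 mismatches when present.
#'
#' @param genome A \code{\link{CbeReference}}, \code{DNAString}, or
#'   character sequence.
#' @param guide A 20-nt protospacer string, or a length-1 guide
#'   \code{GRanges}.
#' @param max_mm Maximum number of protospacer mismatches (>= 0).
#' @param pam IUPAC PAM pattern the off-target PAM must match.
#' @return \code{GRanges} of protospacer intervals sorted by mismatch count
#'   then coordinate, with metadata columns \code{mismatches}, \code{pam},
#'   \code{site} (observed protospacer-strand 20-mer).
#' @examples
#' ref <- makeReference(2000, seed = 5)
#' g <- scanProtospacers(ref, "NRN")[1]
#' scanOfftargets(ref, g, max_mm = 0, pam = "NRN")
#' @export
scanOfftargets <- function(genome, guide, max_mm = 3L, pam = "NRN") {
  max_mm <- .assert_scalar_int(max_mm, "max_mm", 0L)
  if (is(guide, "GRanges")) {
    if (length(guide) != 1L)
      stop("guide must be a single candidate", call. = FALSE)
    guide <- S4Vectors::mcols(guide)$protospacer
  }
  .check_dna(guide, "protospacer", allow_n = FALSE)
  if (nchar(guide) != 20L)
    stop("protospacer must be 20 nt", call. = FALSE)
  if (is.character(genome)) genome <- CbeReference(genome, id = "genome")
  contig <- if (is(genome, "CbeReference")) refId(genome) else "genome"
  subject <- if (is(genome, "CbeReference")) refSeq(genome)
             else Biostrings::DNAString(genome)
  s <- as.character(subject)
  n <- nchar(s)
  proto <- Biostrings::DNAString(guide)

  collect <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject, max.mismatch = max_mm,
                                  with.indels = FALSE)
    st <- BiocGenerics::start(m)
    if (strand == "+") st <- st[st + 22L <= n] else st <- st[st >= 4L]
    if (!length(st)) return(NULL)
    mm <- Biostrings::neditStartingAt(pattern, subject, starting.at = st,
                                      with.indels = FALSE)
    pam_obs <- if (strand == "+")
      substring(s, st + 20L, st + 22L)
    else .revcomp(substring(s, st - 3L, st - 1L))
    keep <- pamMatches(pam_obs, pam)
    if (!any(keep)) return(NULL)
    site <- substring(s, st, st + 19L)
    if (strand == "-") site <- .revcomp(site)
    data.frame(start = st[keep], strand = strand, mismatches = mm[keep],
               pam = pam_obs[keep], site = site[keep],
               stringsAsFactors = FALSE)
  }

  hits <- rbind(collect(proto, "+"),
                collect(Biostrings::reverseComplement(proto), "-"))
  if (is.null(hits) || !nrow(hits)) {
    gr <- GenomicRanges::GRanges(seqnames = character(0),
                                 ranges = IRanges::IRanges())
    S4Vectors::mcols(gr)$mismatches <- integer(0)
    S4Vectors::mcols(gr)$pam <- character(0)
    S4Vectors::mcols(gr)$site <- character(0)
    return(gr)
  }
  hits <- hits[order(hits$mismatches, hits$start, hits$strand), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = rep(contig, nrow(hits)),
    ranges = IRanges::IRanges(hits$start, width = rep(20L, nrow(hits))),
    strand = hits$strand)
  S4Vectors::mcols(gr)$mismatches <- as.integer(hits$mismatches)
  S4Vectors::mcols(gr)$pam <- hits$pam
  S4Vectors::mcols(gr)$site <- hits$site
  gr
}
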