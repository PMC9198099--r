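#' Enumerate candidate CBE protospacers under an IUPAC PAM pattern
#'
#' Scans both strands of a reference for every 20-mer whose immediately
#' 3'-adjacent 3-mer matches the PAM pattern, and annotates the distances
#' from the PAM of every C in the editing window on the protospacer strand.
#' Candidates whose window holds no C are retained but flagged
#' (\code{has_window_c = FALSE}); protospacers containing N are never
#' called (an N in the reference matches no protospacer base).
#'
#' Distance convention: the PAM-adjacent protospacer base is at distance 1,
#' so the canonical window (13, 19) covers protospacer positions 2--8 from
#' the 5' end of the 20-mer.
#'
#' @param ref A \code{\link{CbeReference}} (or character sequence).
#' @param pam A 3-character IUPAC PAM pattern, e.g. \code{"NGG"},
#'   \code{"NRN"}, \code{"NNN"}.
#' @param window Editing window \code{c(min, max)} in distance-from-PAM
#'   coordinates; \code{c(13, 19)} canonical, \code{c(12, 19)} extended.
#' @return A \code{GRanges} over the protospacer intervals (1-based closed,
#'   forward strand coordinates; \code{strand} is the guide strand) with
#'   metadata columns \code{protospacer}, \code{pam}, \code{pam_class},
#'   \code{window_c_dists} (\code{IntegerList}, ascending),
#'   \code{n_window_c}, \code{has_window_c}.
#' @examples
#' ref <- CbeReference(paste0(strrep("A", 20), "TGGACT"), id = "toy")
#' scanProtospacers(ref, "NGG")
#' @export
scanProtospacers <- function(ref, pam = "NGG", window = c(13L, 19L)) {
  if (is.character(ref)) ref <- CbeReference(ref)
  pam <- validatePamPattern(pam)
  window <- as.integer(window)
  if (length(window) != 2L || window[1] < 1L || window[1] > window[2] ||
      window[2] > 20L)
    stop("window must be c(min, max) with 1 <= min <= max <= 20",
         call. = FALSE)
  s <- as.character(refSeq(ref))
  n <- nchar(s)
  if (n < 23L) return(.guide_granges(ref, integer(0), character(0),
                                     character(0), character(0), list(),
                                     window))
  ch <- strsplit(s, "")[[1]]
  pch <- strsplit(pam, "")[[1]]
  isN <- ch == "N"
  cumN <- cumsum(isN)
  # any N inside [i, i+19]?
  protoN <- function(i) (cumN[i + 19L] - c(0L, cumN)[i]) > 0L

  # positionwise PAM-letter match with the reference-N rule
  base_ok <- function(pos, code) {
    if (code == "N") return(ch[pos] %in% c(DNA_BASES, "N"))
    ch[pos] %in% IUPAC_SETS[[code]]
  }
  comp <- chartr("ACGTN", "TGCAN", ch)

  dists <- seq(window[1], window[2])

  # forward: protospacer [i, i+19], PAM [i+20, i+22]
  i_f <- seq_len(max(0L, n - 22L))
  if (length(i_f)) {
    ok <- base_ok(i_f + 20L, pch[1]) & base_ok(i_f + 21L, pch[2]) &
      base_ok(i_f + 22L, pch[3]) & !protoN(i_f)
    i_f <- i_f[ok]
  }
  cdists_f <- lapply(i_f, function(i) dists[ch[i + 20L - dists] == "C"])

  # reverse: protospacer [i, i+19] (revcomp), PAM forward [i-3, i-1]
  i_r <- if (n >= 23L) seq(4L, n - 19L) else integer(0)
  if (length(i_r)) {
    # pattern position 1 pairs with forward i-1 complemented, etc.
    rc_ok <- function(pos, code) {
      if (code == "N") return(comp[pos] %in% c(DNA_BASES, "N"))
      comp[pos] %in% IUPAC_SETS[[code]]
    }
    ok <- rc_ok(i_r - 1L, pch[1]) & rc_ok(i_r - 2L, pch[2]) &
      rc_ok(i_r - 3L, pch[3]) & !protoN(i_r)
    i_r <- i_r[ok]
  }
  # C on the protospacer (minus) strand at distance d = G on forward at i+d-1
  cdists_r <- lapply(i_r, function(i) dists[ch[i + dists - 1L] == "G"])

  proto_f <- vapply(i_f, function(i) substr(s, i, i + 19L), character(1))
  pam_f <- vapply(i_f, function(i) substr(s, i + 20L, i + 22L), character(1))
  proto_r <- .revcomp(vapply(i_r, function(i) substr(s, i, i + 19L),
                             character(1)))
  pam_r <- .revcomp(vapply(i_r, function(i) substr(s, i - 3L, i - 1L),
                           character(1)))

  starts <- c(i_f, i_r)
  strands <- c(rep("+", length(i_f)), rep("-", length(i_r)))
  .guide_granges(ref, starts, strands, c(proto_f, proto_r),
                 c(pam_f, pam_r), c(cdists_f, cdists_r), window)
}

.guide_granges <- function(ref, starts, strands, proto, pam, cdists, window) {
  k <- length(starts)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(refId(ref), k),
    ranges = IRanges::IRanges(start = as.integer(starts),
                              width = rep(20L, k)),
    strand = strands)
  S4Vectors::mcols(gr)$protospacer <- proto
  S4Vectors::mcols(gr)$pam <- pam
  S4Vectors::mcols(gr)$pam_class <- pamClass(pam)
  S4Vectors::mcols(gr)$window_c_dists <- IRanges::IntegerList(cdists)
  S4Vectors::mcols(gr)$n_window_c <- lengths(cdists)
  S4Vectors::mcols(gr)$has_window_c <- lengths(cdists) > 0L
  S4Vectors::metadata(gr)$window <- window
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  names(gr) <- if (length(gr)) sprintf("%s_g%03d", refId(ref), seq_along(gr))
               else NULL
  gr
}

#' Rank guide candidates
#'
#' Stable ordering policy for PAM-flexible CBE guides, reflecting the
#' observed efficacy hierarchy of the editor: canonical NGG first, then the
#' other NRN classes, then NYN; within a tier, guides whose target Cs sit
#' closest to the window midpoint come first, then guides with fewer
#' bystander Cs; remaining ties break by genomic coordinate (then strand,
#' \code{+} first).
#'
#' @param cands Guide \code{GRanges} from \code{\link{scanProtospacers}} or
#'   \code{\link{designStopGuides}}.
#' @param targets Optional \code{IntegerList}/list of per-guide target
#'   distances used for the centrality term; defaults to
#'   \code{required_c_dists} when present, else all window Cs.
#' @return The reordered \code{GRanges}.
#' @export
rankGuides <- function(cands, targets = NULL) {
  if (!length(cands)) return(cands)
  mc <- S4Vectors::mcols(cands)
  window <- S4Vectors::metadata(cands)$window
  if (is.null(window)) window <- c(13L, 19L)
  mid <- mean(window)
  if (is.null(targets))
    targets <- if ("required_c_dists" %in% names(mc)) mc$required_c_dists
               else mc$window_c_dists
  targets <- as.list(targets)
  centrality <- vapply(targets, function(d)
    if (length(d)) mean(abs(d - mid)) else Inf, numeric(1))
  n_bystander <- mc$n_window_c - lengths(targets)
  n_bystander[n_bystander < 0L] <- 0L
  tier <- .pam_tier(mc$pam_class)
  o <- order(tier, centrality, n_bystander,
             GenomicRanges::start(cands),
             as.character(GenomicRanges::strand(cands)))
  cands[o]
}

#' Export guide candidates as TSV and JSON
#'
#' Fixed column order: \code{id}, \code{contig}, \code{start}, \code{end},
#' \code{strand}, \code{protospacer}, \code{pam}, \code{pam_class},
#' \code{window_c_dists}, \code{plan}, \code{bystanders} (1-based
#' coordinates; list columns serialised comma-separated in the TSV).
#'
#' @param guides Guide \code{GRanges}.
#' @param tsv_path,json_path Output paths (either may be \code{NULL}).
#' @return The table (invisibly).
#' @export
writeGuideTable <- function(guides, tsv_path = NULL, json_path = NULL) {
  mc <- S4Vectors::mcols(guides)
  plan <- if ("edited_codon" %in% names(mc))
    sprintf("%s:%s>%s@%s", mc$protein_notation, mc$original_codon,
            mc$edited_codon,
            vapply(as.list(mc$required_c_dists), paste, character(1),
                   collapse = ","))
  else rep("", length(guides))
  bystanders <- if ("bystanders" %in% names(mc)) mc$bystanders
                else rep("", length(guides))
  tab <- data.frame(
    id = if (is.null(names(guides))) sprintf("g%03d", seq_along(guides))
         else names(guides),
    contig = as.character(GenomicRanges::seqnames(guides)),
    start = GenomicRanges::start(guides),
    end = GenomicRanges::end(guides),
    strand = as.character(GenomicRanges::strand(guides)),
    protospacer = mc$protospacer,
    pam = mc$pam,
    pam_class = mc$pam_class,
    window_c_dists = vapply(as.list(mc$window_c_dists), paste, character(1),
                            collapse = ","),
    plan = plan,
    bystanders = bystanders,
    stringsAsFactors = FALSE)
  if (!is.null(tsv_path))
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(tab, json_path, auto_unbox = FALSE, digits = NA)
  invisible(tab)
}
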