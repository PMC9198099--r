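#' Enumerate C-to-T edits that convert a codon to a STOP
#'
#' A CBE deaminates Cs on the protospacer strand, which reads as C-to-T on
#' that strand: sense-strand C-to-T, or antisense-strand C-to-T seen as
#' G-to-A on the sense strand. For a codon, every non-empty subset of
#' sense C-to-T edits and every non-empty subset of sense G-to-A edits is
#' applied (one guide edits exactly one strand, so mixed subsets are
#' excluded) and subsets producing TAA, TAG or TGA are returned.
#'
#' @param codon 3-character string over A/C/G/T.
#' @return A data.frame with columns \code{edited_codon},
#'   \code{edited_strand} (\code{"sense"}/\code{"antisense"}), and list
#'   column \code{positions} (1-based positions within the codon that must
#'   convert). Zero rows when the codon has no C-to-T route to a STOP.
#' @examples
#' stopEditsForCodon("CAG")  # -> TAG via sense C1
#' stopEditsForCodon("TGG")  # -> TAG/TGA/TAA via antisense G-to-A
#' @export
stopEditsForCodon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L)
    stop("codon must be a single string", call. = FALSE)
  codon <- toupper(codon)
  ch <- strsplit(codon, "")[[1]]
  if (length(ch) != 3L || !all(ch %in% DNA_BASES))
    stop("codon must be 3 characters over A/C/G/T, got '", codon, "'",
         call. = FALSE)

  out <- list()
  enumerate <- function(pos, from, to, strand) {
    for (k in seq_along(pos)) {
      # combn over indices: combn(x, k) misreads a scalar x as seq_len(x)
      for (sub_i in utils::combn(seq_along(pos), k, simplify = FALSE)) {
        sub <- pos[sub_i]
        e <- ch
        e[sub] <- to
        ec <- paste(e, collapse = "")
        if (ec %in% STOP_CODONS)
          out[[length(out) + 1L]] <<- list(edited_codon = ec,
                                           edited_strand = strand,
                                           positions = sub)
      }
    }
  }
  enumerate(which(ch == "C"), "C", "T", "sense")
  enumerate(which(ch == "G"), "G", "A", "antisense")

  if (!length(out))
    return(data.frame(edited_codon = character(0),
                      edited_strand = character(0),
                      positions = I(list())))
  df <- data.frame(
    edited_codon = vapply(out, `[[`, character(1), "edited_codon"),
    edited_strand = vapply(out, `[[`, character(1), "edited_strand"),
    positions = I(lapply(out, `[[`, "positions")),
    stringsAsFactors = FALSE)
  df[order(df$edited_strand, df$edited_codon,
           vapply(df$positions, paste, character(1), collapse = ",")), ,
     drop = FALSE]
}

# coding forward-strand positions of the CDS, in translation order,
# honouring the phase of the first interval
.coding_positions <- function(ref) {
  cds <- refCds(ref)
  if (!nrow(cds)) stop("reference '", refId(ref),
                       "' has no CDS annotation", call. = FALSE)
  cds <- cds[order(cds$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    seq(cds$start[i], cds$end[i])))
  phase <- cds$frame[1]
  if (phase > 0L) pos <- pos[-seq_len(phase)]
  pos
}

#' Design guides that introduce a premature STOP at a residue
#'
#' For the codon at \code{residue} (1-based) of the reference's CDS, every
#' STOP conversion reachable by single-strand C-to-T editing is combined
#' with every guide whose editing window covers all required C positions on
#' the correct strand: sense edits need a \code{+} guide, antisense edits a
#' \code{-} guide (the deaminase acts on the protospacer strand). Results
#' are ordered by \code{\link{rankGuides}}.
#'
#' @param ref A \code{\link{CbeReference}} with CDS annotation.
#' @param residue 1-based residue (codon) number.
#' @param pam IUPAC PAM pattern to scan under.
#' @param window Editing window \code{c(min, max)}.
#' @return Guide \code{GRanges} with plan columns \code{codon_index}
#'   (1-based), \code{original_codon}, \code{edited_codon},
#'   \code{edited_strand}, \code{required_c_dists} (\code{IntegerList}),
#'   \code{protein_notation}, and a \code{bystanders} count of non-target
#'   window Cs. Empty with attribute \code{reason = "codon not convertible"}
#'   when no C-to-T route to a STOP exists.
#' @export
designStopGuides <- function(ref, residue, pam = "NNN",
                             window = c(13L, 19L)) {
  residue <- .assert_scalar_int(residue, "residue", 1L)
  pos <- .coding_positions(ref)
  if (3L * residue > length(pos))
    stop("residue ", residue, " beyond the annotated CDS (",
         length(pos) %/% 3L, " codons)", call. = FALSE)
  cpos <- pos[(3L * residue - 2L):(3L * residue)]
  s <- as.character(refSeq(ref))
  codon <- paste(substring(s, cpos, cpos), collapse = "")
  aa <- .translate_codon(codon)

  plans <- stopEditsForCodon(codon)
  cands <- scanProtospacers(ref, pam, window)
  if (!nrow(plans)) {
    res <- cands[0]
    attr(res, "reason") <- "codon not convertible"
    return(res)
  }

  hits <- list()
  for (p in seq_len(nrow(plans))) {
    strand_needed <- if (plans$edited_strand[p] == "sense") "+" else "-"
    req_pos <- cpos[plans$positions[[p]]]
    keep <- which(as.character(GenomicRanges::strand(cands)) == strand_needed)
    for (k in keep) {
      st <- GenomicRanges::start(cands)[k]
      d <- if (strand_needed == "+") st + 20L - req_pos else req_pos - st + 1L
      if (all(d >= window[1] & d <= window[2])) {
        g <- cands[k]
        S4Vectors::mcols(g)$codon_index <- residue
        S4Vectors::mcols(g)$original_codon <- codon
        S4Vectors::mcols(g)$edited_codon <- plans$edited_codon[p]
        S4Vectors::mcols(g)$edited_strand <- plans$edited_strand[p]
        S4Vectors::mcols(g)$required_c_dists <-
          IRanges::IntegerList(list(sort(as.integer(d))))
        S4Vectors::mcols(g)$protein_notation <- paste0(aa, residue, "*")
        S4Vectors::mcols(g)$bystanders <-
          S4Vectors::mcols(g)$n_window_c - length(d)
        hits[[length(hits) + 1L]] <- g
      }
    }
  }
  if (!length(hits)) {
    res <- cands[0]
    S4Vectors::metadata(res)$window <- as.integer(window)
    return(res)
  }
  res <- do.call(c, hits)
  S4Vectors::metadata(res)$window <- as.integer(window)
  rankGuides(res)
}

#' Annotate bystander Cs in a guide's editing window
#'
#' Every window C on the protospacer strand that is not one of the intended
#' targets is reported with the coding consequence of its C-to-T conversion
#' (via the standard genetic code): \code{synonymous}, \code{missense},
#' \code{nonsense}, or \code{noncoding} for positions outside the CDS.
#'
#' @param guide A single guide (length-1 \code{GRanges} from
#'   \code{\link{scanProtospacers}} / \code{\link{designStopGuides}}).
#' @param ref The \code{\link{CbeReference}} the guide was designed on.
#' @param target_dists Distances from the PAM of the intended edits.
#' @return data.frame with columns \code{c_dist}, \code{cds_consequence},
#'   \code{protein_notation} (\code{NA} for noncoding).
#' @export
annotateBystanders <- function(guide, ref, target_dists = integer(0)) {
  if (length(guide) != 1L)
    stop("guide must be a single candidate", call. = FALSE)
  s <- as.character(refSeq(ref))
  st <- GenomicRanges::start(guide)
  strand <- as.character(GenomicRanges::strand(guide))
  proto <- S4Vectors::mcols(guide)$protospacer
  site <- substr(s, st, st + 19L)
  site_proto <- if (strand == "+") site else .revcomp(site)
  if (!identical(site_proto, proto))
    stop("guide does not reconstruct from reference '", refId(ref), "'",
         call. = FALSE)

  dists <- setdiff(as.integer(S4Vectors::mcols(guide)$window_c_dists[[1]]),
                   as.integer(target_dists))
  if (!length(dists))
    return(data.frame(c_dist = integer(0), cds_consequence = character(0),
                      protein_notation = character(0)))

  pos <- if (strand == "+") st + 20L - dists else st + dists - 1L
  coding <- tryCatch(.coding_positions(ref), error = function(e) integer(0))

  res <- lapply(seq_along(dists), function(i) {
    p <- pos[i]
    idx <- match(p, coding)
    if (is.na(idx))
      return(list(c_dist = dists[i], cds_consequence = "noncoding",
                  protein_notation = NA_character_))
    codon_n <- (idx - 1L) %/% 3L + 1L
    cpos <- coding[(3L * codon_n - 2L):(3L * codon_n)]
    codon <- paste(substring(s, cpos, cpos), collapse = "")
    edited <- strsplit(codon, "")[[1]]
    within <- (idx - 1L) %% 3L + 1L
    edited[within] <- if (strand == "+") "T" else "A"
    edited <- paste(edited, collapse = "")
    aa0 <- .translate_codon(codon); aa1 <- .translate_codon(edited)
    consequence <- if (aa1 == "*") "nonsense"
      else if (aa0 == aa1) "synonymous" else "missense"
    list(c_dist = dists[i], cds_consequence = consequence,
         protein_notation = paste0(aa0, codon_n,
                                   if (aa1 == "*") "*" else aa1))
  })
  df <- data.frame(
    c_dist = vapply(res, `[[`, integer(1), "c_dist"),
    cds_consequence = vapply(res, `[[`, character(1), "cds_consequence"),
    protein_notation = vapply(res, `[[`, character(1), "protein_notation"),
    stringsAsFactors = FALSE)
  df[order(df$c_dist), , drop = FALSE]
}
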