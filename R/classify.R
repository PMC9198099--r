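#' Editing-outcome quantification result
#'
#' Aggregated outcome of classifying amplicon reads against an
#' \code{\link{AmpliconSpec}}: a per-position base-count matrix over the
#' editing window, read-category counts, and the summary rates reported in
#' base-editing experiments (per-target expected-edit rate, percent of reads
#' with other substitutions, percent with spacer-overlapping indels, and
#' their union as percent unwanted outcomes).
#'
#' Read categories, in precedence order: \code{discarded} (identity below
#' the floor or incomplete window coverage), \code{indel} (an insertion or
#' deletion overlapping the spacer), \code{other_substitution} (a window
#' substitution that is not an expected edit), \code{expected_edit_only}
#' (at least one expected C-to-T on the guide strand and no other
#' difference), \code{WT}.
#'
#' @slot nInput,nDiscarded,nAnalyzed Read counts.
#' @slot categories Named integer: WT, expected_edit_only,
#'   other_substitution, indel (sums to \code{nAnalyzed}).
#' @slot counts Integer matrix, window positions x (A, C, G, T, del);
#'   rownames are forward-strand amplicon positions.
#' @slot refBases Forward-strand reference base at each window position.
#' @slot targetRates Named numeric, expected-edit percent per target
#'   position (names = forward positions).
#' @slot pctOther,pctIndel,pctUnwanted Summary percentages over analyzed
#'   reads.
#' @export
setClass("QuantResult",
  representation(nInput = "integer", nDiscarded = "integer",
                 nAnalyzed = "integer", categories = "integer",
                 counts = "matrix", refBases = "character",
                 targetRates = "numeric", pctOther = "numeric",
                 pctIndel = "numeric", pctUnwanted = "numeric"))

setValidity("QuantResult", function(object) {
  msg <- character(0)
  cats <- c("WT", "expected_edit_only", "other_substitution", "indel")
  if (!identical(names(object@categories), cats))
    msg <- c(msg, "categories must be WT/expected_edit_only/other_substitution/indel")
  else if (sum(object@categories) != object@nAnalyzed)
    msg <- c(msg, "category counts must sum to nAnalyzed")
  if (object@nAnalyzed + object@nDiscarded != object@nInput)
    msg <- c(msg, "nAnalyzed + nDiscarded must equal nInput")
  if (!identical(colnames(object@counts), c("A", "C", "G", "T", "del")))
    msg <- c(msg, "counts columns must be A,C,G,T,del")
  rates <- c(object@targetRates, object@pctOther, object@pctIndel,
             object@pctUnwanted)
  if (length(rates) && (any(rates < 0) || any(rates > 100)))
    msg <- c(msg, "rates must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QuantResult", function(object) {
  cat("QuantResult: ", object@nInput, " reads in, ", object@nAnalyzed,
      " analyzed (", object@nDiscarded, " discarded)\n", sep = "")
  cat("  categories:",
      paste(names(object@categories), object@categories, sep = "=",
            collapse = ", "), "\n")
  if (length(object@targetRates))
    cat("  expected-edit rate (%):",
        paste(names(object@targetRates),
              sprintf("%.1f", object@targetRates), sep = ":",
              collapse = ", "), "\n")
  cat(sprintf("  other substitutions %.2f%%, indels %.2f%%, unwanted %.2f%%\n",
              object@pctOther, object@pctIndel, object@pctUnwanted))
})

#' @describeIn QuantResult category counts.
#' @param x A \code{QuantResult}.
#' @export
readCategories <- function(x) x@categories

#' @describeIn QuantResult per-position count matrix.
#' @export
windowCounts <- function(x) x@counts

#' @describeIn QuantResult expected-edit percent per target position.
#' @export
targetRates <- function(x) x@targetRates

#' @describeIn QuantResult percent of analyzed reads with unwanted outcomes
#'   (other substitutions and/or spacer indels).
#' @export
pctUnwanted <- function(x) x@pctUnwanted

#' @describeIn QuantResult percent of analyzed reads with spacer indels.
#' @export
pctIndel <- function(x) x@pctIndel

#' @describeIn QuantResult percent of analyzed reads with non-expected
#'   window substitutions.
#' @export
pctOther <- function(x) x@pctOther

#' Classify one aligned read
#'
#' Applies the category rules to a \code{ReadAlignment}: a read is
#' \code{discarded} when its identity is below the floor or it does not
#' cover the whole editing window; otherwise \code{indel} when an
#' insertion/deletion footprint overlaps the spacer (an insertion exactly at
#' a spacer boundary only counts when strictly inside); otherwise
#' \code{other_substitution} when any window substitution (whole-read when
#' \code{params$wholeReadSubstitutions}) is not an expected edit; otherwise
#' \code{expected_edit_only} when at least one expected edit is present;
#' otherwise \code{WT}.
#'
#' @param aln A \code{\link{alignRead}} result.
#' @param spec The \code{AmpliconSpec} the read was aligned against.
#' @param params See \code{\link{alignParams}}.
#' @return List with \code{category}, \code{window_bases} (observed
#'   forward-strand base or \code{"-"} per window position),
#'   \code{edited_target_count}.
#' @export
classifyRead <- function(aln, spec, params = alignParams()) {
  if (!inherits(aln, "ReadAlignment"))
    stop("aln must be a ReadAlignment", call. = FALSE)
  wpos <- windowPositions(spec)
  L <- length(spec@amplicon)
  if (aln$ref_end > L)
    stop("alignment does not fit the spec's amplicon", call. = FALSE)
  obs <- .observed_bases(aln, wpos)

  if (aln$identity < params$minIdentity || anyNA(obs))
    return(list(category = "discarded", window_bases = obs,
                edited_target_count = 0L))

  ss <- start(spec@spacer); se <- end(spec@spacer)
  ops <- aln$ops
  ind <- ops$op %in% c("I", "D")
  indel_hit <- FALSE
  if (any(ind)) {
    io <- ops[ind, , drop = FALSE]
    del <- io$op == "D"
    # deletion footprint [ref_pos, ref_pos+len-1]; insertion point before
    # ref_pos counts only strictly inside the spacer
    hit_del <- del & (io$ref_pos <= se) & (io$ref_pos + io$len - 1L >= ss)
    hit_ins <- !del & (io$ref_pos > ss) & (io$ref_pos <= se)
    indel_hit <- any(hit_del | hit_ins)
  }

  refb <- strsplit(as.character(spec@amplicon), "")[[1]]
  expected <- expectedBase(spec)
  tpos <- spec@targetPositions
  is_target <- wpos %in% tpos
  subst <- !is.na(obs) & obs != "-" & obs != refb[wpos]
  exp_edit <- subst & is_target & obs == expected
  other <- subst & !exp_edit
  if (params$wholeReadSubstitutions && !indel_hit) {
    mm <- ops[ops$op == "X", , drop = FALSE]
    if (nrow(mm)) {
      all_mm <- unlist(lapply(seq_len(nrow(mm)), function(i)
        seq(mm$ref_pos[i], length.out = mm$len[i])))
      if (length(setdiff(all_mm, wpos))) other <- c(other, TRUE)
    }
  }

  category <- if (indel_hit) "indel"
    else if (any(other)) "other_substitution"
    else if (any(exp_edit)) "expected_edit_only"
    else "WT"
  list(category = category, window_bases = obs,
       edited_target_count = sum(obs[is_target] == expected, na.rm = TRUE))
}

# observed forward-strand base per requested reference position:
# A/C/G/T from M/X columns, "-" under a deletion, NA when not covered
.observed_bases <- function(aln, pos) {
  obs <- rep(NA_character_, length(pos))
  ops <- aln$ops
  read <- aln$read
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]
    if (op == "I") next
    rp <- ops$ref_pos[i]; len <- ops$len[i]
    sel <- which(pos >= rp & pos <= rp + len - 1L)
    if (!length(sel)) next
    if (op == "D") obs[sel] <- "-"
    else obs[sel] <- substring(read, ops$read_pos[i] + (pos[sel] - rp),
                               ops$read_pos[i] + (pos[sel] - rp))
  }
  obs
}

#' Quantify editing outcomes from amplicon reads
#'
#' The NGS quantification pipeline: each read is aligned to the amplicon in
#' both orientations (affine gaps, read end-to-end, free reference end
#' gaps), classified, and accumulated into a per-position base-count matrix
#' over the editing window plus read-category fractions. Identical reads
#' are dereplicated before alignment, so runtime scales with the number of
#' distinct sequences. The per-target expected-edit rate is the fraction of
#' covering reads showing the expected base at that position.
#'
#' @param reads A \code{DNAStringSet}, character vector, or FASTQ path.
#' @param spec An \code{\link{AmpliconSpec}}.
#' @param params See \code{\link{alignParams}}; the quantifier defaults to
#'   a banded DP (band 32), exact for amplicon-length reads with indels
#'   shorter than the band.
#' @return A \code{\link{QuantResult}}.
#' @examples
#' ps <- plantGuideSite(makeReference(240, seed = 3),
#'   protospacer = "GATTACAGATTACAGACCAT", pam = "AGG",
#'   position = 101, strand = "+", targetDists = 15)
#' sim <- simulateReads(ps$spec, simTruth(editFractions = c(`15` = 0.4),
#'   nReads = 200, seed = 9))
#' quantifyAmplicon(sim$reads, ps$spec)
#' @export
quantifyAmplicon <- function(reads, spec, params = alignParams(band = 32L)) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readFastq(reads)
  reads <- as.character(reads)
  n_input <- length(reads)
  if (!n_input) stop("no reads supplied", call. = FALSE)

  uniq <- table(reads)
  useq <- names(uniq)
  mult <- as.integer(uniq)

  wpos <- windowPositions(spec)
  nw <- length(wpos)
  counts <- matrix(0L, nrow = nw, ncol = 5L,
                   dimnames = list(as.character(wpos),
                                   c("A", "C", "G", "T", "del")))
  cats <- c(WT = 0L, expected_edit_only = 0L, other_substitution = 0L,
            indel = 0L)
  n_disc <- 0L

  for (k in seq_along(useq)) {
    aln <- alignRead(useq[k], spec, params)
    cl <- classifyRead(aln, spec, params)
    if (cl$category == "discarded") { n_disc <- n_disc + mult[k]; next }
    cats[cl$category] <- cats[cl$category] + mult[k]
    obs <- cl$window_bases
    col <- match(obs, c("A", "C", "G", "T"))
    col[obs == "-"] <- 5L
    ok <- which(!is.na(col))
    if (length(ok))
      counts[cbind(ok, col[ok])] <- counts[cbind(ok, col[ok])] + mult[k]
  }

  n_analyzed <- n_input - n_disc
  if (n_analyzed == 0L)
    stop("no analyzable reads: all ", n_input, " reads were discarded",
         call. = FALSE)

  refb <- strsplit(as.character(spec@amplicon), "")[[1]][wpos]
  tpos <- spec@targetPositions
  trate <- vapply(tpos, function(p) {
    row <- counts[as.character(p), ]
    covering <- sum(row)
    if (covering == 0) return(NA_real_)
    100 * row[[expectedBase(spec)]] / covering
  }, numeric(1))
  names(trate) <- as.character(tpos)

  pct_other <- 100 * cats[["other_substitution"]] / n_analyzed
  pct_indel <- 100 * cats[["indel"]] / n_analyzed
  pct_unwanted <- 100 *
    (cats[["other_substitution"]] + cats[["indel"]]) / n_analyzed

  new("QuantResult", nInput = as.integer(n_input),
      nDiscarded = as.integer(n_disc), nAnalyzed = as.integer(n_analyzed),
      categories = cats, counts = counts, refBases = refb,
      targetRates = trate, pctOther = pct_other, pctIndel = pct_indel,
      pctUnwanted = pct_unwanted)
}

#' Write / read a quantification report
#'
#' Emits the per-position count matrix as TSV (columns \code{pos},
#' \code{ref_base}, \code{A}, \code{C}, \code{G}, \code{T}, \code{del},
#' \code{expected_rate_pct}) and a JSON summary (\code{n_input},
#' \code{n_discarded}, \code{n_analyzed}, \code{categories},
#' \code{per_target}, \code{pct_other_substitution}, \code{pct_indel},
#' \code{pct_unwanted}). \code{readQuantReport} parses both back; the
#' round trip reproduces the in-memory numbers exactly.
#'
#' @param result A \code{\link{QuantResult}}.
#' @param tsv_path,json_path Output paths (either may be \code{NULL}).
#' @export
writeQuantReport <- function(result, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    pos <- as.integer(rownames(result@counts))
    rate <- rep(NA_real_, length(pos))
    idx <- match(as.integer(names(result@targetRates)), pos)
    rate[idx] <- unname(result@targetRates)
    tab <- data.frame(pos = pos, ref_base = result@refBases,
                      result@counts, del = result@counts[, "del"],
                      expected_rate_pct = rate, check.names = FALSE)
    tab$del <- NULL
    tab <- tab[, c("pos", "ref_base", "A", "C", "G", "T", "del",
                   "expected_rate_pct")]
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n_input = result@nInput, n_discarded = result@nDiscarded,
      n_analyzed = result@nAnalyzed,
      categories = as.list(result@categories),
      per_target = lapply(seq_along(result@targetRates), function(i)
        list(pos = as.integer(names(result@targetRates)[i]),
             rate_pct = unname(result@targetRates[i]))),
      pct_other_substitution = result@pctOther,
      pct_indel = result@pctIndel,
      pct_unwanted = result@pctUnwanted),
      json_path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(list(tsv = tsv_path, json = json_path))
}

#' @rdname writeQuantReport
#' @export
readQuantReport <- function(tsv_path = NULL, json_path = NULL) {
  out <- list()
  if (!is.null(tsv_path))
    out$matrix <- utils::read.table(tsv_path, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
  if (!is.null(json_path))
    out$summary <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  out
}
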