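# Independent oracles and shared fixtures. Everything here is deliberately
# written against different machinery than the package internals it checks.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

# sample() misreads a scalar first argument as seq_len(x); always use this
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  # independent reverse complement (Biostrings-based)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---- stop-codon table oracle --------------------------------------------
# brute force over all 2^3 edit masks per strand, using Biostrings'
# GENETIC_CODE only to spot stops
oracle_stop_edits <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  res <- list()
  for (strand in c("sense", "antisense")) {
    editable <- if (strand == "sense") ch == "C" else ch == "G"
    to <- if (strand == "sense") "T" else "A"
    for (mask in 1:7) {
      bits <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
      if (any(bits & !editable)) next
      if (!any(bits)) next
      e <- ch
      e[bits] <- to
      ec <- paste(e, collapse = "")
      if (ec %in% c("TAA", "TAG", "TGA"))
        res[[length(res) + 1L]] <- list(edited = ec, strand = strand,
                                        positions = which(bits))
    }
  }
  res
}

# canonical string form of a stop-edit set, for set comparison
stop_set_key <- function(edited, strand, positions)
  paste(edited, strand, paste(sort(positions), collapse = "+"), sep = "|")

# ---- alignment score oracle ---------------------------------------------
oracle_align_score <- function(read, ref) {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                baseOnly = TRUE)
  s1 <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read), Biostrings::DNAString(ref),
    type = "global-local", substitutionMatrix = m,
    gapOpening = 8, gapExtension = 1))
  s2 <- Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::reverseComplement(Biostrings::DNAString(read)),
    Biostrings::DNAString(ref),
    type = "global-local", substitutionMatrix = m,
    gapOpening = 8, gapExtension = 1))
  max(s1, s2)
}

# ---- off-target brute force ---------------------------------------------
# quadratic position-by-position scan with its own IUPAC handling
oracle_offtargets <- function(genome, proto, max_mm, pam) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), N = c("A", "C", "G", "T"))
  pam_ok <- function(obs) {
    p <- strsplit(pam, "")[[1]]
    o <- strsplit(obs, "")[[1]]
    all(vapply(1:3, function(i) {
      if (o[i] == "N") p[i] == "N" else o[i] %in% iupac[[p[i]]]
    }, logical(1)))
  }
  gch <- strsplit(genome, "")[[1]]
  pch <- strsplit(proto, "")[[1]]
  pch_rc <- strsplit(revcomp_chr(proto), "")[[1]]
  n <- length(gch)
  hits <- list()
  for (st in seq_len(n - 19L)) {
    win <- gch[st:(st + 19L)]
    # forward strand placement needs a PAM to the right
    if (st + 22L <= n) {
      mm <- sum(win != pch | win == "N")
      if (mm <= max_mm &&
          pam_ok(paste(gch[(st + 20L):(st + 22L)], collapse = "")))
        hits[[length(hits) + 1L]] <- data.frame(
          start = st, strand = "+", mismatches = mm,
          stringsAsFactors = FALSE)
    }
    # reverse strand placement needs a PAM to the left
    if (st >= 4L) {
      mm <- sum(win != pch_rc | win == "N")
      if (mm <= max_mm &&
          pam_ok(revcomp_chr(paste(gch[(st - 3L):(st - 1L)],
                                   collapse = ""))))
        hits[[length(hits) + 1L]] <- data.frame(
          start = st, strand = "-", mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(0), strand = character(0),
                      mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$mismatches, out$start, out$strand), , drop = FALSE]
}

# ---- exhaustive permutation p oracle -------------------------------------
# insertion-based permutation generation (different algorithm from the
# package) + stats::cor for the Spearman statistic
oracle_exact_perm_p <- function(g, y) {
  perms_of <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (p in perms_of(v[-1L])) {
      for (k in 0:length(p)) {
        out[[length(out) + 1L]] <- append(p, v[1L], after = k)
      }
    }
    out
  }
  obs <- stats::cor(rank(g), rank(y), method = "pearson")
  stats_all <- vapply(perms_of(seq_along(y)), function(idx)
    stats::cor(rank(g), rank(y[idx]), method = "pearson"), numeric(1))
  mean(abs(stats_all) >= abs(obs) - 1e-8)
}

# ---- shared fixtures -----------------------------------------------------
# a 240-bp amplicon with a planted + guide; Cs at distances 15 and 16
toy_spec <- function(seed = 3L, strand = "+", window = c(13L, 19L)) {
  proto <- paste0("GATT", "CC", strrep("A", 14))   # Cs at d = 16, 15
  plantGuideSite(makeReference(240, seed = seed),
                 protospacer = proto, pam = "AGG",
                 position = if (strand == "+") 101L else 104L,
                 strand = strand, window = window)
}

# apply a single forward-strand substitution to a sequence
mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}
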