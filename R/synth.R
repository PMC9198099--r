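#' Generate a random reference sequence
#'
#' Seeded i.i.d. sequence with a target GC content. When \code{length} is
#' \code{NULL} an amplicon-sized length is drawn uniformly from 228--313 bp
#' (the span of typical base-editing amplicons).
#'
#' @param length Sequence length (>= 23), or \code{NULL} to draw one.
#' @param gc Target GC fraction in [0, 1].
#' @param seed Integer seed.
#' @param id Reference identifier.
#' @param cds Optional CDS table (see \code{\link{CbeReference}}).
#' @return A \code{\link{CbeReference}}.
#' @examples
#' makeReference(250, gc = 0.5, seed = 7)
#' @export
makeReference <- function(length = NULL, gc = 0.5, seed = 1L, id = "ref",
                          cds = NULL) {
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  if (is.null(length)) length <- sample(228:313, 1L)
  length <- .assert_scalar_int(length, "length", 23L)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seq <- paste(sample(DNA_BASES, length, replace = TRUE, prob = probs),
               collapse = "")
  CbeReference(seq, id = id, cds = cds)
}

#' Plant a guide site into a reference
#'
#' Overwrites the reference so that the given protospacer + PAM occupy the
#' requested position and strand, and returns both the modified reference
#' and the matching \code{\link{AmpliconSpec}}. The planted site is
#' guaranteed to be recovered by \code{\link{scanProtospacers}} with a
#' matching PAM pattern.
#'
#' @param ref A \code{\link{CbeReference}}.
#' @param protospacer 20-nt protospacer-strand sequence.
#' @param pam Concrete 3-nt PAM (protospacer strand).
#' @param position 1-based forward-strand start of the protospacer
#'   interval.
#' @param strand \code{"+"} or \code{"-"}.
#' @param targetDists Distances from the PAM of the intended targets;
#'   default every window C of the planted guide.
#' @param window Editing window.
#' @return List with elements \code{ref} (modified \code{CbeReference})
#'   and \code{spec} (\code{AmpliconSpec}).
#' @export
plantGuideSite <- function(ref, protospacer, pam, position, strand = "+",
                           targetDists = NULL, window = c(13L, 19L)) {
  protospacer <- toupper(protospacer); pam <- toupper(pam)
  .check_dna(protospacer, "protospacer", allow_n = FALSE)
  .check_dna(pam, "pam", allow_n = FALSE)
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt",
                                      call. = FALSE)
  if (nchar(pam) != 3L) stop("pam must be 3 nt", call. = FALSE)
  position <- .assert_scalar_int(position, "position", 1L)
  s <- strsplit(as.character(refSeq(ref)), "")[[1]]
  n <- length(s)

  if (strand == "+") {
    if (position + 22L > n)
      stop("site overlaps the sequence end", call. = FALSE)
    ins <- strsplit(paste0(protospacer, pam), "")[[1]]
    s[position:(position + 22L)] <- ins
  } else {
    if (position < 4L || position + 19L > n)
      stop("site overlaps the sequence end", call. = FALSE)
    ins <- strsplit(.revcomp(paste0(protospacer, pam)), "")[[1]]
    s[(position - 3L):(position + 19L)] <- ins
  }
  ref2 <- CbeReference(paste(s, collapse = ""), id = refId(ref),
                       cds = refCds(ref))
  if (is.null(targetDists)) {
    d <- seq(window[1], window[2])
    pch <- strsplit(protospacer, "")[[1]]
    targetDists <- d[pch[21L - d] == "C"]
  }
  spec <- AmpliconSpec(ref2, spacerStart = position, guideStrand = strand,
                       targetDists = targetDists, window = window)
  list(ref = ref2, spec = spec)
}

#' Ground truth for read simulation
#'
#' @param editFractions Named numeric vector of per-target true edit
#'   fractions, names = distances from the PAM.
#' @param errorRate Per-base uniform substitution error rate.
#' @param indelRate Per-read probability of one spacer indel.
#' @param indelMeanLen Mean indel length (geometric, support >= 1).
#' @param nReads Number of reads.
#' @param seed Integer seed.
#' @return Validated list (class \code{SimTruth}).
#' @export
simTruth <- function(editFractions = numeric(0), errorRate = 0.001,
                     indelRate = 0, indelMeanLen = 2, nReads = 6800L,
                     seed = 1L) {
  rates <- c(editFractions, errorRate, indelRate)
  if (length(rates) && (any(rates < 0) || any(rates > 1)))
    stop("all rates must lie in [0, 1]", call. = FALSE)
  if (indelMeanLen < 1) stop("indelMeanLen must be >= 1", call. = FALSE)
  nReads <- .assert_scalar_int(nReads, "nReads", 1L)
  structure(list(editFractions = editFractions, errorRate = errorRate,
                 indelRate = indelRate, indelMeanLen = indelMeanLen,
                 nReads = nReads, seed = as.integer(seed)),
            class = "SimTruth")
}

#' Simulate amplicon reads with known ground truth
#'
#' Each read starts as a full-length amplicon copy (merged-read
#' abstraction); per read, independently: the expected edit is applied at
#' each target with its true fraction (on the guide strand), then with
#' probability \code{indelRate} one indel whose reference footprint lies
#' inside the spacer (deletion, or insertion strictly inside), then uniform
#' substitution errors; finally about half the reads are emitted
#' reverse-complemented. Ground truth per read is returned as a sidecar
#' table and optionally written as TSV next to the FASTQ.
#'
#' @param spec An \code{\link{AmpliconSpec}}.
#' @param truth A \code{\link{simTruth}} object; names of
#'   \code{editFractions} must be target distances of \code{spec} (an
#'   unnamed vector of length one per target is recycled positionally in
#'   ascending distance order).
#' @param fastq_path,truth_path Optional output paths (FASTQ may be .gz).
#' @return Invisible list with \code{reads} (\code{DNAStringSet}) and
#'   \code{truth} (data.frame: \code{read_id}, \code{orientation},
#'   \code{edited_dists}, \code{n_expected_edits}, \code{indel},
#'   \code{indel_type}, \code{n_errors}).
#' @export
simulateReads <- function(spec, truth, fastq_path = NULL,
                          truth_path = NULL) {
  if (!inherits(truth, "SimTruth"))
    stop("truth must come from simTruth()", call. = FALSE)
  set.seed(truth$seed)
  n <- truth$nReads
  ref <- as.character(amplicon(spec))
  L <- nchar(ref)
  td <- targetDists(spec)
  ef <- truth$editFractions
  if (length(ef)) {
    if (is.null(names(ef))) {
      if (length(ef) != length(td))
        stop("unnamed editFractions must match the number of targets",
             call. = FALSE)
      names(ef) <- as.character(td)
    }
    if (!all(names(ef) %in% as.character(td)))
      stop("editFractions names must be target distances (",
           paste(td, collapse = ","), ")", call. = FALSE)
  }

  M <- matrix(strsplit(ref, "")[[1]], nrow = n, ncol = L, byrow = TRUE)
  expected <- expectedBase(spec)
  edited_mask <- matrix(FALSE, n, length(ef))
  if (length(ef)) colnames(edited_mask) <- names(ef)
  for (j in seq_along(ef)) {
    p <- .position_for_dist(spec, as.integer(names(ef)[j]))
    hit <- stats::runif(n) < ef[j]
    M[hit, p] <- expected
    edited_mask[, j] <- hit
  }

  # spacer indel (one per selected read)
  has_indel <- stats::runif(n) < truth$indelRate
  indel_type <- ifelse(has_indel,
                       ifelse(stats::runif(n) < 0.5, "del", "ins"), "")
  ss <- start(spacerRange(spec)); se <- end(spacerRange(spec))
  p_len <- 1 / truth$indelMeanLen
  # substitution errors
  err <- matrix(stats::runif(n * L) < truth$errorRate, n, L)
  n_err <- rowSums(err)
  if (any(err)) {
    idx <- which(err)
    cur <- M[idx]
    alt <- vapply(cur, function(b)
      sample(setdiff(DNA_BASES, b), 1L), character(1))
    M[idx] <- alt
  }

  seqs <- apply(M, 1L, paste, collapse = "")
  for (i in which(has_indel)) {
    len <- 1L + stats::rgeom(1L, p_len)
    if (indel_type[i] == "del") {
      maxs <- se - len + 1L
      st <- if (maxs > ss) sample(ss:maxs, 1L) else ss
      len <- min(len, se - st + 1L)
      seqs[i] <- paste0(substr(seqs[i], 1L, st - 1L),
                        substr(seqs[i], st + len, L))
    } else {
      at <- sample((ss + 1L):se, 1L)  # insert before `at`: strictly inside
      insseq <- paste(sample(DNA_BASES, len, replace = TRUE),
                      collapse = "")
      seqs[i] <- paste0(substr(seqs[i], 1L, at - 1L), insseq,
                        substr(seqs[i], at, L))
    }
  }

  rc <- stats::runif(n) < 0.5
  seqs[rc] <- .revcomp(seqs[rc])
  ids <- sprintf("read%06d", seq_len(n))
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids

  edited_dists <- if (length(ef))
    apply(edited_mask, 1L, function(r)
      paste(sort(as.integer(names(ef)[r])), collapse = ","))
  else rep("", n)
  truth_tab <- data.frame(
    read_id = ids,
    orientation = ifelse(rc, "reverse-complement", "forward"),
    edited_dists = edited_dists,
    n_expected_edits = if (length(ef)) as.integer(rowSums(edited_mask))
                       else 0L,
    indel = has_indel,
    indel_type = indel_type,
    n_errors = n_err,
    stringsAsFactors = FALSE)

  if (!is.null(fastq_path)) writeFastq(reads, fastq_path)
  if (!is.null(truth_path))
    utils::write.table(truth_tab, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(reads = reads, truth = truth_tab))
}

#' Simulate a Sanger trace from an allele mixture
#'
#' Per position, each channel's height is 1000 times the summed fraction of
#' alleles carrying that base, plus a zero-truncated Gaussian noise term
#' (the absolute value of a normal draw with SD \code{1000 * noise_sd},
#' i.e. half-normal, so heights stay non-negative and baseline channels
#' carry positive noise the way real chromatogram baselines do). The
#' primary call at each position is the highest channel.
#'
#' @param alleles Character vector of equal-length allele sequences (e.g.
#'   wild-type amplicon and \code{\link{editedAllele}} product).
#' @param fractions Allele fractions summing to 1.
#' @param noise_sd Channel noise SD as a fraction of full scale (0.02 =
#'   2\% noise).
#' @param seed Integer seed.
#' @param ab1_path Optional path to also write a minimal AB1 file.
#' @return A \code{\link{TraceData}}.
#' @examples
#' ps <- plantGuideSite(makeReference(240, seed = 3),
#'   protospacer = "GATTACAGATTACAGACCAT", pam = "AGG",
#'   position = 101, strand = "+", targetDists = 15)
#' tr <- simulateTrace(c(as.character(amplicon(ps$spec)),
#'                       editedAllele(ps$spec)), c(0.05, 0.95),
#'                     noise_sd = 0, seed = 1)
#' @export
simulateTrace <- function(alleles, fractions, noise_sd = 0.02, seed = 1L,
                          ab1_path = NULL) {
  if (length(alleles) != length(fractions) || !length(alleles))
    stop("alleles and fractions must have equal positive length",
         call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-6 || any(fractions < 0))
    stop("fractions must be non-negative and sum to 1", call. = FALSE)
  if (length(unique(nchar(alleles))) != 1L)
    stop("alleles must have equal length", call. = FALSE)
  set.seed(seed)
  L <- nchar(alleles[1])
  h <- matrix(0, L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (a in seq_along(alleles)) {
    ch <- strsplit(toupper(alleles[a]), "")[[1]]
    for (b in DNA_BASES) {
      sel <- ch == b
      h[sel, b] <- h[sel, b] + 1000 * fractions[a]
    }
  }
  if (noise_sd > 0)
    h <- h + matrix(abs(stats::rnorm(L * 4L, 0, 1000 * noise_sd)), L, 4L)
  called <- paste(DNA_BASES[max.col(h, ties.method = "first")],
                  collapse = "")
  trace <- TraceData(called, h)
  if (!is.null(ab1_path)) writeAb1(trace, ab1_path)
  trace
}
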