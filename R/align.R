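#' Alignment and classification parameters
#'
#' Defaults: match +2, mismatch -3, gap open -8, gap extend -1 (a gap of
#' length L costs 8 + L); reads with alignment identity below
#' \code{minIdentity} or not covering the whole editing window are discarded.
#' Substitution accounting is window-scoped unless
#' \code{wholeReadSubstitutions} is set.
#'
#' @param match,mismatch,gapOpen,gapExt Alignment scores (penalties positive).
#' @param minIdentity Identity floor below which a read is discarded.
#' @param wholeReadSubstitutions If \code{TRUE}, substitutions anywhere in
#'   the read (not only inside the window) count as unexpected.
#' @param band Diagonal band half-width: when positive, the DP is
#'   restricted to \code{|ref_pos - read_pos| <= band} whenever the read
#'   and reference lengths differ by at most \code{band/2}. Exact for
#'   full-length amplicon reads whose indels are smaller than the band,
#'   and roughly an order of magnitude faster; 0 (the default) always runs
#'   the exhaustive DP. \code{\link{quantifyAmplicon}} uses band 32 by
#'   default.
#' @return A named list of parameters.
#' @export
alignParams <- function(match = 2, mismatch = -3, gapOpen = 8, gapExt = 1,
                        minIdentity = 0.75, wholeReadSubstitutions = FALSE,
                        band = 0L) {
  stopifnot(gapOpen >= 0, gapExt >= 0, minIdentity >= 0, minIdentity <= 1,
            band >= 0)
  list(match = match, mismatch = mismatch, gapOpen = gapOpen,
       gapExt = gapExt, minIdentity = minIdentity,
       wholeReadSubstitutions = isTRUE(wholeReadSubstitutions),
       band = as.integer(band))
}

#' Align one read to an amplicon reference
#'
#' Affine-gap alignment, end-to-end on the read with free end gaps on the
#' reference; both orientations are tried and the higher-scoring one is
#' returned (forward wins ties). Deterministic for fixed parameters.
#'
#' @param read Character string, \code{DNAString}, or named character.
#' @param spec An \code{AmpliconSpec} (or a reference sequence).
#' @param params See \code{\link{alignParams}}.
#' @return A \code{ReadAlignment}: list with \code{score},
#'   \code{orientation} (\code{"forward"} / \code{"reverse-complement"}),
#'   \code{ref_start}, \code{ref_end}, \code{identity}, and an \code{ops}
#'   data.frame (\code{op} in M/X/I/D, \code{ref_pos}, \code{read_pos},
#'   \code{len}) tiling the read.
#' @export
alignRead <- function(read, spec, params = alignParams()) {
  ref <- if (is(spec, "AmpliconSpec")) as.character(spec@amplicon)
         else as.character(spec)
  read <- toupper(as.character(read))
  if (!nzchar(read)) stop("read must be non-empty", call. = FALSE)
  fwd <- .cbe_align(read, ref, params$match, params$mismatch,
                    params$gapOpen, params$gapExt, params$band)
  rc <- .cbe_align(.revcomp(read), ref, params$match, params$mismatch,
                   params$gapOpen, params$gapExt, params$band)
  aln <- if (rc$score > fwd$score) {
    rc$orientation <- "reverse-complement"; rc$read <- .revcomp(read); rc
  } else {
    fwd$orientation <- "forward"; fwd$read <- read; fwd
  }
  structure(aln, class = "ReadAlignment")
}

#' @export
print.ReadAlignment <- function(x, ...) {
  cat("ReadAlignment: score ", x$score, ", ", x$orientation,
      ", ref ", x$ref_start, "-", x$ref_end,
      ", identity ", round(x$identity, 3), "\n", sep = "")
  invisible(x)
}
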