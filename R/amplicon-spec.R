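#' Amplicon specification for editing quantification
#'
#' An \code{AmpliconSpec} ties an amplicon reference to the guide placed on
#' it: the spacer (protospacer) interval, the adjacent PAM, the strand the
#' guide edits, the forward-strand positions of the expected target Cs, and
#' the editing window in distance-from-PAM coordinates.
#'
#' Distance convention: distance \eqn{d} from the PAM denotes the protospacer
#' base \eqn{d} positions 5' of the PAM, 1-based, so the PAM-adjacent base is
#' \eqn{d = 1} and the default window (13, 19) spans protospacer positions
#' 2--8 from the protospacer 5' end.
#'
#' On a \code{+} guide the target bases are C on the forward strand (edited
#' to T); on a \code{-} guide they appear as G on the forward strand (edited
#' to A).
#'
#' @slot ampliconId Amplicon identifier.
#' @slot amplicon The amplicon reference (\code{DNAString}), typically
#'   228--313 bp.
#' @slot spacer \code{IRanges} of the 20-nt protospacer (forward strand,
#'   1-based closed).
#' @slot pam \code{IRanges} of the adjacent 3-nt PAM.
#' @slot guideStrand \code{"+"} or \code{"-"}.
#' @slot targetPositions Integer forward-strand amplicon positions of the
#'   expected edited Cs.
#' @slot window Integer (min, max) distance-from-PAM window.
#' @export
setClass("AmpliconSpec",
  representation(ampliconId = "character", amplicon = "DNAString",
                 spacer = "IRanges", pam = "IRanges",
                 guideStrand = "character", targetPositions = "integer",
                 window = "integer"))

setValidity("AmpliconSpec", function(object) {
  msg <- character(0)
  L <- length(object@amplicon)
  sp <- object@spacer; pm <- object@pam
  if (length(sp) != 1L || width(sp) != 20L)
    msg <- c(msg, "spacer must be a single 20-bp interval")
  if (length(pm) != 1L || width(pm) != 3L)
    msg <- c(msg, "pam must be a single 3-bp interval")
  if (!object@guideStrand %in% c("+", "-"))
    msg <- c(msg, "guideStrand must be '+' or '-'")
  w <- object@window
  if (length(w) != 2L || w[1] > w[2] || w[1] < 1L || w[2] > 20L)
    msg <- c(msg, "window must be (min, max) with 1 <= min <= max <= 20")
  if (!length(msg)) {
    if (start(sp) < 1L || end(sp) > L || start(pm) < 1L || end(pm) > L)
      msg <- c(msg, "spacer/pam out of amplicon bounds")
    else {
      adj_ok <- if (object@guideStrand == "+")
        start(pm) == end(sp) + 1L else end(pm) == start(sp) - 1L
      if (!adj_ok)
        msg <- c(msg, "pam not adjacent to spacer on the PAM side")
      if (length(object@targetPositions)) {
        d <- .dist_for_position(object, object@targetPositions)
        if (any(is.na(d)) || any(d < w[1] | d > w[2]))
          msg <- c(msg, "target positions must fall inside the editing window")
        ref <- as.character(object@amplicon)
        want <- if (object@guideStrand == "+") "C" else "G"
        bases <- substring(ref, object@targetPositions,
                           object@targetPositions)
        if (any(bases != want))
          msg <- c(msg, sprintf(
            "forward-strand base at each target must be %s for a %s guide",
            want, object@guideStrand))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

# forward amplicon position(s) -> distance from PAM, NA if outside protospacer
.dist_for_position <- function(spec, pos) {
  s <- start(spec@spacer)
  d <- if (spec@guideStrand == "+") s + 20L - pos else pos - s + 1L
  d[d < 1L | d > 20L] <- NA_integer_
  d
}

# distance from PAM -> forward amplicon position
.position_for_dist <- function(spec, d) {
  s <- start(spec@spacer)
  if (spec@guideStrand == "+") s + 20L - as.integer(d) else s + as.integer(d) - 1L
}

#' Construct an AmpliconSpec
#'
#' @param amplicon Amplicon sequence (character or \code{DNAString}), or a
#'   \code{CbeReference}.
#' @param spacerStart 1-based forward-strand start of the 20-nt protospacer
#'   interval.
#' @param guideStrand \code{"+"} or \code{"-"}.
#' @param targetDists Distances from the PAM of the expected target Cs.
#' @param window Editing window \code{c(min, max)}; default \code{c(13, 19)},
#'   use \code{c(12, 19)} for the extended near-PAM-less window.
#' @param id Amplicon identifier.
#' @return An \code{AmpliconSpec}.
#' @examples
#' ref <- makeReference(250, seed = 11)
#' ps <- plantGuideSite(ref, protospacer = strrep("A", 13) %+%
#'   "CC" %+% strrep("A", 5), pam = "AGG", position = 100, strand = "+")
#' ps$spec
#' @export
AmpliconSpec <- function(amplicon, spacerStart, guideStrand = "+",
                         targetDists = integer(0), window = c(13L, 19L),
                         id = "amplicon") {
  if (is(amplicon, "CbeReference")) { id <- refId(amplicon); amplicon <- refSeq(amplicon) }
  if (is.character(amplicon)) amplicon <- Biostrings::DNAString(toupper(amplicon))
  spacerStart <- .assert_scalar_int(spacerStart, "spacerStart", 1L)
  spacer <- IRanges::IRanges(spacerStart, width = 20L)
  pam <- if (guideStrand == "+")
    IRanges::IRanges(spacerStart + 20L, width = 3L)
  else IRanges::IRanges(spacerStart - 3L, width = 3L)
  obj <- new("AmpliconSpec", ampliconId = as.character(id),
             amplicon = amplicon, spacer = spacer, pam = pam,
             guideStrand = guideStrand,
             targetPositions = integer(0),
             window = as.integer(window))
  obj@targetPositions <- sort(.position_for_dist(obj, targetDists))
  validObject(obj)
  obj
}

#' @describeIn AmpliconSpec the amplicon \code{DNAString}.
#' @param x An \code{AmpliconSpec}.
#' @export
amplicon <- function(x) x@amplicon

#' @describeIn AmpliconSpec protospacer interval (\code{IRanges}).
#' @export
spacerRange <- function(x) x@spacer

#' @describeIn AmpliconSpec PAM interval (\code{IRanges}).
#' @export
pamRange <- function(x) x@pam

#' @describeIn AmpliconSpec forward-strand target C positions.
#' @export
targetPositions <- function(x) x@targetPositions

#' @describeIn AmpliconSpec distances from PAM of the targets.
#' @export
targetDists <- function(x) sort(.dist_for_position(x, x@targetPositions))

#' @describeIn AmpliconSpec guide strand.
#' @export
guideStrand <- function(x) x@guideStrand

#' @describeIn AmpliconSpec editing window \code{c(min, max)}.
#' @export
editingWindow <- function(x) x@window

#' @describeIn AmpliconSpec forward-strand positions of the whole editing
#'   window (ascending).
#' @export
windowPositions <- function(x) {
  sort(.position_for_dist(x, seq(x@window[1], x@window[2])))
}

#' @describeIn AmpliconSpec expected observed base at targets on the forward
#'   strand (\code{"T"} for + guides, \code{"A"} for -).
#' @export
expectedBase <- function(x) if (x@guideStrand == "+") "T" else "A"

setMethod("show", "AmpliconSpec", function(object) {
  cat("AmpliconSpec '", object@ampliconId, "': ", length(object@amplicon),
      " bp amplicon\n  spacer ", start(object@spacer), "-",
      end(object@spacer), " (", object@guideStrand, "), PAM ",
      start(object@pam), "-", end(object@pam),
      "\n  window ", object@window[1], "-", object@window[2],
      " bp from PAM; targets at distance ",
      paste(targetDists(object), collapse = ","), "\n", sep = "")
})

#' Spec YAML round trip
#'
#' Serialise / load an \code{AmpliconSpec} to the documented YAML dialect
#' (fields \code{id}, \code{amplicon}, \code{spacer_start},
#' \code{guide_strand}, \code{target_dists}, \code{window}).
#'
#' @param spec An \code{AmpliconSpec}.
#' @param path YAML file path.
#' @export
writeAmpliconSpecYaml <- function(spec, path) {
  yaml::write_yaml(list(
    id = spec@ampliconId,
    amplicon = as.character(spec@amplicon),
    spacer_start = start(spec@spacer),
    guide_strand = spec@guideStrand,
    target_dists = as.integer(targetDists(spec)),
    window = as.integer(spec@window)), path)
  invisible(path)
}

#' @rdname writeAmpliconSpecYaml
#' @export
readAmpliconSpecYaml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  AmpliconSpec(y$amplicon, spacerStart = y$spacer_start,
               guideStrand = y$guide_strand,
               targetDists = as.integer(y$target_dists),
               window = as.integer(y$window), id = y$id)
}

#' Apply the expected edits to an amplicon sequence
#'
#' Returns the amplicon with the expected C-to-T (forward C>T for + guides,
#' forward G>A for - guides) applied at the given distances; used to build
#' edited alleles for trace simulation and fixtures.
#'
#' @param spec An \code{AmpliconSpec}.
#' @param dists Distances from the PAM to edit; default all targets.
#' @return Character string.
#' @export
editedAllele <- function(spec, dists = targetDists(spec)) {
  s <- strsplit(as.character(spec@amplicon), "")[[1]]
  pos <- .position_for_dist(spec, dists)
  s[pos] <- expectedBase(spec)
  paste(s, collapse = "")
}

#' @rdname grapes-plus-grapes
#' @name grapes-plus-grapes
#' @title String concatenation helper
#' @param a,b Character vectors.
#' @usage a \%+\% b
#' @return \code{paste0(a, b)}.
#' @export
`%+%` <- function(a, b) paste0(a, b)
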