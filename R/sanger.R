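#' Sanger trace data for editing quantification
#'
#' Per-called-base four-channel peak heights from a Sanger chromatogram,
#' the input of EditR-style editing quantification.
#'
#' @slot calledBases Primary base calls as one string.
#' @slot peakHeights Numeric matrix, called positions x channels
#'   (columns A, C, G, T), non-negative with at least one positive channel
#'   per position.
#' @export
setClass("TraceData",
  representation(calledBases = "character", peakHeights = "matrix"))

setValidity("TraceData", function(object) {
  msg <- character(0)
  h <- object@peakHeights
  if (!identical(colnames(h), c("A", "C", "G", "T")))
    msg <- c(msg, "peakHeights columns must be A,C,G,T")
  if (length(object@calledBases) != 1L ||
      nchar(object@calledBases) != nrow(h))
    msg <- c(msg, "calledBases length must equal nrow(peakHeights)")
  if (any(h < 0)) msg <- c(msg, "peak heights must be non-negative")
  if (nrow(h) && any(rowSums(h) <= 0))
    msg <- c(msg, "every position needs at least one positive channel")
  if (length(msg)) msg else TRUE
})

#' @describeIn TraceData constructor.
#' @param calledBases Primary base calls (single string).
#' @param peakHeights Numeric matrix with columns A, C, G, T.
#' @export
TraceData <- function(calledBases, peakHeights) {
  peakHeights <- as.matrix(peakHeights)
  colnames(peakHeights) <- c("A", "C", "G", "T")
  new("TraceData", calledBases = as.character(calledBases),
      peakHeights = peakHeights)
}

#' @describeIn TraceData primary base calls.
#' @param x,object A \code{TraceData}.
#' @export
calledBases <- function(x) x@calledBases

#' @describeIn TraceData peak-height matrix.
#' @export
peakHeights <- function(x) x@peakHeights

setMethod("show", "TraceData", function(object) {
  cat("TraceData: ", nrow(object@peakHeights), " called bases\n", sep = "")
})

#' Parse a Sanger trace file
#'
#' Accepts either an AB1 (ABIF) chromatogram or the 5-column tabular trace
#' dialect: a TSV with header \code{base}, \code{A}, \code{C}, \code{G},
#' \code{T}, one row per called base. AB1 files are recognised by their
#' magic bytes.
#'
#' @param path Trace file.
#' @return A \code{\link{TraceData}}.
#' @export
parseTrace <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  if (identical(rawToChar(magic), "ABIF")) return(readAb1(path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("base", "A", "C", "G", "T")
  if (!all(need %in% names(tab)))
    stop("tabular trace needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  h <- as.matrix(tab[, c("A", "C", "G", "T")])
  zero <- which(rowSums(h) <= 0)
  if (length(zero))
    stop("all-zero peak heights at trace row ", zero[1], call. = FALSE)
  TraceData(paste(tab$base, collapse = ""), h)
}

#' @rdname parseTrace
#' @param trace A \code{TraceData} to write.
#' @export
writeTraceTsv <- function(trace, path) {
  tab <- data.frame(base = strsplit(trace@calledBases, "")[[1]],
                    trace@peakHeights, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- minimal ABIF (AB1) subset ------------------------------------------
# ABIF is a big-endian tag directory; the subset handled here is the one
# needed for per-called-base peak heights: FWO_ (channel order), PBAS
# (base calls), PLOC (peak locations), DATA 9-12 (processed traces).

.abif_entry <- function(name, number, type, elsize, nel, data_raw) {
  list(name = name, number = number, type = type, elsize = elsize,
       nel = nel, data = data_raw)
}

#' Minimal AB1 (ABIF) reading and writing
#'
#' Reads the subset of an ABIF chromatogram needed for quantification:
#' processed traces (\code{DATA} 9--12), peak locations (\code{PLOC}),
#' base calls (\code{PBAS}) and channel order (\code{FWO_}); peak heights
#' are the trace values at each called peak. \code{writeAb1} emits a
#' matching minimal file (one trace sample per called base) so synthetic
#' traces can round-trip through the binary format.
#'
#' @param path AB1 file.
#' @return \code{readAb1}: a \code{\link{TraceData}}.
#' @export
readAb1 <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (!identical(rawToChar(raw[1:4]), "ABIF"))
    stop("not an ABIF file: ", path, call. = FALSE)
  int4 <- function(off) readBin(raw[(off + 1):(off + 4)], "integer",
                                size = 4, endian = "big")
  int2 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer",
                                size = 2, endian = "big")
  n_entries <- int4(18)
  dir_off <- int4(26)
  entries <- lapply(seq_len(n_entries), function(i) {
    o <- dir_off + (i - 1L) * 28L
    name <- rawToChar(raw[(o + 1):(o + 4)])
    number <- int4(o + 4)
    type <- int2(o + 8)
    elsize <- int2(o + 10)
    nel <- int4(o + 12)
    dsize <- int4(o + 16)
    doff <- if (dsize <= 4L) o + 20L else int4(o + 20)
    list(name = name, number = number, type = type, nel = nel,
         data = raw[(doff + 1):(doff + dsize)])
  })
  get <- function(name, number) {
    for (e in entries) if (e$name == name && e$number == number) return(e)
    NULL
  }
  read_shorts <- function(e)
    readBin(e$data, "integer", n = e$nel, size = 2, endian = "big")
  fwo <- get("FWO_", 1L)
  order_ <- if (is.null(fwo)) "GATC" else rawToChar(fwo$data[1:4])
  pbas <- get("PBAS", 2L); if (is.null(pbas)) pbas <- get("PBAS", 1L)
  ploc <- get("PLOC", 2L); if (is.null(ploc)) ploc <- get("PLOC", 1L)
  if (is.null(pbas) || is.null(ploc))
    stop("ABIF file lacks PBAS/PLOC tags: ", path, call. = FALSE)
  bases <- rawToChar(pbas$data[seq_len(pbas$nel)])
  peaks <- read_shorts(ploc) + 1L  # 0-based sample indices
  traces <- lapply(9:12, function(num) {
    e <- get("DATA", num)
    if (is.null(e)) stop("ABIF file lacks DATA", num, call. = FALSE)
    read_shorts(e)
  })
  channels <- strsplit(order_, "")[[1]]
  h <- matrix(0, nrow = length(peaks), ncol = 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (k in seq_len(4L)) h[, channels[k]] <- traces[[k]][peaks]
  TraceData(bases, h)
}

#' @rdname readAb1
#' @param trace A \code{\link{TraceData}}.
#' @export
writeAb1 <- function(trace, path) {
  bases <- trace@calledBases
  n <- nchar(bases)
  h <- round(trace@peakHeights)
  h[h > 32767] <- 32767
  shorts_raw <- function(x)
    writeBin(as.integer(x), raw(), size = 2, endian = "big")
  int4_raw <- function(x)
    writeBin(as.integer(x), raw(), size = 4, endian = "big")
  int2_raw <- function(x)
    writeBin(as.integer(x), raw(), size = 2, endian = "big")

  channels <- c("A", "C", "G", "T")
  payload <- list(
    list(name = "FWO_", number = 1L, type = 2L, elsize = 1L, nel = 4L,
         data = charToRaw("ACGT")),
    list(name = "PBAS", number = 2L, type = 2L, elsize = 1L, nel = n,
         data = charToRaw(bases)),
    list(name = "PLOC", number = 2L, type = 4L, elsize = 2L, nel = n,
         data = shorts_raw(seq_len(n) - 1L)))
  for (k in seq_len(4L))
    payload[[length(payload) + 1L]] <-
      list(name = "DATA", number = 8L + k, type = 4L, elsize = 2L, nel = n,
           data = shorts_raw(h[, channels[k]]))

  header_len <- 128L
  body <- raw(0)
  offsets <- integer(length(payload))
  for (i in seq_along(payload)) {
    offsets[i] <- header_len + length(body)
    body <- c(body, payload[[i]]$data)
  }
  dir_off <- header_len + length(body)
  dir <- raw(0)
  for (i in seq_along(payload)) {
    e <- payload[[i]]
    dsize <- length(e$data)
    entry <- c(charToRaw(e$name), int4_raw(e$number), int2_raw(e$type),
               int2_raw(e$elsize), int4_raw(e$nel), int4_raw(dsize),
               if (dsize <= 4L) c(e$data, raw(4L - dsize))
               else int4_raw(offsets[i]),
               int4_raw(0L))
    dir <- c(dir, entry)
  }
  header <- c(charToRaw("ABIF"), int2_raw(101L),
              charToRaw("tdir"), int4_raw(1L), int2_raw(1023L),
              int2_raw(28L), int4_raw(length(payload)),
              int4_raw(length(payload) * 28L), int4_raw(dir_off),
              int4_raw(0L))
  header <- c(header, raw(header_len - length(header)))
  writeBin(c(header, body, dir), path)
  invisible(path)
}

# ---- quantification ------------------------------------------------------

#' Map amplicon target positions to trace indices
#'
#' Aligns the trace's called bases to the amplicon (same aligner and
#' parameters as the NGS pipeline, both orientations) and maps each target
#' position to the corresponding called-base index.
#'
#' @param trace A \code{\link{TraceData}}.
#' @param spec An \code{\link{AmpliconSpec}}.
#' @param positions Forward-strand amplicon positions to map; defaults to
#'   the spec's targets.
#' @param params Alignment parameters.
#' @return Named integer vector (names = amplicon positions, values = trace
#'   indices). Errors when a requested position falls in an alignment gap.
#' @export
locateTarget <- function(trace, spec, positions = targetPositions(spec),
                         params = alignParams()) {
  aln <- alignRead(trace@calledBases, spec, params)
  if (aln$orientation != "forward")
    stop("trace aligns as reverse complement; flip it first", call. = FALSE)
  idx <- rep(NA_integer_, length(positions))
  ops <- aln$ops
  for (i in seq_len(nrow(ops))) {
    if (ops$op[i] %in% c("I", "D")) next
    rp <- ops$ref_pos[i]; len <- ops$len[i]
    sel <- which(positions >= rp & positions <= rp + len - 1L)
    idx[sel] <- ops$read_pos[i] + (positions[sel] - rp)
  }
  if (anyNA(idx))
    stop("target position(s) ",
         paste(positions[is.na(idx)], collapse = ","),
         " unmappable (alignment gap or uncovered)", call. = FALSE)
  names(idx) <- positions
  idx
}

#' Editing proportion at one trace position
#'
#' Two-channel proportion used for C-to-T quantification:
#' \code{100 * h(edited) / (h(edited) + h(target))} at the called position.
#'
#' @param trace A \code{\link{TraceData}}.
#' @param index Trace (called-base) index.
#' @param target_base,edited_base Channel letters, e.g. \code{"C"} and
#'   \code{"T"}.
#' @return Percentage in [0, 100].
#' @export
editProportion <- function(trace, index, target_base, edited_base) {
  h <- trace@peakHeights
  index <- .assert_scalar_int(index, "index", 1L)
  if (index > nrow(h)) stop("index beyond trace length", call. = FALSE)
  ht <- unname(h[index, target_base]); he <- unname(h[index, edited_base])
  if (ht + he <= 0)
    stop("both channels zero at trace index ", index, call. = FALSE)
  100 * he / (ht + he)
}

#' Call edits from a trace with a background noise threshold
#'
#' For each target the editing proportion is compared against a detection
#' threshold estimated from background positions: mean + 3 SD of the
#' edited-base channel proportion at positions where the trace agrees with
#' the reference and no editing is expected. Positions whose reference base
#' is the target or edited base are excluded from the background, as are
#' window positions and positions where the primary call mismatches the
#' reference.
#'
#' @param trace A \code{\link{TraceData}}.
#' @param spec An \code{\link{AmpliconSpec}}.
#' @param background_positions Optional forward-strand amplicon positions to
#'   use as background; chosen automatically when \code{NULL}.
#' @param min_background Minimum usable background positions (default 20).
#' @param params Alignment parameters.
#' @return data.frame with one row per target: \code{position},
#'   \code{target_base}, \code{edited_base}, \code{proportion_pct},
#'   \code{noise_threshold_pct}, \code{detected}.
#' @export
detectEdit <- function(trace, spec, background_positions = NULL,
                       min_background = 20L, params = alignParams()) {
  target_base <- if (guideStrand(spec) == "+") "C" else "G"
  edited_base <- expectedBase(spec)
  refch <- strsplit(as.character(amplicon(spec)), "")[[1]]
  tpos <- targetPositions(spec)
  wpos <- windowPositions(spec)

  if (is.null(background_positions)) {
    cand <- setdiff(seq_along(refch), wpos)
    cand <- cand[!refch[cand] %in% c(target_base, edited_base)]
    background_positions <- cand
  }
  map <- locateTarget(trace, spec,
                      positions = c(tpos, background_positions),
                      params = params)
  tidx <- map[seq_along(tpos)]
  bidx <- map[-seq_along(tpos)]
  bpos <- background_positions

  # keep background positions whose primary call agrees with the reference
  trch <- strsplit(trace@calledBases, "")[[1]]
  agree <- trch[bidx] == refch[bpos]
  bidx <- bidx[agree]; bpos <- bpos[agree]
  if (length(bidx) < min_background)
    stop("only ", length(bidx), " usable background positions (need >= ",
         min_background, ")", call. = FALSE)

  h <- trace@peakHeights
  primary_col <- match(refch[bpos], c("A", "C", "G", "T"))
  bg_prop <- 100 * h[bidx, edited_base] /
    (h[bidx, edited_base] + h[cbind(bidx, primary_col)])
  threshold <- mean(bg_prop) + 3 * stats::sd(bg_prop)

  prop <- vapply(tidx, function(i)
    editProportion(trace, i, target_base, edited_base), numeric(1))
  data.frame(position = tpos,
             target_base = target_base, edited_base = edited_base,
             proportion_pct = unname(prop),
             noise_threshold_pct = threshold,
             detected = unname(prop) > threshold,
             stringsAsFactors = FALSE)
}
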