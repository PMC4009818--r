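#' Construct a conservation track from per-position scores
#'
#' @param chrom chromosome-arm names.
#' @param pos 1-based positions.
#' @param score conservation scores in [0, 1].
#' @return a [ConservationTrack].
#' @export
conservationTrack <- function(chrom, pos, score) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(as.integer(pos), width = 1L))
  S4Vectors::mcols(gr)$score <- as.numeric(score)
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  obj <- new("ConservationTrack", scores = gr)
  validObject(obj)
  obj
}

## fast fixed-step WIG parser.  rtracklayer's generic WIG importer handles
## every dialect but needs ~10 s for a 270k-position track; this track is on
## the per-screen hot path, so fixedStep (the only dialect the pipeline
## emits or accepts) is parsed directly.
.readWig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (any(startsWith(lines, "variableStep")))
    stop("only fixedStep WIG is supported")
  hdrIdx <- which(startsWith(lines, "fixedStep"))
  if (!length(hdrIdx)) stop("no fixedStep declaration found in ", path)
  getField <- function(h, f, default = NA) {
    m <- regmatches(h, regexpr(paste0(f, "=[^ \t]+"), h))
    if (!length(m)) return(default)
    sub(paste0(f, "="), "", m)
  }
  blockEnd <- c(hdrIdx[-1] - 1L, length(lines))
  nVals <- blockEnd - hdrIdx
  if (any(nVals < 1L)) stop("fixedStep block without values in ", path)
  chromB <- vapply(lines[hdrIdx], getField, "", f = "chrom")
  startB <- as.integer(vapply(lines[hdrIdx], getField, "", f = "start"))
  stepB <- as.integer(vapply(lines[hdrIdx], getField, "",
                             f = "step", default = "1"))
  spanB <- vapply(lines[hdrIdx], getField, "", f = "span", default = "1")
  if (any(as.integer(spanB) != 1L))
    stop("fixedStep span > 1 is not supported")
  vals <- as.numeric(lines[unlist(Map(seq, hdrIdx + 1L, blockEnd))])
  pos <- unlist(Map(function(s, st, n) s + st * (seq_len(n) - 1L),
                    startB, stepB, nVals))
  chrom <- rep(chromB, nVals)
  list(chrom = chrom, pos = pos, score = vals)
}

#' Read a per-position conservation track
#'
#' Accepts fixed-step WIG (`fixedStep chrom=... start=... step=...` blocks,
#' one value per line) or a 3-column tab-delimited table with header
#' `chrom`, `pos`, `score`.  Positions absent from the track have no score;
#' the conservation filter treats absence as failing by default.
#'
#' @param path path to the track file.
#' @param format `"auto"` (by extension), `"wig"` or `"tsv"`.
#' @return a [ConservationTrack].
#' @importFrom utils read.delim
#' @export
readConservation <- function(path, format = c("auto", "wig", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "tsv"
  if (format == "wig") {
    d <- .readWig(path)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "score")
    if (!all(need %in% colnames(df)))
      stop("tabular conservation track needs columns chrom, pos, score")
    d <- list(chrom = as.character(df$chrom), pos = df$pos, score = df$score)
  }
  conservationTrack(d$chrom, d$pos, d$score)
}

#' Write a conservation track as fixed-step WIG
#'
#' Consecutive covered positions are emitted as one `fixedStep` block with
#' `step=1`.  Deterministic output (no date stamp).
#'
#' @param track a [ConservationTrack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeConservationWig <- function(track, path) {
  stopifnot(is(track, "ConservationTrack"))
  gr <- track@scores
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)
  score <- S4Vectors::mcols(gr)$score
  newBlock <- c(TRUE, diff(pos) != 1L | chrom[-1] != chrom[-length(chrom)])
  blockId <- cumsum(newBlock)
  starts <- pos[newBlock]
  chroms <- chrom[newBlock]
  valStr <- formatC(score, digits = 3, format = "f")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("track type=wiggle_0 name=conservation", con)
  sp <- split(valStr, blockId)
  for (b in seq_along(sp)) {
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                       chroms[b], starts[b]), con)
    writeLines(sp[[b]], con)
  }
  invisible(path)
}

#' Look up conservation scores at single bases
#'
#' Returns the score at exactly each queried base, or `NA` where the track
#' has no value (absence is a value the filters act on, not an error).
#'
#' @param track a [ConservationTrack].
#' @param chrom chromosome-arm names (recycled against `pos`).
#' @param pos 1-based positions.
#' @return numeric vector of scores in [0,1], `NA` where uncovered.
#' @export
conservationAt <- function(track, chrom, pos) {
  stopifnot(is(track, "ConservationTrack"))
  if (length(pos) == 0) return(numeric(0))
  q <- GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(as.integer(pos), width = 1L))
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(q, track@scores, select = "first"))
  out <- rep(NA_real_, length(q))
  ok <- !is.na(hit)
  out[ok] <- S4Vectors::mcols(track@scores)$score[hit[ok]]
  out
}

setMethod("show", "ConservationTrack", function(object) {
  cat(sprintf("ConservationTrack covering %d positions on %d sequence(s)\n",
              length(object@scores),
              length(unique(as.character(
                GenomicRanges::seqnames(object@scores))))))
  invisible(NULL)
})
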