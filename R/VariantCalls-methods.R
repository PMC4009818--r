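#' Construct a VariantCalls object
#'
#' Low-level constructor assembling per-sample SNV calls.  Most users obtain
#' `VariantCalls` objects from [readVariantCalls()] or the simulator.
#'
#' @param chrom chromosome-arm names.
#' @param pos 1-based positions.
#' @param ref,alt single upper-case bases; `alt != ref`.
#' @param qual Phred-scaled site qualities (QUAL), non-negative.
#' @param geno character matrix (variants x samples) of zygosity states
#'   (`"hom_ref"`, `"het"`, `"hom_alt"`, `"missing"`), or a vector for a
#'   single sample.
#' @param gq integer matrix/vector of genotype qualities (0..99, `NA` if
#'   absent); forced to `NA` wherever the genotype is missing.
#' @param depth optional integer matrix/vector of read depths.
#' @param samples sample names (colnames of `geno` take precedence).
#' @param role sample role tag: `"background"`, `"mutant"`, `"unrelated"`
#'   or `"unknown"`.
#' @param skipLog optional data.frame (reason, count) of dropped input rows.
#' @return a [VariantCalls] object.
#' @export
VariantCalls <- function(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         qual = numeric(0), geno = NULL, gq = NULL,
                         depth = NULL, samples = "sample1",
                         role = "unknown", skipLog = NULL) {
  n <- length(pos)
  asMat <- function(x, default) {
    if (is.null(x)) return(matrix(default, nrow = n, ncol = length(samples)))
    if (!is.matrix(x))
      x <- matrix(x, nrow = n,
                  ncol = if (n > 0) length(x) / n else length(samples))
    x
  }
  geno <- asMat(geno, "missing")
  if (is.null(colnames(geno))) colnames(geno) <- samples
  gq <- asMat(gq, NA_integer_)
  depth <- asMat(depth, NA_integer_)
  storage.mode(gq) <- "integer"
  storage.mode(depth) <- "integer"
  miss <- geno == "missing"
  gq[miss] <- NA_integer_
  depth[miss] <- NA_integer_
  dimnames(gq) <- dimnames(depth) <- dimnames(geno)
  sites <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L)
  )
  S4Vectors::mcols(sites)$ref <- as.character(ref)
  S4Vectors::mcols(sites)$alt <- as.character(alt)
  S4Vectors::mcols(sites)$qual <- as.numeric(qual)
  if (is.null(skipLog)) skipLog <- .emptySkipLog()
  new("VariantCalls", sites = sites, geno = geno, gq = gq, depth = depth,
      role = role, annotations = .emptyAnnotations(), annotated = FALSE,
      skipLog = skipLog)
}

.vcKeys <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

#' @rdname VariantCalls-class
#' @export
setMethod("variantKeys", "VariantCalls", function(x) {
  .vcKeys(as.character(GenomicRanges::seqnames(x@sites)),
          GenomicRanges::start(x@sites),
          S4Vectors::mcols(x@sites)$ref, S4Vectors::mcols(x@sites)$alt)
})

#' @rdname VariantCalls-class
#' @export
setMethod("variantSites", "VariantCalls", function(x) x@sites)

#' @rdname VariantCalls-class
#' @export
setMethod("refAllele", "VariantCalls",
          function(x) S4Vectors::mcols(x@sites)$ref)

#' @rdname VariantCalls-class
#' @export
setMethod("altAllele", "VariantCalls",
          function(x) S4Vectors::mcols(x@sites)$alt)

#' @rdname VariantCalls-class
#' @export
setMethod("qualScores", "VariantCalls",
          function(x) S4Vectors::mcols(x@sites)$qual)

#' @rdname VariantCalls-class
#' @export
setMethod("genotypes", "VariantCalls", function(x) x@geno)

#' @rdname VariantCalls-class
#' @export
setMethod("genotypeQuality", "VariantCalls", function(x) x@gq)

#' @rdname VariantCalls-class
#' @export
setMethod("readDepths", "VariantCalls", function(x) x@depth)

#' @rdname VariantCalls-class
#' @export
setMethod("sampleNames", "VariantCalls", function(x) colnames(x@geno))

#' @rdname VariantCalls-class
#' @export
setMethod("sampleRole", "VariantCalls", function(x) x@role)

#' @rdname VariantCalls-class
#' @export
setMethod("variantAnnotations", "VariantCalls", function(x) x@annotations)

#' @rdname VariantCalls-class
#' @export
setMethod("isAnnotated", "VariantCalls", function(x) x@annotated)

#' @rdname VariantCalls-class
#' @export
setMethod("skipLog", "VariantCalls", function(x) x@skipLog)

#' @rdname VariantCalls-class
#' @export
setMethod("length", "VariantCalls", function(x) length(x@sites))

#' @rdname VariantCalls-class
#' @param i integer or logical index over variants.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "VariantCalls", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) return(x)
  idx <- seq_along(x@sites)[i]
  ann <- x@annotations
  if (nrow(ann) > 0) {
    keep <- ann$variant %in% idx
    ann <- ann[keep, , drop = FALSE]
    ann$variant <- match(ann$variant, idx)
  }
  initialize(x,
    sites = x@sites[idx],
    geno = x@geno[idx, , drop = FALSE],
    gq = x@gq[idx, , drop = FALSE],
    depth = x@depth[idx, , drop = FALSE],
    annotations = ann)
})

setMethod("show", "VariantCalls", function(object) {
  cat(sprintf(
    "VariantCalls with %d variant%s, %d sample%s (role: %s)%s\n",
    length(object), if (length(object) == 1) "" else "s",
    ncol(object@geno), if (ncol(object@geno) == 1) "" else "s",
    object@role, if (object@annotated) ", annotated" else ""))
  if (length(object) > 0) {
    n <- min(5L, length(object))
    k <- variantKeys(object)[seq_len(n)]
    g <- object@geno[seq_len(n), 1L]
    cat(sprintf("  %s [%s]\n", k, g), sep = "")
    if (length(object) > n) cat("  ...\n")
  }
  if (nrow(object@skipLog) > 0) {
    cat("skip log:\n")
    for (r in seq_len(nrow(object@skipLog)))
      cat(sprintf("  %s: %d\n", object@skipLog$reason[r],
                  object@skipLog$count[r]))
  }
  invisible(NULL)
})

## internal: replace annotations, marking the object annotated
.setAnnotations <- function(x, ann) {
  initialize(x, annotations = ann, annotated = TRUE)
}

## internal: zygosity of the focal sample (default: first column)
.focalGeno <- function(x, sample = 1L) {
  if (is.character(sample)) {
    if (!sample %in% colnames(x@geno))
      stop("unknown sample: ", sample)
  }
  x@geno[, sample]
}
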