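#' Build the backfilled cross-sample genotype status matrix
#'
#' For every variant site observed in any sample, determines every sample's
#' status: `alt` if the sample carries the alternate allele (het or
#' hom_alt); `ref` if the sample's calls cover the position with a hom-ref
#' or other-allele call, or a supplied well-covered interval spans it;
#' `missing` otherwise.  Backfilling a `ref` requires positive evidence --
#' absence of a site from a sample's file is never taken as evidence of the
#' reference allele.
#'
#' @param calls a named list of single- or multi-sample [VariantCalls];
#'   element names override sample names where given.  Duplicate sample
#'   names are an identity error.
#' @param coverage optional named list of [GenomicRanges::GRanges] per
#'   sample marking intervals with adequate read depth (>= the caller's
#'   chosen minimum, conventionally 8x); sites inside them backfill as
#'   `ref` when the sample is not a carrier.
#' @return a [CohortMatrix].
#' @seealso [altFrequency()], [isUniqueTo()], [filterCohortUnique()]
#' @export
buildCohortMatrix <- function(calls, coverage = NULL) {
  stopifnot(length(calls) >= 1)
  perSample <- list()
  roles <- character(0)
  for (i in seq_along(calls)) {
    x <- calls[[i]]
    stopifnot(is(x, "VariantCalls"))
    nm <- sampleNames(x)
    if (!is.null(names(calls)) && nzchar(names(calls)[i]) &&
        ncol(x@geno) == 1L)
      nm <- names(calls)[i]
    for (s in seq_along(nm)) {
      if (nm[s] %in% names(perSample))
        stop("identity error: duplicate sample name '", nm[s], "'")
      perSample[[nm[s]]] <- list(x = x, col = s)
      roles[nm[s]] <- sampleRole(x)
    }
  }
  samples <- names(perSample)

  allKeys <- character(0)
  meta <- list()
  for (s in samples) {
    x <- perSample[[s]]$x
    k <- variantKeys(x)
    new <- !(k %in% allKeys)
    if (any(new)) {
      allKeys <- c(allKeys, k[new])
      meta[[s]] <- data.frame(
        key = k[new],
        chrom = as.character(GenomicRanges::seqnames(x@sites))[new],
        pos = GenomicRanges::start(x@sites)[new],
        ref = refAllele(x)[new], alt = altAllele(x)[new],
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  o <- order(meta$chrom, meta$pos, meta$ref, meta$alt)
  meta <- meta[o, , drop = FALSE]
  keys <- meta$key
  posKey <- paste(meta$chrom, meta$pos, sep = ":")

  status <- matrix(0L, nrow = length(keys), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (s in samples) {
    x <- perSample[[s]]$x
    col <- perSample[[s]]$col
    z <- x@geno[, col]
    k <- variantKeys(x)
    called <- z != "missing"
    ## positions this sample's file covers with a non-missing call
    coveredPos <- unique(paste(
      as.character(GenomicRanges::seqnames(x@sites))[called],
      GenomicRanges::start(x@sites)[called], sep = ":"))
    st <- as.integer(posKey %in% coveredPos)
    if (!is.null(coverage) && s %in% names(coverage)) {
      q <- GenomicRanges::GRanges(meta$chrom,
                                  IRanges::IRanges(meta$pos, width = 1L))
      covered <- suppressWarnings(IRanges::overlapsAny(q, coverage[[s]]))
      st[covered & st == 0L] <- 1L
    }
    carrierKeys <- k[z %in% c("het", "hom_alt")]
    st[match(carrierKeys, keys)] <- 2L
    status[, s] <- st
  }
  obj <- new("CohortMatrix", keys = keys,
             sites = {
               gr <- GenomicRanges::GRanges(
                 meta$chrom, IRanges::IRanges(meta$pos, width = 1L))
               S4Vectors::mcols(gr)$ref <- meta$ref
               S4Vectors::mcols(gr)$alt <- meta$alt
               gr
             },
             samples = samples, roles = roles, status = status,
             altCount = as.integer(rowSums(status == 2L)))
  validObject(obj)
  obj
}

#' @rdname CohortMatrix-class
#' @export
setMethod("cohortKeys", "CohortMatrix", function(x) x@keys)

#' @rdname CohortMatrix-class
#' @export
setMethod("cohortSamples", "CohortMatrix", function(x) x@samples)

#' @rdname CohortMatrix-class
#' @export
setMethod("cohortStatus", "CohortMatrix", function(x) x@status)

#' @rdname CohortMatrix-class
#' @export
setMethod("altCounts", "CohortMatrix",
          function(x) stats::setNames(x@altCount, x@keys))

#' @rdname CohortMatrix-class
#' @export
setMethod("length", "CohortMatrix", function(x) length(x@keys))

setMethod("show", "CohortMatrix", function(object) {
  cat(sprintf("CohortMatrix: %d sites x %d samples (%s)\n",
              length(object@keys), length(object@samples),
              paste(sprintf("%d %s", table(object@roles)[unique(object@roles)],
                            unique(object@roles)), collapse = ", ")))
  invisible(NULL)
})

#' Anonymous alternate-allele frequency at a site
#'
#' Returns the number of carrier samples and the carrier fraction among
#' samples with non-missing status at the site.  If every sample is missing
#' at the site the fraction is reported as `NA`.
#'
#' @param cohort a [CohortMatrix].
#' @param key a `chrom:pos:ref:alt` identity key (see [variantKeys()]).
#' @return list with elements `count` and `fraction`.
#' @export
altFrequency <- function(cohort, key) {
  i <- match(key, cohort@keys)
  if (is.na(i)) stop("unknown site: ", key)
  st <- cohort@status[i, ]
  nonMissing <- sum(st != 0L)
  count <- sum(st == 2L)
  list(count = as.integer(count),
       fraction = if (nonMissing == 0) NA_real_ else count / nonMissing)
}

#' Is a variant unique to one sample within the cohort?
#'
#' `TRUE` iff at most `maxOtherCarriers` samples other than `sample` carry
#' the alternate allele.  The queried sample must itself be a carrier.
#'
#' @param cohort a [CohortMatrix].
#' @param key a `chrom:pos:ref:alt` identity key.
#' @param sample carrier sample name.
#' @param maxOtherCarriers tolerated other carriers (default 0).
#' @return logical.
#' @export
isUniqueTo <- function(cohort, key, sample, maxOtherCarriers = 0L) {
  i <- match(key, cohort@keys)
  if (is.na(i)) stop("unknown site: ", key)
  if (!sample %in% cohort@samples) stop("unknown sample: ", sample)
  if (cohort@status[i, sample] != 2L)
    stop("precondition violated: ", sample, " does not carry ", key)
  others <- cohort@altCount[i] - 1L
  others <= maxOtherCarriers
}

#' Persist a cohort matrix as a tab-delimited sidecar file
#'
#' Writes the sites-by-samples status matrix (`alt` / `ref` / `missing`)
#' with site key columns, for offline inspection; no database server is
#' involved.
#'
#' @param cohort a [CohortMatrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCohortMatrix <- function(cohort, path) {
  words <- c("missing", "ref", "alt")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(cohort@sites)),
    pos = GenomicRanges::start(cohort@sites),
    ref = S4Vectors::mcols(cohort@sites)$ref,
    alt = S4Vectors::mcols(cohort@sites)$alt,
    alt_count = cohort@altCount,
    stringsAsFactors = FALSE)
  for (s in cohort@samples) df[[s]] <- words[cohort@status[, s] + 1L]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
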