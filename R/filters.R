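#' Create filter cascade settings
#'
#' @param minGQ minimum genotype quality, inclusive (default 75).
#' @param minQual minimum Phred site quality, inclusive (default 100).
#' @param zygosity allowed zygosity states for the focal sample
#'   (default `"het"`: mutants are sequenced as heterozygotes over the
#'   background chromosome).
#' @param classes qualifying effect classes (default NS/SS:
#'   nonsynonymous, nonsense, splice_site; nonsense is part of the NS set).
#' @param emsOnly keep only G->A / C->T transitions (default `TRUE`).
#' @param minConservation conservation threshold; kept variants must score
#'   strictly above it (default 0.5).
#' @param keepMissingConservation treat absent conservation scores as
#'   passing (default `FALSE`: absent scores fail, mirroring the
#'   shrinking-funnel strategy).
#' @param region `NA` for genome-wide, an arm name, or `c(arm, start, end)`
#'   with 1-based inclusive bounds.
#' @param maxCohortCount maximum tolerated number of other cohort carriers
#'   (default 0).
#' @param subtractBackground apply background-strain subtraction
#'   (default `TRUE`).
#' @return a [FilterSpec] object.
#' @export
filterSpec <- function(minGQ = 75L, minQual = 100, zygosity = "het",
                       classes = c("nonsynonymous", "nonsense",
                                   "splice_site"),
                       emsOnly = TRUE, minConservation = 0.5,
                       keepMissingConservation = FALSE,
                       region = NA_character_, maxCohortCount = 0L,
                       subtractBackground = TRUE) {
  obj <- new("FilterSpec", minGQ = as.integer(minGQ),
             minQual = as.numeric(minQual), zygosity = zygosity,
             classes = classes, emsOnly = isTRUE(emsOnly),
             minConservation = as.numeric(minConservation),
             keepMissingConservation = isTRUE(keepMissingConservation),
             region = as.character(region),
             maxCohortCount = as.integer(maxCohortCount),
             subtractBackground = isTRUE(subtractBackground))
  validObject(obj)
  obj
}

setMethod("show", "FilterSpec", function(object) {
  cat("FilterSpec:",
      sprintf("GQ>=%d QUAL>=%g", object@minGQ, object@minQual),
      sprintf("zygosity={%s}", paste(object@zygosity, collapse = ",")),
      sprintf("classes={%s}", paste(object@classes, collapse = ",")),
      if (object@emsOnly) "EMS-only" else NULL,
      sprintf("conservation>%g", object@minConservation),
      if (!is.na(object@region[1]))
        sprintf("region=%s", paste(object@region, collapse = ":")) else NULL,
      sprintf("maxOtherCarriers=%d", object@maxCohortCount), "\n")
  invisible(NULL)
})

#' Quality filter: GQ and QUAL thresholds
#'
#' Keeps records whose focal-sample genotype quality and site quality both
#' meet inclusive thresholds (`gq >= minGQ` and `qual >= minQual`).  A
#' record with a missing GQ on a non-missing genotype fails the filter and
#' is logged via a message, never an exception.
#'
#' @param x a [VariantCalls] object.
#' @param minGQ,minQual inclusive thresholds.
#' @param sample focal sample (index or name).
#' @return the surviving subset of `x`.
#' @export
filterQuality <- function(x, minGQ = 75L, minQual = 100, sample = 1L) {
  g <- x@gq[, sample]
  q <- qualScores(x)
  z <- .focalGeno(x, sample)
  noGQ <- is.na(g) & z != "missing"
  if (any(noGQ))
    message(sum(noGQ), " record(s) with missing GQ on a called genotype ",
            "failed the quality filter")
  keep <- !is.na(g) & g >= minGQ & !is.na(q) & q >= minQual
  x[keep]
}

#' Zygosity filter
#'
#' Keeps records whose focal-sample zygosity is in the allowed set.
#' Missing calls are never carriers and are always removed.
#'
#' @param x a [VariantCalls] object.
#' @param allowed allowed zygosity states (default `"het"`).
#' @param sample focal sample (index or name).
#' @return the surviving subset of `x`.
#' @export
filterZygosity <- function(x, allowed = "het", sample = 1L) {
  stopifnot(all(allowed %in% .ZYGOSITY))
  z <- .focalGeno(x, sample)
  x[z %in% setdiff(allowed, "missing")]
}

#' Effect-class filter
#'
#' Keeps records carrying at least one annotation whose class is in
#' `classes` (any-annotation rule: a record overlapping two genes qualifies
#' if either annotation qualifies).
#'
#' @param x an annotated [VariantCalls] object.
#' @param classes qualifying effect classes.
#' @return the surviving subset of `x`.
#' @export
filterClass <- function(x, classes = c("nonsynonymous", "nonsense",
                                       "splice_site")) {
  if (!isAnnotated(x))
    stop("records must be annotated before class filtering; ",
         "run annotateVariants() first")
  ann <- x@annotations
  keep <- sort(unique(ann$variant[ann$class %in% classes]))
  x[keep]
}

#' EMS transition filter
#'
#' Keeps records whose substitution is an EMS-signature G->A or C->T
#' transition (see [isEmsTransition()]).
#'
#' @param x a [VariantCalls] object.
#' @return the surviving subset of `x`.
#' @export
filterEms <- function(x) {
  if (length(x) == 0) return(x)
  x[isEmsTransition(refAllele(x), altAllele(x))]
}

#' Background-strain subtraction
#'
#' Removes every record whose identity key (chrom, pos, ref, alt) appears
#' with a carrier genotype (het or hom_alt, at any quality) in the
#' background strain.  Sites where the background has only missing data do
#' NOT cause removal; such records are kept and flagged in a
#' `background_missing` metadata column for auditability.
#'
#' @param x mutant [VariantCalls].
#' @param background background-strain [VariantCalls].
#' @return the surviving subset of `x`.
#' @export
subtractBackground <- function(x, background) {
  stopifnot(is(background, "VariantCalls"))
  if (length(x) == 0 || length(background) == 0) {
    S4Vectors::mcols(x@sites)$background_missing <- rep(FALSE, length(x))
    return(x)
  }
  carrier <- rowSums(background@geno == "het" |
                     background@geno == "hom_alt") > 0L
  allMissing <- rowSums(background@geno != "missing") == 0L
  bgKeys <- variantKeys(background)
  keys <- variantKeys(x)
  S4Vectors::mcols(x@sites)$background_missing <-
    keys %in% bgKeys[allMissing]
  x[!keys %in% bgKeys[carrier]]
}

#' Conservation filter
#'
#' Keeps records whose conservation score is strictly greater than
#' `minConservation` (default 0.5: moderately conserved).  Records without
#' a score are removed unless `keepMissing = TRUE`.
#'
#' @param x an annotated [VariantCalls] object.
#' @param minConservation strict lower bound.
#' @param keepMissing keep records with absent scores (default `FALSE`).
#' @return the surviving subset of `x`.
#' @export
filterConservation <- function(x, minConservation = 0.5,
                               keepMissing = FALSE) {
  if (!isAnnotated(x))
    stop("records must be annotated before conservation filtering")
  ann <- x@annotations
  cons <- rep(NA_real_, length(x))
  if (nrow(ann) > 0) {
    agg <- tapply(ann$conservation, ann$variant, function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    cons[as.integer(names(agg))] <- as.numeric(agg)
  }
  keep <- ifelse(is.na(cons), keepMissing, cons > minConservation)
  x[keep]
}

#' Region filter
#'
#' Restricts records to a chromosome arm, or to a 1-based inclusive
#' interval on an arm.  An arm not present in the data yields an empty
#' result with a warning, not an error.
#'
#' @param x a [VariantCalls] object.
#' @param region an arm name, or `c(arm, start, end)`.
#' @return the surviving subset of `x`.
#' @export
filterRegion <- function(x, region) {
  region <- as.character(region)
  arm <- region[1]
  chrom <- as.character(GenomicRanges::seqnames(x@sites))
  if (length(x) > 0 && !arm %in% chrom) {
    warning("region arm '", arm, "' matches no records")
  }
  keep <- chrom == arm
  if (length(region) == 3L) {
    pos <- GenomicRanges::start(x@sites)
    keep <- keep & pos >= as.integer(region[2]) & pos <= as.integer(region[3])
  }
  x[keep]
}

#' Cohort-uniqueness filter
#'
#' Keeps records carried by at most `maxOtherCarriers` samples other than
#' the focal sample across the whole cohort (background, other mutants and
#' unrelated genomes).  Records absent from the cohort matrix count zero
#' other carriers.
#'
#' @param x a [VariantCalls] object.
#' @param cohort a [CohortMatrix].
#' @param sample focal sample name in the cohort.
#' @param maxOtherCarriers tolerated other carriers (default 0).
#' @return the surviving subset of `x`.
#' @export
filterCohortUnique <- function(x, cohort, sample, maxOtherCarriers = 0L) {
  stopifnot(is(cohort, "CohortMatrix"))
  if (length(x) == 0) return(x)
  m <- match(variantKeys(x), cohortKeys(cohort))
  others <- rep(0L, length(x))
  hit <- !is.na(m)
  own <- if (sample %in% cohortSamples(cohort))
    as.integer(cohortStatus(cohort)[m[hit], sample] == 2L) else 0L
  others[hit] <- altCounts(cohort)[m[hit]] - own
  x[others <= maxOtherCarriers]
}

#' Run the full step-wise filter cascade for one strain
#'
#' Applies the screen's filters in their narrative order -- quality, coding
#' class, zygosity, background subtraction, EMS transition, conservation,
#' cohort uniqueness, region -- recording the surviving variant count and
#' distinct qualifying-gene count after each step.  Counts are
#' non-increasing down the cascade; because every filter is an independent
#' per-record predicate, the final record set does not depend on the order
#' (only intermediate counts do).
#'
#' For the two steps before the class filter, the gene count covers genes
#' with any coding-region variant (synonymous included, plus splice sites);
#' from the class step on, only `spec@classes` qualify.
#'
#' @param x an annotated [VariantCalls] for the focal strain.
#' @param spec a [FilterSpec].
#' @param background background-strain [VariantCalls], or `NULL` to skip
#'   subtraction.
#' @param cohort a [CohortMatrix], or `NULL` to skip the uniqueness step.
#' @param sample focal sample name (defaults to the first sample of `x`).
#' @return a list with `counts` (data.frame: step, variants, genes),
#'   `geneSets` (character vectors of qualifying genes per step) and
#'   `records` (the final [VariantCalls]).
#' @export
runCascade <- function(x, spec = filterSpec(), background = NULL,
                       cohort = NULL, sample = NULL) {
  stopifnot(is(spec, "FilterSpec"))
  if (is.null(sample)) sample <- sampleNames(x)[1]
  codingClasses <- c("synonymous", "nonsynonymous", "nonsense",
                     "splice_site")
  steps <- list(input = identity)
  steps$quality <- function(v) filterQuality(v, spec@minGQ, spec@minQual,
                                             sample)
  steps$class <- function(v) filterClass(v, spec@classes)
  steps$zygosity <- function(v) filterZygosity(v, spec@zygosity, sample)
  if (spec@subtractBackground && !is.null(background))
    steps$background <- function(v) subtractBackground(v, background)
  if (spec@emsOnly) steps$ems <- filterEms
  steps$conservation <- function(v)
    filterConservation(v, spec@minConservation,
                       spec@keepMissingConservation)
  if (!is.null(cohort))
    steps$cohort_unique <- function(v)
      filterCohortUnique(v, cohort, sample, spec@maxCohortCount)
  if (!is.na(spec@region[1]))
    steps$region <- function(v) filterRegion(v, spec@region)

  labels <- names(steps)
  counts <- data.frame(step = labels, variants = NA_integer_,
                       genes = NA_integer_, stringsAsFactors = FALSE)
  geneSets <- vector("list", length(steps))
  names(geneSets) <- labels
  cur <- x
  for (i in seq_along(steps)) {
    cur <- steps[[i]](cur)
    gcl <- if (labels[i] %in% c("input", "quality")) codingClasses
           else spec@classes
    genes <- names(collapseToGenes(cur, gcl))
    counts$variants[i] <- length(cur)
    counts$genes[i] <- length(genes)
    geneSets[[i]] <- genes
  }
  list(counts = counts, geneSets = geneSets, records = cur)
}
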