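#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges findOverlaps
NULL

## Zygosity states a genotype call can take. "missing" covers any call with a
## missing allele ("./." and friends): backfilling must distinguish it from ref.
.ZYGOSITY <- c("hom_ref", "het", "hom_alt", "missing")

## Functional effect classes assigned by the annotator.
.EFFECT_CLASSES <- c("synonymous", "nonsynonymous", "nonsense",
                     "splice_site", "intronic", "intergenic")

## Sample roles in a screen.
.ROLES <- c("background", "mutant", "unrelated", "unknown")

.BASES <- c("A", "C", "G", "T")

.emptyAnnotations <- function() {
  S4Vectors::DataFrame(
    variant = integer(0), gene_id = character(0), class = character(0),
    aa_change = character(0), conservation = numeric(0)
  )
}

.emptySkipLog <- function() {
  data.frame(reason = character(0), count = integer(0),
             stringsAsFactors = FALSE)
}

#' Per-sample biallelic SNV calls
#'
#' `VariantCalls` holds one biallelic single-nucleotide variant per row
#' (identified by chromosome arm, 1-based position, reference and alternate
#' base) together with per-sample genotype calls, Phred-scaled genotype
#' qualities (GQ, capped at 99), optional read depths, and the Phred-scaled
#' site quality (QUAL).  Multi-allelic input rows are split upstream into one
#' record per alternate allele; `(chrom, pos, ref, alt)` is the identity key
#' used for all cross-sample joins.
#'
#' @slot sites a width-1 [GenomicRanges::GRanges] with metadata columns
#'   `ref`, `alt` (single upper-case bases) and `qual` (site quality).
#' @slot geno character matrix (variants x samples) with values
#'   `"hom_ref"`, `"het"`, `"hom_alt"` or `"missing"`.
#' @slot gq integer matrix of genotype qualities in 0..99; `NA` where the
#'   genotype is missing or the input carried no GQ.
#' @slot depth integer matrix of read depths; `NA` when absent.
#' @slot role sample role tag for the file this object came from
#'   (`"background"`, `"mutant"`, `"unrelated"` or `"unknown"`).
#' @slot annotations a [S4Vectors::DataFrame] of effect annotations with
#'   columns `variant` (row index), `gene_id`, `class`, `aa_change`,
#'   `conservation`.
#' @slot annotated logical; `TRUE` once [annotateVariants()] has run.
#' @slot skipLog data.frame logging input rows/alleles dropped by the
#'   SNV-only model (reason, count).
#'
#' @seealso [readVariantCalls()], [annotateVariants()], [filterQuality()]
#' @export
setClass("VariantCalls",
  representation(
    sites = "GRanges",
    geno = "matrix",
    gq = "matrix",
    depth = "matrix",
    role = "character",
    annotations = "DataFrame",
    annotated = "logical",
    skipLog = "data.frame"
  )
)

setValidity("VariantCalls", function(object) {
  msg <- character(0)
  n <- length(object@sites)
  mc <- S4Vectors::mcols(object@sites)
  if (!all(c("ref", "alt", "qual") %in% colnames(mc)))
    return("sites must carry 'ref', 'alt' and 'qual' metadata columns")
  if (n > 0 && any(GenomicRanges::width(object@sites) != 1L))
    msg <- c(msg, "all sites must have width 1 (SNV-only model)")
  if (n > 0 && any(GenomicRanges::start(object@sites) < 1L))
    msg <- c(msg, "positions must be >= 1")
  if (!all(mc$ref %in% .BASES) || !all(mc$alt %in% .BASES))
    msg <- c(msg, "ref and alt must be single upper-case bases A/C/G/T")
  if (any(mc$ref == mc$alt))
    msg <- c(msg, "alt must differ from ref")
  if (any(mc$qual < 0, na.rm = TRUE))
    msg <- c(msg, "qual must be non-negative")
  if (anyDuplicated(paste(GenomicRanges::seqnames(object@sites),
                          GenomicRanges::start(object@sites),
                          mc$ref, mc$alt)))
    msg <- c(msg, "duplicate (chrom, pos, ref, alt) identity keys")
  for (m in c("geno", "gq", "depth")) {
    if (nrow(slot(object, m)) != n)
      msg <- c(msg, sprintf("'%s' must have one row per variant", m))
  }
  if (!identical(dim(object@geno), dim(object@gq)) ||
      !identical(dim(object@geno), dim(object@depth)))
    msg <- c(msg, "geno, gq and depth must share dimensions")
  if (is.null(colnames(object@geno)) && ncol(object@geno) > 0)
    msg <- c(msg, "geno must have sample names as colnames")
  if (n > 0 && !all(object@geno %in% .ZYGOSITY))
    msg <- c(msg, "genotypes must be hom_ref/het/hom_alt/missing")
  if (any(object@gq < 0L | object@gq > 99L, na.rm = TRUE))
    msg <- c(msg, "GQ must lie in 0..99 (Phred-scaled, capped at 99)")
  miss <- object@geno == "missing"
  if (any(!is.na(object@gq[miss])) || any(!is.na(object@depth[miss])))
    msg <- c(msg, "missing genotypes must have absent GQ and depth")
  if (length(object@role) != 1L || !object@role %in% .ROLES)
    msg <- c(msg, "role must be one of background/mutant/unrelated/unknown")
  ann <- object@annotations
  if (nrow(ann) > 0) {
    if (any(ann$variant < 1L | ann$variant > n))
      msg <- c(msg, "annotation variant indices out of range")
    if (!all(ann$class %in% .EFFECT_CLASSES))
      msg <- c(msg, "unknown effect class in annotations")
    if (any(ann$class == "intergenic" & !is.na(ann$gene_id)))
      msg <- c(msg, "intergenic annotations must not carry a gene_id")
    cons <- ann$conservation
    if (any(cons < 0 | cons > 1, na.rm = TRUE))
      msg <- c(msg, "conservation scores must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Gene models (one transcript per gene)
#'
#' Coding gene models read from GFF3: per gene an ordered set of CDS exons,
#' the strand, the genomic span, and the 2-bp intronic splice-site windows at
#' every internal exon junction.  A single transcript (the first mRNA chain
#' in the GFF3) represents each gene; the analysis is gene-level.
#'
#' @slot cds [GenomicRanges::GRangesList] of CDS exons per gene, in genomic
#'   order.
#' @slot strand named character vector, `"+"` or `"-"` per gene.
#' @slot spans [GenomicRanges::GRanges] of gene extents with `gene_id`.
#' @slot spliceWindows [GenomicRanges::GRanges] of 2-bp intronic windows
#'   flanking internal CDS junctions, with `gene_id`.
#' @seealso [readGeneModels()], [classifyVariants()]
#' @export
setClass("GeneModels",
  representation(
    cds = "GRangesList",
    strand = "character",
    spans = "GRanges",
    spliceWindows = "GRanges"
  )
)

setValidity("GeneModels", function(object) {
  msg <- character(0)
  ids <- names(object@cds)
  if (is.null(ids) || anyDuplicated(ids))
    return("cds must be named by unique gene ids")
  if (!identical(sort(ids), sort(names(object@strand))))
    msg <- c(msg, "strand must be named by the same gene ids")
  if (!all(object@strand %in% c("+", "-")))
    msg <- c(msg, "strand must be '+' or '-'")
  w <- sum(GenomicRanges::width(object@cds))
  if (any(w %% 3L != 0L))
    msg <- c(msg, "total CDS length must be divisible by 3 for every gene")
  if (length(msg)) msg else TRUE
})

#' Per-position conservation scores
#'
#' Sparse per-base conservation track (PhastCons-style scores in [0,1]).
#' Positions not covered by the track have no score: absence is a value the
#' conservation filter acts on.
#'
#' @slot scores a [GenomicRanges::GRanges] (width-1, sorted) with a numeric
#'   `score` metadata column in [0,1].
#' @seealso [readConservation()], [conservationAt()]
#' @export
setClass("ConservationTrack", representation(scores = "GRanges"))

setValidity("ConservationTrack", function(object) {
  sc <- S4Vectors::mcols(object@scores)$score
  if (is.null(sc)) return("scores GRanges must carry a 'score' column")
  if (any(sc < 0 | sc > 1, na.rm = TRUE))
    return("conservation scores must lie in [0, 1]")
  TRUE
})

#' Backfilled cross-sample genotype status matrix
#'
#' For every variant site observed in any sample of a cohort, the matrix
#' records for every sample one of three statuses: `alt` (the sample carries
#' the alternate allele, het or hom), `ref` (the sample's calls cover the
#' site with a hom-ref or other-allele call), or `missing` (no evidence).
#' This "backfilling" keeps honest frequency counts: absence of evidence is
#' never treated as evidence of the reference allele.
#'
#' @slot keys character vector of `chrom:pos:ref:alt` identity keys.
#' @slot sites width-1 [GenomicRanges::GRanges] with `ref`, `alt` columns.
#' @slot samples character vector of sample names.
#' @slot roles named character vector of sample roles.
#' @slot status integer matrix (sites x samples): 0 missing, 1 ref, 2 alt.
#' @slot altCount integer vector of per-site alt carrier counts.
#' @seealso [buildCohortMatrix()], [altFrequency()], [isUniqueTo()]
#' @export
setClass("CohortMatrix",
  representation(
    keys = "character",
    sites = "GRanges",
    samples = "character",
    roles = "character",
    status = "matrix",
    altCount = "integer"
  )
)

setValidity("CohortMatrix", function(object) {
  msg <- character(0)
  n <- length(object@keys)
  s <- length(object@samples)
  if (anyDuplicated(object@samples))
    msg <- c(msg, "sample names must be unique")
  if (!identical(dim(object@status), c(n, s)))
    msg <- c(msg, "status matrix must be |sites| x |samples| with no gaps")
  if (n * s > 0 && !all(object@status %in% 0:2))
    msg <- c(msg, "status codes must be 0 (missing), 1 (ref) or 2 (alt)")
  if (length(object@altCount) != n)
    msg <- c(msg, "altCount must have one entry per site")
  if (n > 0 && s > 0 &&
      !identical(object@altCount,
                 as.integer(rowSums(object@status == 2L))))
    msg <- c(msg, "altCount must equal the row-wise alt status count")
  if (length(msg)) msg else TRUE
})

#' Filter cascade settings
#'
#' Bundles every tunable threshold of the step-wise filtering strategy.
#' Defaults are the screen's operating point: genotype quality GQ >= 75 and
#' site quality QUAL >= 100 (inclusive), heterozygous calls only,
#' nonsynonymous/nonsense/splice-site effect classes, EMS G/C->A/T
#' transitions only, conservation strictly > 0.5, no other cohort carriers
#' allowed, and background subtraction on.
#'
#' @slot minGQ minimum genotype quality (0..99), inclusive.
#' @slot minQual minimum site QUAL, inclusive.
#' @slot zygosity allowed zygosities for the focal sample.
#' @slot classes qualifying effect classes.
#' @slot emsOnly keep only G->A / C->T transitions.
#' @slot minConservation conservation threshold (strict inequality).
#' @slot keepMissingConservation if `FALSE` (default) variants without a
#'   conservation score fail the conservation filter.
#' @slot region `NA`, an arm name, or `c(arm, start, end)` (1-based
#'   inclusive) as a character vector.
#' @slot maxCohortCount maximum number of other cohort carriers tolerated.
#' @slot subtractBackground apply background-strain subtraction.
#' @seealso [filterSpec()], [runCascade()]
#' @export
setClass("FilterSpec",
  representation(
    minGQ = "integer",
    minQual = "numeric",
    zygosity = "character",
    classes = "character",
    emsOnly = "logical",
    minConservation = "numeric",
    keepMissingConservation = "logical",
    region = "character",
    maxCohortCount = "integer",
    subtractBackground = "logical"
  )
)

setValidity("FilterSpec", function(object) {
  msg <- character(0)
  if (object@minGQ < 0L || object@minGQ > 99L)
    msg <- c(msg, "minGQ must lie in 0..99")
  if (object@minQual < 0)
    msg <- c(msg, "minQual must be >= 0")
  if (object@minConservation < 0 || object@minConservation > 1)
    msg <- c(msg, "minConservation must lie in [0, 1]")
  if (!all(object@zygosity %in% .ZYGOSITY))
    msg <- c(msg, "unknown zygosity state")
  if (!all(object@classes %in% .EFFECT_CLASSES))
    msg <- c(msg, "unknown effect class")
  if (object@maxCohortCount < 0L)
    msg <- c(msg, "maxCohortCount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Screen sample manifest
#'
#' Names the samples of one screen and their roles: the unmutagenized
#' background strain, the non-complementing mutant strains (one
#' complementation group), and unrelated cohort genomes used only for
#' frequency-based uniqueness filtering.  `region` optionally restricts the
#' analysis to a mapped chromosome arm.
#'
#' @slot background background sample name.
#' @slot mutants ordered mutant sample names (>= 1).
#' @slot unrelated unrelated cohort sample names.
#' @slot region mapped arm name, or `NA_character_` for genome-wide.
#' @seealso [screenManifest()], [readScreenManifest()]
#' @export
setClass("ScreenManifest",
  representation(
    background = "character",
    mutants = "character",
    unrelated = "character",
    region = "character"
  )
)

setValidity("ScreenManifest", function(object) {
  msg <- character(0)
  if (length(object@mutants) < 1L)
    msg <- c(msg, "at least one mutant strain is required")
  nm <- c(object@background, object@mutants, object@unrelated)
  if (anyDuplicated(nm))
    msg <- c(msg, "sample names must be disjoint across roles")
  if (length(msg)) msg else TRUE
})

#' Cascade report: gene counts per filter step and strain-support level
#'
#' Rows are cumulative filter steps; column k holds the number of genes with
#' at least one qualifying variant in each of at least k mutant strains.
#' Per-strain surviving variant counts per step are kept alongside.  Both
#' matrices are non-increasing down rows; gene counts are non-increasing in
#' k within a row.
#'
#' @slot steps ordered filter-step labels.
#' @slot geneCounts integer matrix (steps x k).
#' @slot variantCounts integer matrix (steps x strains).
#' @slot strains mutant strain names.
#' @seealso [buildCascadeReport()]
#' @export
setClass("CascadeReport",
  representation(
    steps = "character",
    geneCounts = "matrix",
    variantCounts = "matrix",
    strains = "character"
  )
)

setValidity("CascadeReport", function(object) {
  msg <- character(0)
  gc <- object@geneCounts
  if (nrow(gc) != length(object@steps))
    msg <- c(msg, "geneCounts must have one row per step")
  if (nrow(gc) > 1 && any(diff(gc) > 0))
    msg <- c(msg, "gene counts must be non-increasing down the cascade")
  if (ncol(gc) > 1 && any(t(diff(t(gc))) > 0))
    msg <- c(msg, "gene counts must be non-increasing as k grows")
  vc <- object@variantCounts
  if (nrow(vc) > 1 && any(diff(vc) > 0))
    msg <- c(msg, "variant counts must be non-increasing down the cascade")
  if (length(msg)) msg else TRUE
})

#' Synthetic screen configuration
#'
#' Parameters of the synthetic EMS screen generator.  Defaults emulate the
#' measured genome statistics of a fly screen at desk scale: a 2 Mb "3L" arm
#' plus a 1 Mb "2R" arm; natural background variation at 10,000 variants/Mbp
#' (within the ~8,100-11,000 autosomal range); an induced EMS rate of 0.6
#' mutations/kb per strain of which 80% are G/C->A/T transitions (literature
#' range 70-100%); three mutant strains over one background plus eight
#' unrelated genomes; and one planted causative gene on arm 3L carrying a
#' distinct nonsense lesion per mutant.
#'
#' @slot arms named numeric vector of arm lengths in bp.
#' @slot geneCount total number of genes placed across arms.
#' @slot meanGeneLength approximate mean genomic gene span in bp.
#' @slot backgroundDensity background variants per Mbp.
#' @slot emsRate induced mutations per kb per strain.
#' @slot transitionFraction fraction of induced mutations forced to be
#'   G->A / C->T.
#' @slot homFraction fraction of background variants that are homozygous.
#' @slot conservedCdsFraction fraction of each CDS covered by conserved
#'   (score > 0.5) blocks in the synthetic conservation track.
#' @slot nMutants number of mutant strains.
#' @slot nUnrelated number of unrelated cohort genomes.
#' @slot causativeArm arm carrying the planted causative gene.
#' @slot seed integer seed; all simulator randomness flows from it.
#' @seealso [simulationConfig()], [generateScreen()]
#' @export
setClass("SimulationConfig",
  representation(
    arms = "numeric",
    geneCount = "integer",
    meanGeneLength = "numeric",
    backgroundDensity = "numeric",
    emsRate = "numeric",
    transitionFraction = "numeric",
    homFraction = "numeric",
    conservedCdsFraction = "numeric",
    nMutants = "integer",
    nUnrelated = "integer",
    causativeArm = "character",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  if (is.null(names(object@arms)) || any(!nzchar(names(object@arms))))
    msg <- c(msg, "arms must be a named vector of lengths")
  if (any(object@arms <= 0))
    msg <- c(msg, "arm lengths must be positive")
  if (object@transitionFraction < 0 || object@transitionFraction > 1)
    msg <- c(msg, "transitionFraction must lie in [0, 1]")
  if (object@emsRate <= 0)
    msg <- c(msg, "emsRate must be positive")
  if (object@homFraction < 0 || object@homFraction > 1)
    msg <- c(msg, "homFraction must lie in [0, 1]")
  if (object@conservedCdsFraction < 0 || object@conservedCdsFraction > 1)
    msg <- c(msg, "conservedCdsFraction must lie in [0, 1]")
  if (object@nMutants < 1L)
    msg <- c(msg, "nMutants must be >= 1")
  if (object@nUnrelated < 0L)
    msg <- c(msg, "nUnrelated must be >= 0")
  if (!object@causativeArm %in% names(object@arms))
    msg <- c(msg, "causativeArm must name one of the arms")
  if (length(msg)) msg else TRUE
})

#' Bundled synthetic reference assets
#'
#' The simulator's reference genome, gene models and conservation track as
#' in-memory objects, with the generating configuration.
#'
#' @slot sequences [Biostrings::DNAStringSet] of arm sequences.
#' @slot genes a [GeneModels] object.
#' @slot conservation a [ConservationTrack].
#' @slot config the generating [SimulationConfig].
#' @seealso [generateReference()]
#' @export
setClass("ScreenReference",
  representation(
    sequences = "DNAStringSet",
    genes = "GeneModels",
    conservation = "ConservationTrack",
    config = "SimulationConfig"
  )
)
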