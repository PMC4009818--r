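## shared fixtures, built in code

## quick single-sample VariantCalls constructor
toyCalls <- function(chrom = "3L", pos, ref = "G", alt = "A", qual = 500,
                     zyg = "het", gq = 99L, depth = 30L,
                     sample = "s1", role = "mutant") {
  n <- length(pos)
  VariantCalls(chrom = rep(chrom, length.out = n), pos = pos,
               ref = rep(ref, length.out = n), alt = rep(alt, length.out = n),
               qual = rep(qual, length.out = n),
               geno = rep(zyg, length.out = n),
               gq = rep(gq, length.out = n),
               depth = rep(depth, length.out = n),
               samples = sample, role = role)
}

## hand-built 600 bp arm with two genes:
##  geneA (+): single CDS exon "ATG CAG GGA TGG TAA" at 101..115
##  geneB (-): two CDS exons; coding-strand CDS "ATG CAG GGA TGG TAA",
##             exon widths (transcription order) 9 + 6, intron 20 bp,
##             placed at 301..; genomic content is revcomp pieces
toyGenome <- function() {
  set.seed(99)
  arm <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
               collapse = "")
  cds <- "ATGCAGGGATGGTAA"
  substr(arm, 101, 115) <- cds
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  ## transcription pieces: p1 = first 9, p2 = last 6
  p1 <- substr(cds, 1, 9); p2 <- substr(cds, 10, 15)
  ## genomic ascending: exon1 = revcomp(p2) (width 6), exon2 = revcomp(p1)
  substr(arm, 301, 306) <- rc(p2)
  substr(arm, 327, 335) <- rc(p1)
  sequences <- Biostrings::DNAStringSet(c("3L" = arm))
  models <- geneModels(
    list(geneA = GenomicRanges::GRanges("3L", IRanges::IRanges(101, 115)),
         geneB = GenomicRanges::GRanges(
           "3L", IRanges::IRanges(c(301, 327), c(306, 335)))),
    strand = c(geneA = "+", geneB = "-"))
  track <- conservationTrack(rep("3L", 15), 101:115,
                             rep(c(0.9, 0.6, 0.97), 5))
  list(sequences = sequences, models = models, track = track)
}

## small but complete synthetic screen, generated once per test run
.screenCache <- new.env(parent = emptyenv())

smallConfig <- function(seed = 11L) {
  simulationConfig(arms = c("3L" = 3e5, "2R" = 1.5e5), geneCount = 34L,
                   nUnrelated = 2L, seed = seed)
}

smallScreen <- function() {
  if (is.null(.screenCache$scr)) {
    dir <- file.path(tempdir(), "emsscreen-small-fixture")
    .screenCache$scr <- generateScreen(smallConfig(), dir = dir)
  }
  .screenCache$scr
}

## the same screen with mutant/background records annotated
smallScreenAnnotated <- function() {
  if (is.null(.screenCache$ann)) {
    scr <- smallScreen()
    ref <- scr$reference
    recs <- c(list(background = scr$background), scr$mutants)
    .screenCache$ann <- lapply(recs, annotateVariants, models = ref@genes,
                               reference = ref@sequences,
                               track = ref@conservation)
  }
  .screenCache$ann
}

smallCohort <- function() {
  if (is.null(.screenCache$cohort)) {
    scr <- smallScreen()
    .screenCache$cohort <- buildCohortMatrix(
      c(list(background = scr$background), scr$mutants, scr$unrelated))
  }
  .screenCache$cohort
}

truthKeys <- function(truth) paste(truth$chrom, truth$pos, truth$ref,
                                   truth$alt, sep = ":")
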