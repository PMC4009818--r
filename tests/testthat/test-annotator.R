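test_that("EMS transition predicate matches guanine-alkylation chemistry", {
  expect_true(isEmsTransition("G", "A"))
  expect_true(isEmsTransition("C", "T"))
  expect_false(isEmsTransition("A", "G"))  # reverse direction
  expect_false(isEmsTransition("G", "T"))  # transversion
  expect_false(isEmsTransition("T", "C"))
  expect_error(isEmsTransition("G", "G"), "differ")
  expect_error(isEmsTransition("N", "A"), "single base")
})

## toy gene A: CDS "ATG CAG GGA TGG TAA" on + strand at 101..115
test_that("coding changes are translated and classified correctly", {
  g <- toyGenome()
  classify1 <- function(pos, ref, alt) {
    x <- toyCalls(pos = pos, ref = ref, alt = alt)
    ann <- classifyVariants(x, g$models, g$sequences)
    ann[ann$variant == 1L, ]
  }
  ## codon 2 CAG, C->T at its first base (pos 104) -> TAG stop
  nonsense <- classify1(104L, "C", "T")
  expect_identical(nonsense$class, "nonsense")
  expect_identical(nonsense$aa_change, "Q2*")
  ## codon 3 GGA, A->G at third base (pos 109) -> GGG, Gly->Gly
  syn <- classify1(109L, "A", "G")
  expect_identical(syn$class, "synonymous")
  expect_identical(syn$aa_change, "G3G")
  ## codon 2 CAG, C->G -> GAG, Gln->Glu
  ns <- classify1(104L, "C", "G")
  expect_identical(ns$class, "nonsynonymous")
  expect_identical(ns$aa_change, "Q2E")
  ## outside any gene
  expect_identical(classify1(50L,
    substring(as.character(g$sequences[[1]]), 50, 50),
    setdiff(c("A", "C", "G", "T"),
            substring(as.character(g$sequences[[1]]), 50, 50))[1])$class,
    "intergenic")
})

test_that("reference mismatches are consistency errors naming the site", {
  g <- toyGenome()
  base <- substring(as.character(g$sequences[[1]]), 104, 104)  # "C"
  wrong <- setdiff(c("A", "C", "G", "T"), base)[1]
  x <- toyCalls(pos = 104L, ref = wrong, alt = base)
  expect_error(classifyVariants(x, g$models, g$sequences),
               "reference mismatch at 3L:104")
})

test_that("splice-site and intronic windows follow the 2-bp rule", {
  g <- toyGenome()
  arm <- as.character(g$sequences[[1]])
  classAt <- function(pos) {
    ref <- substring(arm, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    ann <- classifyVariants(toyCalls(pos = pos, ref = ref, alt = alt),
                            g$models, g$sequences)
    ann$class[ann$gene_id %in% "geneB"]
  }
  ## geneB exons at 301..306 and 327..335; intron 307..326
  expect_identical(classAt(307L), "splice_site")
  expect_identical(classAt(308L), "splice_site")   # 2 bases into the intron
  expect_identical(classAt(309L), "intronic")      # 3rd intronic base
  expect_identical(classAt(326L), "splice_site")
  expect_identical(classAt(325L), "splice_site")
  expect_identical(classAt(324L), "intronic")
})

test_that("reverse-strand genes give the same amino-acid changes", {
  g <- toyGenome()
  ## geneB carries the same CDS as geneA on the minus strand.
  ## codon 2 base 1 (CDS pos 4, coding C) sits at genomic 335 - 3 = 332,
  ## genomic ref = G; coding C->T is genomic G->A.
  x <- toyCalls(pos = 332L, ref = "G", alt = "A")
  ann <- classifyVariants(x, g$models, g$sequences)
  annB <- ann[ann$gene_id %in% "geneB", ]
  expect_identical(annB$class, "nonsense")
  expect_identical(annB$aa_change, "Q2*")
  ## codon 3 base 3 (CDS pos 9) maps to genomic 335 - 8 = 327;
  ## coding A->G is genomic T->C
  x2 <- toyCalls(pos = 327L, ref = "T", alt = "C")
  ann2 <- classifyVariants(x2, g$models, g$sequences)
  ann2B <- ann2[ann2$gene_id %in% "geneB", ]
  expect_identical(ann2B$class, "synonymous")
  expect_identical(ann2B$aa_change, "G3G")
})

test_that("conservation lookups return the exact base score or NA", {
  g <- toyGenome()
  expect_identical(conservationAt(g$track, "3L", 101L), 0.9)
  expect_identical(conservationAt(g$track, "3L", 103L), 0.97)
  expect_true(is.na(conservationAt(g$track, "3L", 50L)))
  expect_true(is.na(conservationAt(g$track, "2R", 101L)))
})

test_that("fixed-step WIG blocks enumerate positions from start", {
  p <- tempfile(fileext = ".wig")
  writeLines(c("track type=wiggle_0",
               "fixedStep chrom=3L start=100 step=1",
               "0.1", "0.9"), p)
  tr <- readConservation(p)
  expect_identical(conservationAt(tr, "3L", 100L), 0.1)
  expect_identical(conservationAt(tr, "3L", 101L), 0.9)
  expect_true(is.na(conservationAt(tr, "3L", 102L)))
  ## tabular variant of the same data
  p2 <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tscore", "3L\t100\t0.1", "3L\t101\t0.9"), p2)
  tr2 <- readConservation(p2)
  expect_identical(conservationAt(tr2, "3L", c(100L, 101L)), c(0.1, 0.9))
})

test_that("WIG write/read round-trips a track", {
  scr <- smallScreen()
  track <- scr$reference@conservation
  p <- tempfile(fileext = ".wig")
  writeConservationWig(track, p)
  back <- readConservation(p)
  expect_identical(length(back@scores), length(track@scores))
  expect_identical(GenomicRanges::start(back@scores),
                   GenomicRanges::start(track@scores))
  expect_equal(back@scores$score, track@scores$score, tolerance = 1e-3)
})

test_that("annotation preserves record count and covers every record", {
  g <- toyGenome()
  ## zero records stay zero
  empty <- annotateVariants(toyCalls(pos = integer(0)), g$models,
                            g$sequences, g$track)
  expect_length(empty, 0L)
  expect_true(isAnnotated(empty))
  ## every record gets >= 1 annotation; count and order unchanged
  scr <- smallScreen()
  x <- scr$mutants$mut1[1:500]
  ann <- annotateVariants(x, scr$reference@genes, scr$reference@sequences,
                          scr$reference@conservation)
  expect_length(ann, 500L)
  expect_identical(variantKeys(ann), variantKeys(x))
  expect_setequal(unique(variantAnnotations(ann)$variant), 1:500)
})

test_that("a variant overlapping two genes is annotated for both", {
  set.seed(5)
  arm <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  cds <- "ATGCAGGGATGGTAA"
  substr(arm, 101, 115) <- cds
  sequences <- Biostrings::DNAStringSet(c("3L" = arm))
  ## two single-exon genes sharing the same CDS interval
  models <- geneModels(
    list(g1 = GenomicRanges::GRanges("3L", IRanges::IRanges(101, 115)),
         g2 = GenomicRanges::GRanges("3L", IRanges::IRanges(101, 115))),
    strand = c(g1 = "+", g2 = "+"))
  x <- toyCalls(pos = 104L, ref = "C", alt = "T")
  ann <- classifyVariants(x, models, sequences)
  expect_identical(nrow(ann), 2L)
  expect_setequal(ann$gene_id, c("g1", "g2"))
  expect_identical(unique(ann$class), "nonsense")
})

test_that("annotator classes agree with the simulator truth table", {
  scr <- smallScreen()
  ann <- smallScreenAnnotated()
  sev <- c("nonsense", "splice_site", "nonsynonymous", "synonymous",
           "intronic", "intergenic")
  for (m in names(scr$mutants)) {
    tt <- scr$truth[scr$truth$strain == m, ]
    A <- variantAnnotations(ann[[m]])
    idx <- match(truthKeys(tt), variantKeys(ann[[m]]))
    expect_false(anyNA(idx))
    got <- vapply(idx, function(i) {
      cl <- A$class[A$variant == i]
      cl[which.min(match(cl, sev))]
    }, character(1))
    expect_identical(got, tt$class)
  }
  ## in particular every planted nonsense lesion is annotated nonsense
  caus <- scr$truth[scr$truth$is_causative, ]
  expect_identical(unique(caus$class), "nonsense")
})
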