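test_that("identical configurations produce byte-identical screens", {
  cfg <- simulationConfig(arms = c("3L" = 1.2e5, "2R" = 6e4),
                          geneCount = 14L, nUnrelated = 1L, seed = 21L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generateScreen(cfg, dir = d1)
  generateScreen(cfg, dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("generated references respect the configuration", {
  scr <- smallScreen()
  cfg <- smallConfig()
  seqs <- scr$reference@sequences
  ## arm lengths match the config exactly
  expect_identical(stats::setNames(Biostrings::width(seqs), names(seqs)),
                   stats::setNames(as.integer(cfg@arms), names(cfg@arms)))
  models <- scr$reference@genes
  expect_length(geneIds(models), cfg@geneCount)
  ## every CDS is a clean ORF: starts ATG, ends on a stop, no internal stops
  cdsSeqs <- Biostrings::DNAStringSet(EMSscreen:::.cdsSequences(
    models, EMSscreen:::.armChars(seqs)))
  expect_true(all(Biostrings::width(cdsSeqs) %% 3 == 0))
  aa <- as.character(Biostrings::translate(cdsSeqs))
  expect_true(all(startsWith(aa, "M")))
  expect_true(all(endsWith(aa, "*")))
  expect_false(any(grepl("\\*.", aa)))   # no internal stop codons
  ## exons per gene within 3..5
  nEx <- S4Vectors::elementNROWS(cdsExons(models))
  expect_true(all(nEx >= 3 & nEx <= 5))
})

test_that("gene placement failure is a config error, not a crash", {
  cfg <- simulationConfig(arms = c("3L" = 2e4), geneCount = 40L,
                          causativeArm = "3L", seed = 1L)
  expect_error(generateReference(cfg), "config error")
})

test_that("background variant counts follow the Poisson density", {
  cfg <- simulationConfig(arms = c("3L" = 1e6), geneCount = 75L,
                          nUnrelated = 0L, seed = 33L)
  ref <- generateReference(cfg)
  bg <- generateBackground(cfg, ref)
  lambda <- 10000
  expect_lt(abs(length(bg) - lambda), 3 * sqrt(lambda))
  expect_identical(sampleRole(bg), "background")
  ## density 0: empty call set, header-only VCF
  cfg0 <- simulationConfig(arms = c("3L" = 1e5), geneCount = 8L,
                           backgroundDensity = 0, seed = 5L)
  bg0 <- generateBackground(cfg0, generateReference(cfg0))
  expect_length(bg0, 0L)
  p <- tempfile(fileext = ".vcf")
  writeVariantCalls(bg0, p)
  expect_true(all(startsWith(readLines(p), "#")))
})

test_that("mutant strains carry background plus calibrated EMS load", {
  scr <- smallScreen()
  cfg <- smallConfig()
  bgKeys <- variantKeys(scr$background)
  genomeKb <- sum(cfg@arms) / 1000
  for (m in names(scr$mutants)) {
    keys <- variantKeys(scr$mutants[[m]])
    ## the full background variant set rides along
    expect_true(all(bgKeys %in% keys))
    tt <- scr$truth[scr$truth$strain == m, ]
    ## every induced mutation is present and heterozygous
    idx <- match(truthKeys(tt), keys)
    expect_false(anyNA(idx))
    expect_true(all(genotypes(scr$mutants[[m]])[idx, 1] == "het"))
    ## induced count within 3-sigma Poisson bounds of rate x kb
    lambda <- cfg@emsRate * genomeKb
    expect_lt(abs(nrow(tt) - 1 - lambda), 3 * sqrt(lambda))
  }
})

test_that("transitionFraction = 1 makes every induced mutation G>A or C>T", {
  cfg <- simulationConfig(arms = c("3L" = 1.5e5), geneCount = 10L,
                          transitionFraction = 1, nMutants = 1L,
                          nUnrelated = 0L, seed = 13L)
  ref <- generateReference(cfg)
  bg <- generateBackground(cfg, ref)
  m <- mutagenize(cfg, ref, bg, 1L)
  induced <- m$truth[!m$truth$is_causative, ]
  expect_true(all(isEmsTransition(induced$ref, induced$alt)))
})

test_that("the realized transition fraction sits in a 99% binomial band", {
  scr <- smallScreen()
  cfg <- smallConfig()
  induced <- scr$truth[!scr$truth$is_causative, ]
  n <- nrow(induced)
  expect_gt(n, 500)
  obs <- sum(isEmsTransition(induced$ref, induced$alt))
  band <- stats::qbinom(c(0.005, 0.995), n, cfg@transitionFraction)
  expect_gte(obs, band[1])
  expect_lte(obs, band[2])
})

test_that("planted lesions are distinct, private and filter-proof", {
  scr <- smallScreen()
  caus <- scr$truth[scr$truth$is_causative, ]
  expect_identical(nrow(caus), length(scr$mutants))
  ## one shared gene, distinct positions
  expect_length(unique(caus$gene_id), 1L)
  expect_false(anyDuplicated(caus$pos) > 0)
  ck <- truthKeys(caus)
  ## absent from background and from every other sample
  expect_length(intersect(ck, variantKeys(scr$background)), 0L)
  for (u in scr$unrelated)
    expect_length(intersect(ck, variantKeys(u)), 0L)
  for (i in seq_along(scr$mutants)) {
    others <- ck[-i]
    expect_length(intersect(others, variantKeys(scr$mutants[[i]])), 0L)
  }
  ## satisfies every default filter predicate
  expect_true(all(isEmsTransition(caus$ref, caus$alt)))
  expect_true(all(conservationAt(scr$reference@conservation,
                                 caus$chrom, caus$pos) > 0.5))
  expect_identical(unique(caus$class), "nonsense")
  expect_identical(unique(caus$chrom), smallConfig()@causativeArm)
  for (i in seq_along(scr$mutants)) {
    keys <- variantKeys(scr$mutants[[i]])
    j <- match(ck[i], keys)
    expect_gte(genotypeQuality(scr$mutants[[i]])[j, 1], 75L)
    expect_gte(qualScores(scr$mutants[[i]])[j], 100)
  }
})

test_that("a screen directory holds one VCF per configured sample", {
  scr <- smallScreen()
  cfg <- smallConfig()
  vcfs <- list.files(scr$dir, pattern = "\\.vcf$")
  expect_length(vcfs, 1L + cfg@nMutants + cfg@nUnrelated)
  expect_true(all(c("manifest.yaml", "truth_table.tsv", "config.yaml",
                    "reference.fa", "genes.gff3", "conservation.wig")
                  %in% list.files(scr$dir)))
  ## truth table round-trips
  tt <- readTruthTable(file.path(scr$dir, "truth_table.tsv"))
  expect_identical(nrow(tt), nrow(scr$truth))
  expect_identical(sum(tt$is_causative), length(scr$mutants))
})

test_that("simulation configs validate their parameters", {
  expect_error(simulationConfig(transitionFraction = 1.5), "\\[0, 1\\]")
  expect_error(simulationConfig(emsRate = 0), "positive")
  expect_error(simulationConfig(causativeArm = "X"), "causativeArm")
  expect_error(simulationConfig(arms = c(100, 200)), "named")
})
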