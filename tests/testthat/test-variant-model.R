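test_that("phredToProb follows the Phred convention", {
  expect_identical(phredToProb(10), 0.1)
  expect_identical(phredToProb(0), 1)
  expect_equal(phredToProb(20), 0.01)
  expect_error(phredToProb(-1), "non-negative")
  ## strictly decreasing and multiplicative in q
  q <- seq(0, 90, by = 7.5)
  expect_true(all(diff(phredToProb(q)) < 0))
  expect_equal(phredToProb(q[-1] + 13), phredToProb(q[-1]) * phredToProb(13))
})

writeTestVcf <- function(bodyLines, samples = "s1") {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    bodyLines), path)
  path
}

test_that("multi-allelic rows split into per-allele records", {
  p <- writeTestVcf("3L\t100\t.\tG\tA,T\t200\t.\t.\tGT:GQ\t1/2:80")
  x <- readVariantCalls(p)
  expect_length(x, 2L)
  expect_identical(variantKeys(x), c("3L:100:G:A", "3L:100:G:T"))
  ## the 1/2 carrier is het for each split allele
  expect_identical(unname(genotypes(x)[, 1]), c("het", "het"))
  expect_identical(qualScores(x), c(200, 200))
})

test_that("split-allele genotypes map carriers per allele", {
  p <- writeTestVcf("3L\t100\t.\tG\tA,T\t200\t.\t.\tGT:GQ\t0/1:80")
  x <- readVariantCalls(p)
  ## carrier of allele 1 only: hom_ref for the other split allele
  expect_identical(unname(genotypes(x)[, 1]), c("het", "hom_ref"))
  p2 <- writeTestVcf("3L\t100\t.\tG\tA\t200\t.\t.\tGT:GQ\t./.:.")
  x2 <- readVariantCalls(p2)
  expect_identical(unname(genotypes(x2)[, 1]), "missing")
  expect_true(is.na(genotypeQuality(x2)[1, 1]))
})

test_that("non-SNV alleles are dropped and counted in the skip log", {
  p <- writeTestVcf(c("3L\t100\t.\tG\tGA\t200\t.\t.\tGT:GQ\t0/1:80",
                      "3L\t200\t.\tC\tT\t200\t.\t.\tGT:GQ\t0/1:80"))
  x <- readVariantCalls(p)
  expect_length(x, 1L)
  expect_identical(variantKeys(x), "3L:200:C:T")
  expect_identical(skipLog(x)$reason, "non_snv_allele")
  expect_identical(skipLog(x)$count, 1L)
})

test_that("malformed input raises informative errors", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS"), bad)
  expect_error(readVariantCalls(bad), "error")
  noSample <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), noSample)
  expect_error(readVariantCalls(noSample), "zero sample")
  expect_error(readVariantCalls(tempfile()), "no such file")
})

test_that("VCF write/read round-trips a simulated record set", {
  scr <- smallScreen()
  x <- scr$mutants$mut1
  p <- tempfile(fileext = ".vcf")
  writeVariantCalls(x, p)
  y <- readVariantCalls(p, role = "mutant")
  expect_identical(variantKeys(y), variantKeys(x))
  expect_equal(qualScores(y), qualScores(x))
  expect_identical(unname(genotypes(y)), unname(genotypes(x)))
  expect_identical(unname(genotypeQuality(y)), unname(genotypeQuality(x)))
  expect_identical(unname(readDepths(y)), unname(readDepths(x)))
})

test_that("writeVariantCalls handles edge cases", {
  p <- tempfile(fileext = ".vcf")
  writeVariantCalls(toyCalls(pos = integer(0)), p)
  lines <- readLines(p)
  expect_true(all(startsWith(lines, "#")))   # header-only
  ## one het record with the stated fields
  writeVariantCalls(toyCalls(pos = 42L, gq = 80L, qual = 120), p)
  body <- grep("^#", readLines(p), invert = TRUE, value = TRUE)
  f <- strsplit(body, "\t")[[1]]
  expect_identical(f[c(1, 2, 4, 5, 6)], c("3L", "42", "G", "A", "120"))
  expect_identical(f[10], "0/1:80:30")
  ## unsorted input is an ordering error
  unsorted <- toyCalls(pos = c(50L, 10L))
  expect_error(writeVariantCalls(unsorted, p), "ordering error")
})

test_that("tab-delimited export has one header plus one row per variant", {
  g <- toyGenome()
  pos <- c(103L, 140L, 200L)
  ref <- substring(as.character(g$sequences[[1]]), pos, pos)
  x <- toyCalls(pos = pos, ref = ref, alt = ifelse(ref == "A", "G", "A"))
  x <- annotateVariants(x, g$models, g$sequences, g$track)
  p <- tempfile(fileext = ".tsv")
  exportVariantTable(x, p)
  lines <- readLines(p)
  expect_length(lines, 4L)   # header + 3 rows
  df <- utils::read.delim(p, na.strings = ".")
  expect_identical(df$pos, c(103L, 140L, 200L))
  expect_identical(df$chrom, rep("3L", 3))
  expect_identical(colnames(df)[1:6],
                   c("chrom", "pos", "ref", "alt", "gene", "function_class"))
  ## empty export: header only
  exportVariantTable(annotateVariants(toyCalls(pos = integer(0)),
                                      g$models, g$sequences, g$track), p)
  expect_length(readLines(p), 1L)
})

test_that("BED export uses 0-based half-open width-1 intervals", {
  p <- tempfile(fileext = ".bed")
  exportBedTrack(toyCalls(pos = 100L), "t", p)
  lines <- readLines(p)
  expect_match(lines[1], "^track")
  expect_match(lines[2], "^3L\t99\t100")
  ## empty set: track line only
  exportBedTrack(toyCalls(pos = integer(0)), "empty", p)
  expect_length(readLines(p), 1L)
  ## widths all 1 and starts pos-1 on simulated records
  x <- smallScreen()$background
  x <- x[seq_len(10)]
  exportBedTrack(x, "ten", p)
  bed <- utils::read.table(p, skip = 1, sep = "\t")
  expect_identical(bed$V3 - bed$V2, rep(1L, 10))
  expect_identical(bed$V2, GenomicRanges::start(variantSites(x)) - 1L)
})

test_that("VariantCalls enforces its invariants", {
  expect_error(VariantCalls(chrom = "3L", pos = 1L, ref = "G", alt = "G",
                            qual = 1, samples = "s"), "differ")
  expect_error(VariantCalls(chrom = c("3L", "3L"), pos = c(5L, 5L),
                            ref = c("G", "G"), alt = c("A", "A"),
                            qual = c(1, 1), samples = "s"), "duplicate")
  x <- toyCalls(pos = 7L, zyg = "missing")
  expect_true(is.na(genotypeQuality(x)[1, 1]))  # missing => GQ absent
})
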