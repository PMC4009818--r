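test_that("quality thresholds are inclusive", {
  x <- toyCalls(pos = c(10L, 20L, 30L, 40L, 50L),
                gq = c(99L, 80L, 75L, 74L, 10L), qual = 200)
  kept <- filterQuality(x, 75, 100)
  expect_length(kept, 3L)
  expect_identical(GenomicRanges::start(variantSites(kept)),
                   c(10L, 20L, 30L))
  ## boundary pair: (75, 100) kept, (74, 500) removed
  b <- toyCalls(pos = c(1L, 2L), gq = c(75L, 74L), qual = c(100, 500))
  expect_identical(GenomicRanges::start(variantSites(filterQuality(b))), 1L)
})

test_that("missing GQ on a called genotype fails quietly with a log", {
  x <- toyCalls(pos = c(10L, 20L))
  x@gq[2, 1] <- NA_integer_
  expect_message(kept <- filterQuality(x, 75, 100), "missing GQ")
  expect_length(kept, 1L)
})

test_that("zygosity filter keeps only allowed states; missing never passes", {
  x <- toyCalls(pos = c(1L, 2L, 3L, 4L),
                zyg = c("het", "hom_alt", "hom_ref", "missing"))
  expect_identical(GenomicRanges::start(variantSites(filterZygosity(x))), 1L)
  both <- filterZygosity(x, c("het", "hom_alt"))
  expect_length(both, 2L)
  expect_length(filterZygosity(x, c("het", "hom_alt", "hom_ref",
                                    "missing")), 3L)
})

test_that("class filter uses the any-annotation rule", {
  g <- toyGenome()
  arm <- as.character(g$sequences[[1]])
  pos <- c(109L, 104L, 50L)   # synonymous (A->G), nonsense (C->T), intergenic
  x <- toyCalls(pos = pos, ref = substring(arm, pos, pos),
                alt = c("G", "T", if (substring(arm, 50, 50) == "A") "C"
                        else "A"))
  x <- annotateVariants(x, g$models, g$sequences, g$track)
  kept <- filterClass(x)
  expect_identical(GenomicRanges::start(variantSites(kept)), 104L)
  expect_length(filterClass(x, "synonymous"), 1L)
  expect_error(filterClass(toyCalls(pos = 1L)), "annotated")
})

test_that("EMS filter keeps exactly the G>A / C>T transitions", {
  x <- VariantCalls(chrom = rep("3L", 3), pos = c(1L, 2L, 3L),
                    ref = c("G", "T", "C"), alt = c("A", "C", "G"),
                    qual = rep(500, 3), geno = rep("het", 3),
                    gq = rep(99L, 3), samples = "s1")
  kept <- filterEms(x)
  expect_identical(variantKeys(kept), "3L:1:G:A")
})

test_that("background subtraction is key-based and missing-aware", {
  mut <- toyCalls(pos = c(10L, 20L, 30L))
  bg <- toyCalls(pos = c(10L, 30L), zyg = c("het", "missing"),
                 sample = "bg", role = "background")
  kept <- subtractBackground(mut, bg)
  ## 10 removed (carrier in background); 20 kept (absent); 30 kept (missing)
  expect_identical(GenomicRanges::start(variantSites(kept)), c(20L, 30L))
  flag <- S4Vectors::mcols(variantSites(kept))$background_missing
  expect_identical(flag, c(FALSE, TRUE))
  ## identities: empty background removes nothing; X minus X drops carriers
  expect_length(subtractBackground(mut, toyCalls(pos = integer(0))), 3L)
  expect_length(subtractBackground(mut, mut), 0L)
})

test_that("conservation filter uses a strict threshold and drops absences", {
  g <- toyGenome()
  scores <- seq(0, 0.9, by = 0.1)
  track <- conservationTrack(rep("3L", 10), 201:210, scores)
  arm <- as.character(g$sequences[[1]])
  pos <- 201:212   # two extra positions with no score
  x <- toyCalls(pos = pos, ref = substring(arm, pos, pos),
                alt = ifelse(substring(arm, pos, pos) == "A", "G", "A"))
  x <- annotateVariants(x, g$models, g$sequences, track)
  kept <- filterConservation(x, 0.5)
  expect_length(kept, 4L)   # 0.6, 0.7, 0.8, 0.9
  expect_identical(GenomicRanges::start(variantSites(kept)), 207:210)
  ## 0.5 itself fails (strict); absences kept only on request
  expect_false(206L %in% GenomicRanges::start(variantSites(kept)))
  expect_length(filterConservation(x, 0.5, keepMissing = TRUE), 6L)
})

test_that("region filter honours arms and inclusive intervals", {
  x <- VariantCalls(chrom = c("2R", "3L", "3L", "3L"),
                    pos = c(100L, 50L, 150L, 151L),
                    ref = rep("G", 4), alt = rep("A", 4), qual = rep(500, 4),
                    geno = rep("het", 4), gq = rep(99L, 4), samples = "s1")
  expect_length(filterRegion(x, "3L"), 3L)
  expect_length(filterRegion(x, "2R"), 1L)
  iv <- filterRegion(x, c("3L", 50, 150))
  expect_identical(GenomicRanges::start(variantSites(iv)), c(50L, 150L))
  expect_warning(empty <- filterRegion(x, "4"), "matches no records")
  expect_length(empty, 0L)
})

test_that("cohort-uniqueness filter tolerates up to maxOtherCarriers", {
  scr <- smallScreen()
  cohort <- smallCohort()
  ann <- smallScreenAnnotated()
  m1 <- ann$mut1
  u0 <- filterCohortUnique(m1, cohort, "mut1", 0L)
  u1 <- filterCohortUnique(m1, cohort, "mut1", 1L)
  expect_true(all(variantKeys(u0) %in% variantKeys(u1)))
  ## background-shared variants are never unique at max 0
  bgShared <- intersect(variantKeys(m1), variantKeys(scr$background))
  expect_length(intersect(variantKeys(u0), bgShared), 0L)
  ## strain-private induced mutations survive
  tt <- scr$truth[scr$truth$strain == "mut1" & scr$truth$is_causative, ]
  expect_true(truthKeys(tt) %in% variantKeys(u0))
})

test_that("every filter is idempotent and a subset operation", {
  ann <- smallScreenAnnotated()
  scr <- smallScreen()
  cohort <- smallCohort()
  x <- ann$mut2
  filters <- list(
    quality = function(v) filterQuality(v, 75, 100),
    class = function(v) filterClass(v),
    zygosity = function(v) filterZygosity(v),
    background = function(v) subtractBackground(v, ann$background),
    ems = filterEms,
    conservation = function(v) filterConservation(v),
    cohort = function(v) filterCohortUnique(v, cohort, "mut2"),
    region = function(v) filterRegion(v, "3L"))
  for (nm in names(filters)) {
    f <- filters[[nm]]
    once <- suppressMessages(f(x))
    twice <- suppressMessages(f(once))
    expect_true(all(variantKeys(once) %in% variantKeys(x)), info = nm)
    expect_identical(variantKeys(twice), variantKeys(once), info = nm)
  }
})

test_that("the final record set does not depend on filter order", {
  ann <- smallScreenAnnotated()
  cohort <- smallCohort()
  x <- ann$mut3
  filters <- list(
    function(v) filterQuality(v, 75, 100),
    function(v) filterClass(v),
    function(v) filterZygosity(v),
    function(v) subtractBackground(v, ann$background),
    filterEms,
    function(v) filterConservation(v),
    function(v) filterCohortUnique(v, cohort, "mut3"),
    function(v) filterRegion(v, "3L"))
  apply_all <- function(ord) {
    out <- x
    for (f in filters[ord]) out <- suppressMessages(suppressWarnings(f(out)))
    sort(variantKeys(out))
  }
  baseline <- apply_all(seq_along(filters))
  set.seed(202)
  for (r in 1:10)
    expect_identical(apply_all(sample(seq_along(filters))), baseline)
})

test_that("runCascade yields non-increasing counts and keeps the lesion", {
  scr <- smallScreen()
  ann <- smallScreenAnnotated()
  cohort <- smallCohort()
  spec <- filterSpec(region = "3L")
  for (m in names(scr$mutants)) {
    cc <- runCascade(ann[[m]], spec, background = ann$background,
                     cohort = cohort, sample = m)
    expect_true(all(diff(cc$counts$variants) <= 0))
    expect_true(all(diff(cc$counts$genes) <= 0))
    caus <- scr$truth[scr$truth$strain == m & scr$truth$is_causative, ]
    expect_true(truthKeys(caus) %in% variantKeys(cc$records))
  }
  ## degenerate input: zero variants yield zero counts, not an error
  empty <- annotateVariants(
    toyCalls(pos = integer(0), sample = "mutX", role = "mutant"),
    scr$reference@genes, scr$reference@sequences,
    scr$reference@conservation)
  cc0 <- runCascade(empty, spec, background = ann$background,
                    cohort = cohort, sample = "mutX")
  expect_true(all(cc0$counts$variants == 0L))
  expect_true(all(cc0$counts$genes == 0L))
})

test_that("filterSpec validates its thresholds", {
  expect_error(filterSpec(minGQ = 120), "0..99")
  expect_error(filterSpec(minConservation = 1.5), "\\[0, 1\\]")
  expect_error(filterSpec(zygosity = "hemizygous"), "zygosity")
})
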