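#' Convert a Phred-scaled quality score to an error probability
#'
#' A Phred score q corresponds to an error probability of `10^(-q/10)`: a
#' score of 10 means a 1-in-10 chance of error, 20 a 1-in-100 chance.
#' Genotype quality (GQ) and site quality (QUAL) are both on this scale.
#'
#' @param q numeric vector of non-negative Phred scores.
#' @return numeric vector of error probabilities in (0, 1].
#' @examples
#' phredToProb(10)  # 0.1
#' phredToProb(c(0, 20))
#' @export
phredToProb <- function(q) {
  if (!is.numeric(q) || any(is.na(q)) || any(q < 0))
    stop("Phred scores must be non-negative numbers")
  10^(-q / 10)
}

## locate the first structurally malformed body line for error reporting
.diagnoseVcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM\t", lines)
  if (!length(hdr)) {
    if (!length(lines) || !startsWith(lines[1], "##fileformat"))
      return("missing ##fileformat header line (line 1)")
    return("missing #CHROM column header line")
  }
  ncol0 <- length(strsplit(lines[hdr[1]], "\t", fixed = TRUE)[[1]])
  body <- seq(hdr[1] + 1L, length.out = length(lines) - hdr[1])
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != ncol0 ||
        is.na(suppressWarnings(as.integer(f[2]))))
      return(sprintf("malformed body line %d", i))
  }
  NA_character_
}

## zygosity of one allele index within GT strings, vectorized via a lookup
## over the distinct GT strings in the file
.gtToZygosity <- function(gtStrings, alleleIdx) {
  u <- unique(gtStrings)
  parsed <- strsplit(u, "[/|]")
  hasDot <- vapply(parsed, function(a) any(a == "." | a == ""), logical(1)) |
    u == "." | is.na(u)
  maxA <- max(alleleIdx)
  cnt <- matrix(0L, nrow = length(u), ncol = maxA)
  for (k in seq_len(maxA))
    cnt[, k] <- vapply(parsed, function(a) sum(a == as.character(k)),
                       integer(1))
  ui <- match(gtStrings, u)
  z <- character(length(gtStrings))
  nk <- cnt[cbind(ui, alleleIdx)]
  z[nk == 0L] <- "hom_ref"
  z[nk == 1L] <- "het"
  z[nk >= 2L] <- "hom_alt"
  z[hasDot[ui]] <- "missing"
  z
}

#' Read per-sample SNV calls from a VCF file
#'
#' Parses a VCF 4.x file and returns its biallelic SNV records.
#' Multi-allelic rows are split into one record per alternate allele (all
#' split records share the row's QUAL; a sample's genotype maps to the split
#' allele: carrier becomes het/hom for that allele, otherwise hom_ref; any
#' missing allele in GT makes the call `missing`).  Non-SNV alleles
#' (indels, symbolic alleles, multi-base REF) are dropped and counted in the
#' skip log, never silently.
#'
#' @param path path to a VCF file with at least one sample column.
#' @param role sample role tag recorded on the result.
#' @return a [VariantCalls] object; inspect dropped input with [skipLog()].
#' @seealso [writeVariantCalls()]
#' @importFrom VariantAnnotation readVcf scanVcfHeader
#' @export
readVariantCalls <- function(path, role = "unknown") {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- tryCatch(VariantAnnotation::scanVcfHeader(path), error = function(e) {
    d <- .diagnoseVcf(path)
    stop("VCF parse error in ", path,
         if (!is.na(d)) paste0(": ", d) else paste0(": ", conditionMessage(e)),
         call. = FALSE)
  })
  samp <- VariantAnnotation::samples(hdr)
  if (length(samp) == 0L)
    stop("VCF format error: ", path, " has zero sample columns")
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) {
      d <- .diagnoseVcf(path)
      stop("VCF parse error in ", path,
           if (!is.na(d)) paste0(": ", d) else paste0(": ", conditionMessage(e)),
           call. = FALSE)
    })
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  altsL <- VariantAnnotation::alt(vcf)
  nAlt <- S4Vectors::elementNROWS(altsL)
  rowIdx <- rep(seq_along(vcf), nAlt)
  altFlat <- as.character(unlist(altsL, use.names = FALSE))
  alleleIdx <- sequence(nAlt)
  refFlat <- refs[rowIdx]
  isSnv <- nchar(refFlat) == 1L & nchar(altFlat) == 1L &
    refFlat %in% .BASES & altFlat %in% .BASES
  nSkip <- sum(!isSnv)
  skip <- if (nSkip > 0)
    data.frame(reason = "non_snv_allele", count = as.integer(nSkip),
               stringsAsFactors = FALSE) else .emptySkipLog()
  keep <- which(isSnv)
  rowK <- rowIdx[keep]
  chrom <- as.character(GenomicRanges::seqnames(rr))[rowK]
  pos <- GenomicRanges::start(rr)[rowK]
  qual <- VariantAnnotation::qual(vcf)[rowK]
  gtRaw <- VariantAnnotation::geno(vcf)$GT
  gqRaw <- VariantAnnotation::geno(vcf)$GQ
  dpRaw <- VariantAnnotation::geno(vcf)$DP
  ns <- length(samp)
  nk <- length(keep)
  geno <- matrix("missing", nrow = nk, ncol = ns,
                 dimnames = list(NULL, samp))
  gq <- matrix(NA_integer_, nrow = nk, ncol = ns,
               dimnames = list(NULL, samp))
  dp <- gq
  if (nk > 0) {
    aIdx <- alleleIdx[keep]
    for (s in seq_len(ns)) {
      geno[, s] <- .gtToZygosity(gtRaw[rowK, s], aIdx)
      if (!is.null(gqRaw)) {
        v <- suppressWarnings(as.integer(gqRaw[rowK, s]))
        gq[, s] <- pmin(v, 99L)
      }
      if (!is.null(dpRaw))
        dp[, s] <- suppressWarnings(as.integer(dpRaw[rowK, s]))
    }
  }
  x <- VariantCalls(chrom = chrom, pos = pos, ref = refFlat[keep],
                    alt = altFlat[keep], qual = qual, geno = geno, gq = gq,
                    depth = dp, samples = samp, role = role, skipLog = skip)
  validObject(x)
  x
}

#' Write SNV calls to a VCF file
#'
#' Emits a minimal valid VCF 4.2 file with QUAL per site and GT/GQ/DP per
#' sample.  Records must be sorted by (chrom, pos).  The output carries no
#' date stamp, so identical inputs always produce byte-identical files
#' (required by the simulator's determinism contract).
#' `readVariantCalls(writeVariantCalls(x))` reproduces `x`.
#'
#' @param x a [VariantCalls] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readVariantCalls()]
#' @export
writeVariantCalls <- function(x, path) {
  stopifnot(is(x, "VariantCalls"))
  chrom <- as.character(GenomicRanges::seqnames(x@sites))
  pos <- GenomicRanges::start(x@sites)
  ## sorted = contiguous chrom blocks with non-decreasing positions; any
  ## consistent chromosome order is acceptable
  r <- rle(chrom)
  if (anyDuplicated(r$values) ||
      any(unlist(lapply(split(pos, factor(chrom, unique(chrom))),
                        is.unsorted))))
    stop("ordering error: records must be sorted by (chrom, pos)")
  samp <- sampleNames(x)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=EMSscreen",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp), collapse = "\t"))
  if (length(x) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gtMap <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  fmtInt <- function(m) {
    v <- as.character(m)
    v[is.na(v)] <- "."
    matrix(v, nrow = nrow(m))
  }
  gtM <- matrix(gtMap[x@geno], nrow = length(x))
  gqM <- fmtInt(x@gq)
  dpM <- fmtInt(x@depth)
  sampleCols <- vapply(seq_along(samp), function(s)
    paste(gtM[, s], gqM[, s], dpM[, s], sep = ":"), character(length(x)))
  qual <- qualScores(x)
  qualStr <- ifelse(is.na(qual), ".",
                    format(qual, trim = TRUE, scientific = FALSE, digits = 10))
  body <- paste(chrom, pos, ".", refAllele(x), altAllele(x), qualStr, ".",
                ".", "GT:GQ:DP", sep = "\t")
  body <- paste(body, apply(cbind(sampleCols), 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

.severityOrder <- c("nonsense", "splice_site", "nonsynonymous", "synonymous",
                    "intronic", "intergenic")

#' Export filtered variants as a tab-delimited table
#'
#' One header row, then one row per variant with columns `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `function_class`, `aa_change`, `zygosity`, `GQ`,
#' `QUAL`, `conservation`, `cohort_count`.  Multiple overlapping genes are
#' comma-joined; `function_class` is the most severe annotation class;
#' `cohort_count` is the number of other cohort carriers when a
#' [CohortMatrix] is supplied, `NA` otherwise.
#'
#' @param x an annotated [VariantCalls] object.
#' @param path output file path.
#' @param sample focal sample (index or name) for zygosity/GQ columns.
#' @param cohort optional [CohortMatrix] for the `cohort_count` column.
#' @return `path`, invisibly.
#' @importFrom utils write.table
#' @export
exportVariantTable <- function(x, path, sample = 1L, cohort = NULL) {
  stopifnot(is(x, "VariantCalls"))
  n <- length(x)
  ann <- x@annotations
  gene <- fclass <- aa <- rep(NA_character_, n)
  cons <- rep(NA_real_, n)
  if (nrow(ann) > 0) {
    sp <- split(seq_len(nrow(ann)), ann$variant)
    idx <- as.integer(names(sp))
    gene[idx] <- vapply(sp, function(i) {
      g <- unique(ann$gene_id[i])
      g <- g[!is.na(g)]
      if (length(g)) paste(g, collapse = ",") else NA_character_
    }, character(1))
    fclass[idx] <- vapply(sp, function(i) {
      cl <- ann$class[i]
      cl[which.min(match(cl, .severityOrder))]
    }, character(1))
    aa[idx] <- vapply(sp, function(i) {
      a <- ann$aa_change[i]
      a <- a[!is.na(a)]
      if (length(a)) paste(a, collapse = ",") else NA_character_
    }, character(1))
    cons[idx] <- vapply(sp, function(i)
      suppressWarnings(max(ann$conservation[i], na.rm = TRUE)), numeric(1))
    cons[is.infinite(cons)] <- NA_real_
  }
  cc <- rep(NA_integer_, n)
  if (!is.null(cohort)) {
    m <- match(variantKeys(x), cohortKeys(cohort))
    hit <- !is.na(m)
    focal <- sampleNames(x)[if (is.numeric(sample)) sample else
      match(sample, sampleNames(x))]
    own <- if (focal %in% cohortSamples(cohort))
      as.integer(cohortStatus(cohort)[m[hit], focal] == 2L) else 0L
    cc[hit] <- altCounts(cohort)[m[hit]] - own
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x@sites)),
    pos = GenomicRanges::start(x@sites),
    ref = refAllele(x), alt = altAllele(x),
    gene = gene, function_class = fclass, aa_change = aa,
    zygosity = .focalGeno(x, sample),
    GQ = x@gq[, sample], QUAL = qualScores(x),
    conservation = cons, cohort_count = cc,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

#' Export candidate genes as a tab-delimited table
#'
#' Gene-mode export of an [intersectStrains()] result: one row per candidate
#' gene with the number of supporting strains and each strain's supporting
#' variant keys.
#'
#' @param candidates result of [intersectStrains()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
exportGeneTable <- function(candidates, path) {
  df <- candidateTable(candidates)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export variants as a UCSC custom-track BED file
#'
#' Writes one width-1 interval per variant in 0-based half-open BED
#' coordinates (a variant at 1-based position p becomes the interval
#' [p-1, p)), preceded by a single `track name=...` line, suitable for
#' loading as a custom track in the UCSC genome browser.
#'
#' @param x a [VariantCalls] object, sorted by (chrom, pos).
#' @param trackName name for the track line.
#' @param path output file path.
#' @return `path`, invisibly.
#' @importFrom rtracklayer export
#' @export
exportBedTrack <- function(x, trackName, path) {
  stopifnot(is(x, "VariantCalls"))
  gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(x@sites),
    ranges = IRanges::IRanges(GenomicRanges::start(x@sites), width = 1L),
    name = variantKeys(x))
  line <- methods::new("BasicTrackLine", name = trackName)
  rtracklayer::export(gr, path, format = "bed", trackLine = line)
  invisible(path)
}
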