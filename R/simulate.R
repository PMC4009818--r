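#' Configure a synthetic EMS screen
#'
#' Defaults emulate the measured genome statistics of a three-strain fly
#' screen at desk scale (a 2 Mb "3L" arm plus a 1 Mb "2R" arm): natural
#' background variation at 10,000 variants/Mbp, an induced EMS load of 0.6
#' mutations/kb per strain with 80% G/C->A/T transitions, three mutant
#' strains over one background, eight unrelated genomes, and one causative
#' gene on 3L carrying a distinct nonsense lesion per mutant.  All
#' randomness flows from `seed`.
#'
#' @param arms named numeric vector of arm lengths (bp).
#' @param geneCount genes placed across arms (default 225: fly-like
#'   density of ~75 genes/Mb).
#' @param meanGeneLength approximate mean genomic gene span in bp (compact
#'   desk-scale genes; see the package vignette).
#' @param backgroundDensity background variants per Mbp.
#' @param emsRate induced mutations per kb per strain.
#' @param transitionFraction fraction of induced mutations that are
#'   G->A / C->T (literature range 0.7-1).
#' @param homFraction fraction of background variants drawn homozygous.
#' @param conservedCdsFraction fraction of each CDS exon covered by a
#'   conserved (score > 0.5) block in the synthetic conservation track.
#' @param nMutants number of mutant strains.
#' @param nUnrelated number of unrelated cohort genomes.
#' @param causativeArm arm carrying the planted causative gene.
#' @param seed integer seed.
#' @return a [SimulationConfig].
#' @export
simulationConfig <- function(arms = c("3L" = 2e6, "2R" = 1e6),
                             geneCount = 225L, meanGeneLength = 700,
                             backgroundDensity = 10000, emsRate = 0.6,
                             transitionFraction = 0.8, homFraction = 0.7,
                             conservedCdsFraction = 0.25, nMutants = 3L,
                             nUnrelated = 8L, causativeArm = "3L",
                             seed = 1L) {
  obj <- new("SimulationConfig", arms = arms,
             geneCount = as.integer(geneCount),
             meanGeneLength = as.numeric(meanGeneLength),
             backgroundDensity = as.numeric(backgroundDensity),
             emsRate = as.numeric(emsRate),
             transitionFraction = as.numeric(transitionFraction),
             homFraction = as.numeric(homFraction),
             conservedCdsFraction = as.numeric(conservedCdsFraction),
             nMutants = as.integer(nMutants),
             nUnrelated = as.integer(nUnrelated),
             causativeArm = causativeArm, seed = as.integer(seed))
  validObject(obj)
  obj
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    paste0("SimulationConfig: %s; %d genes; background %g/Mbp; ",
           "EMS %g/kb (%.0f%% transitions); %d mutants + %d unrelated; ",
           "causative on %s; seed %d\n"),
    paste(sprintf("%s=%g bp", names(object@arms), object@arms),
          collapse = ", "),
    object@geneCount, object@backgroundDensity, object@emsRate,
    100 * object@transitionFraction, object@nMutants, object@nUnrelated,
    object@causativeArm, object@seed))
  invisible(NULL)
})

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(.BASES, .BASES, paste0)), .BASES, paste0)),
  .STOP_CODONS)

## split cdsLen (a multiple of 3) into nEx exon widths, each >= 21 bp
.exonWidths <- function(cdsLen, nEx) {
  if (cdsLen < nEx * 21L) return(rep(cdsLen %/% nEx, nEx) +
    c(rep(1L, cdsLen %% nEx), rep(0L, nEx - cdsLen %% nEx)))
  repeat {
    w <- as.vector(stats::rmultinom(1, cdsLen, stats::runif(nEx) + 0.2))
    if (all(w >= 21L)) return(w)
  }
}

#' Generate a synthetic reference: genome, gene models, conservation
#'
#' Builds random arm sequences, places non-overlapping genes with 3-5 CDS
#' exons each (start and stop codons intact, no internal stops, total CDS
#' divisible by 3), and lays down a sparse conservation track over the
#' genic footprint: each CDS exon carries one conserved block
#' (scores 0.55-0.99) covering `conservedCdsFraction` of its length, the
#' rest of the exon and the introns score low (< 0.5).  Positions outside
#' genes are uncovered.  Identical configurations produce byte-identical
#' outputs.
#'
#' @param config a [SimulationConfig].
#' @param dir optional directory; when given, writes `reference.fa`,
#'   `genes.gff3` and `conservation.wig` there.
#' @return a [ScreenReference] (invisibly when `dir` is given).
#' @importFrom Biostrings DNAStringSet writeXStringSet reverseComplement
#'   DNAString
#' @importFrom stats rmultinom runif rpois rbinom rnorm rgamma
#' @export
generateReference <- function(config, dir = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  armNames <- names(config@arms)
  armSeqs <- lapply(config@arms, function(len)
    intToUtf8(utf8ToInt("ACGT")[sample.int(4L, len, replace = TRUE)]))

  nGenes <- stats::setNames(
    pmax(1L, round(config@geneCount * config@arms / sum(config@arms))),
    armNames)
  ## distribute rounding remainder onto the largest arm
  nGenes[which.max(config@arms)] <- nGenes[which.max(config@arms)] +
    (config@geneCount - sum(nGenes))

  cdsList <- list()
  strandOf <- character(0)
  consAcc <- list()   # per-gene conservation fragments, bound once at end
  geneCounter <- 0L
  for (arm in armNames) {
    len <- config@arms[[arm]]
    n <- nGenes[[arm]]
    nEx <- sample(3:5, n, replace = TRUE)
    intronLens <- lapply(nEx, function(k) sample(60:120, k - 1L,
                                                 replace = TRUE))
    intronTot <- vapply(intronLens, sum, integer(1))
    nCodons <- pmax(40L, round(stats::rnorm(
      n, (config@meanGeneLength - mean(intronTot)) / 3, 15)))
    cdsLens <- 3L * nCodons
    spans <- cdsLens + intronTot
    minGap <- 200L
    margin <- 1000L
    extra <- len - 2L * margin - sum(spans) - (n - 1L) * minGap
    if (extra <= n)
      stop("config error: cannot place ", n, " genes on a ", len,
           " bp arm without overlap; use fewer or shorter genes")
    offsets <- sort(floor(sort(stats::runif(n)) * extra))
    starts <- margin + offsets + c(0L, cumsum(spans[-n])) +
      (seq_len(n) - 1L) * minGap + 1L
    exStartsAll <- integer(0); exEndsAll <- integer(0)
    exPieces <- character(0)
    for (g in seq_len(n)) {
      geneCounter <- geneCounter + 1L
      gid <- sprintf("gene%04d", geneCounter)
      w <- .exonWidths(cdsLens[g], nEx[g])
      exStarts <- integer(nEx[g]); exEnds <- integer(nEx[g])
      p <- starts[g]
      for (e in seq_len(nEx[g])) {
        exStarts[e] <- p
        exEnds[e] <- p + w[e] - 1L
        p <- exEnds[e] + 1L +
          if (e < nEx[g]) intronLens[[g]][e] else 0L
      }
      st <- sample(c("+", "-"), 1)
      cds <- paste0("ATG",
                    paste(sample(.SENSE_CODONS, nCodons[g] - 2L,
                                 replace = TRUE), collapse = ""),
                    sample(.STOP_CODONS, 1))
      genomic <- if (st == "+") cds else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      exStartsAll <- c(exStartsAll, exStarts)
      exEndsAll <- c(exEndsAll, exEnds)
      exPieces <- c(exPieces,
                    substring(genomic, cumsum(c(1L, w[-nEx[g]])), cumsum(w)))
      cdsList[[gid]] <- GenomicRanges::GRanges(
        arm, IRanges::IRanges(exStarts, exEnds))
      strandOf[gid] <- st
      ## conservation: one conserved block per exon, low scores elsewhere
      gPos <- starts[g]:(p - 1L)
      gScore <- stats::runif(length(gPos), 0, 0.40)   # intron level
      for (e in seq_len(nEx[g])) {
        we <- w[e]
        blockLen <- max(1L, round(config@conservedCdsFraction * we))
        off <- sample.int(we - blockLen + 1L, 1) - 1L
        sc <- stats::runif(we, 0.05, 0.45)
        sc[(off + 1L):(off + blockLen)] <- stats::runif(blockLen, 0.55, 0.99)
        gScore[(exStarts[e] - starts[g] + 1L):(exEnds[e] - starts[g] + 1L)] <- sc
      }
      consAcc[[gid]] <- list(arm = arm, pos = gPos, score = gScore)
    }
    ## splice the exon sequences into the arm in one reconstruction pass
    armChar <- armSeqs[[arm]]
    gapPieces <- substring(armChar, c(1L, exEndsAll + 1L),
                           c(exStartsAll - 1L, len))
    merged <- character(2L * length(exPieces) + 1L)
    merged[seq(1L, by = 2L, length.out = length(exPieces) + 1L)] <- gapPieces
    merged[seq(2L, by = 2L, length.out = length(exPieces))] <- exPieces
    armSeqs[[arm]] <- paste(merged, collapse = "")
  }
  consChrom <- rep(vapply(consAcc, `[[`, "", "arm"),
                   vapply(consAcc, function(x) length(x$pos), integer(1)))
  consPos <- unlist(lapply(consAcc, `[[`, "pos"), use.names = FALSE)
  consScore <- unlist(lapply(consAcc, `[[`, "score"), use.names = FALSE)
  sequences <- Biostrings::DNAStringSet(unlist(armSeqs))
  names(sequences) <- armNames
  genes <- geneModels(cdsList, strandOf)
  track <- conservationTrack(consChrom, consPos, consScore)
  ref <- new("ScreenReference", sequences = sequences, genes = genes,
             conservation = track, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(sequences, file.path(dir, "reference.fa"))
    writeGeneModels(genes, file.path(dir, "genes.gff3"))
    writeConservationWig(track, file.path(dir, "conservation.wig"))
    return(invisible(ref))
  }
  ref
}

## Enumerate, per gene on the causative arm, the coding positions where a
## single EMS transition (coding-strand C->T or G->A) creates a stop codon,
## restricted to conserved (score > 0.5) bases; pick the best-endowed gene
## and assign one distinct position per mutant strain.
.planCausatives <- function(reference) {
  config <- reference@config
  set.seed(config@seed + 7L)
  models <- reference@genes
  armChars <- .armChars(reference@sequences)
  cdsSeqs <- .cdsSequences(models, armChars)
  arm <- config@causativeArm
  onArm <- geneIds(models)[as.character(GenomicRanges::seqnames(
    geneSpans(models))) == arm]
  code <- Biostrings::GENETIC_CODE
  perGene <- list()
  for (g in onArm) {
    seq <- cdsSeqs[[g]]
    nC <- nchar(seq) %/% 3L
    codons <- substring(seq, 3L * seq_len(nC) - 2L, 3L * seq_len(nC))
    internal <- seq_len(nC) > 1L & seq_len(nC) < nC
    caaLike <- which(codons %in% c("CAA", "CAG", "CGA") & internal)
    tgg <- which(codons == "TGG" & internal)
    ci <- c(caaLike, tgg, tgg)
    if (!length(ci)) next
    pic <- c(rep(1L, length(caaLike)), rep(2L, length(tgg)),
             rep(3L, length(tgg)))
    refC <- c(rep("C", length(caaLike)), rep("G", 2L * length(tgg)))
    altC <- c(rep("T", length(caaLike)), rep("A", 2L * length(tgg)))
    strandG <- models@strand[[g]]
    gpos <- .genomicPosition(models@cds[[g]], strandG, 3L * (ci - 1L) + pic)
    perGene[[g]] <- data.frame(
      gene_id = g, chrom = arm, pos = gpos,
      ref = if (strandG == "+") refC else unname(.COMPLEMENT[refC]),
      alt = if (strandG == "+") altC else unname(.COMPLEMENT[altC]),
      aa_change = paste0(unname(code[codons[ci]]), ci, "*"),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, unname(perGene))
  cons <- conservationAt(reference@conservation, all$chrom, all$pos)
  all <- all[!is.na(cons) & cons > 0.5, , drop = FALSE]
  candidates <- split(all, all$gene_id)
  candidates <- candidates[vapply(candidates, nrow, integer(1)) >=
                           config@nMutants]
  if (!length(candidates))
    stop("fixture error: no gene on ", arm, " offers ", config@nMutants,
         " conserved single-transition nonsense positions; ",
         "try another seed or longer genes")
  best <- names(candidates)[which.max(vapply(candidates, nrow, integer(1)))]
  df <- candidates[[best]]
  pick <- df[sample.int(nrow(df), config@nMutants), , drop = FALSE]
  pick$strain <- seq_len(config@nMutants)
  rownames(pick) <- NULL
  pick
}

## quality-score model: most calls pass the GQ>=75 & QUAL>=100 operating
## point (joint pass ~0.6, echoing the ~52% high-quality fraction a real
## screen shows), independent draws
.drawQuality <- function(n) {
  gqHigh <- stats::runif(n) < 0.75
  gq <- ifelse(gqHigh, sample(75:99, n, replace = TRUE),
               sample(0:74, n, replace = TRUE))
  qHigh <- stats::runif(n) < 0.8
  qual <- ifelse(qHigh, round(100 + stats::rgamma(n, 2, scale = 350), 1),
                 round(stats::runif(n, 0, 99.9), 1))
  list(gq = as.integer(gq), qual = qual,
       dp = stats::rpois(n, 40) + 1L)
}

.OTHER_ALT <- list(A = c("C", "G", "T"), C = c("A", "G"),
                   G = c("C", "T"), T = c("A", "C", "G"))
## for C and G the EMS partner (C->T, G->A) is excluded: non-transition
## draws must come from the remaining substitutions so the realized
## transition fraction is unbiased

.ALL_ALT <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))

.pickAlt <- function(ref, table) {
  if (!length(ref)) return(character(0))
  nOpt <- lengths(table)[ref]
  k <- 1L + floor(stats::runif(length(ref)) * nOpt)
  mat <- matrix(NA_character_, nrow = length(table), ncol = max(lengths(table)),
                dimnames = list(names(table), NULL))
  for (b in names(table)) mat[b, seq_along(table[[b]])] <- table[[b]]
  mat[cbind(match(ref, names(table)), k)]
}

## draw n distinct positions on an arm not flagged in `used`; optionally
## restricted to G/C bases
.drawPositions <- function(n, armChar, used, gcOnly = FALSE) {
  len <- nchar(armChar)
  out <- integer(0)
  while (length(out) < n) {
    cand <- sample.int(len, min(len, max(2L * (n - length(out)), 100L)))
    cand <- cand[!used[cand]]
    if (gcOnly) {
      b <- substring(armChar, cand, cand)
      cand <- cand[b == "G" | b == "C"]
    }
    cand <- unique(cand)
    take <- utils::head(cand, n - length(out))
    used[take] <- TRUE
    out <- c(out, take)
  }
  list(pos = out, used = used)
}

## natural-variation draw for one genome (background strain or an
## unrelated genome): Poisson(density x Mbp) SNVs per arm at uniform
## positions, het/hom mixture, quality mostly passing
.drawNaturalVariants <- function(config, reference, excludePos) {
  armChars <- .armChars(reference@sequences)
  out <- list()
  for (arm in names(config@arms)) {
    len <- config@arms[[arm]]
    n <- stats::rpois(1, config@backgroundDensity * len / 1e6)
    if (n == 0) next
    used <- logical(len)
    if (!is.null(excludePos[[arm]])) used[excludePos[[arm]]] <- TRUE
    d <- .drawPositions(n, armChars[[arm]], used)
    pos <- sort(d$pos)
    ref <- substring(armChars[[arm]], pos, pos)
    alt <- .pickAlt(ref, .ALL_ALT)
    zyg <- ifelse(stats::runif(n) < config@homFraction, "hom_alt", "het")
    out[[arm]] <- data.frame(chrom = arm, pos = pos, ref = ref, alt = alt,
                             zygosity = zyg, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  if (is.null(df))
    df <- data.frame(chrom = character(0), pos = integer(0),
                     ref = character(0), alt = character(0),
                     zygosity = character(0), stringsAsFactors = FALSE)
  df
}

## EMS mutation draw for one genome: Poisson(rate x kb) new het mutations;
## each is a forced G->A / C->T transition with probability
## transitionFraction, otherwise a uniform draw over the remaining
## substitutions at a random site
.drawEmsMutations <- function(config, reference, excludePos) {
  armChars <- .armChars(reference@sequences)
  totalKb <- sum(config@arms) / 1000
  nTotal <- stats::rpois(1, config@emsRate * totalKb)
  armOf <- sample(names(config@arms), nTotal, replace = TRUE,
                  prob = config@arms)
  out <- list()
  for (arm in names(config@arms)) {
    n <- sum(armOf == arm)
    if (n == 0) next
    len <- config@arms[[arm]]
    used <- logical(len)
    if (!is.null(excludePos[[arm]])) used[excludePos[[arm]]] <- TRUE
    nTrans <- stats::rbinom(1, n, config@transitionFraction)
    dT <- .drawPositions(nTrans, armChars[[arm]], used, gcOnly = TRUE)
    used <- dT$used
    dO <- .drawPositions(n - nTrans, armChars[[arm]], used)
    baseAt <- function(p) if (length(p)) substring(armChars[[arm]], p, p)
                          else character(0)
    posT <- dT$pos; posO <- dO$pos
    refT <- baseAt(posT)
    altT <- ifelse(refT == "G", "A", "T")
    refO <- baseAt(posO)
    altO <- .pickAlt(refO, .OTHER_ALT)
    df <- data.frame(chrom = arm, pos = c(posT, posO),
                     ref = c(refT, refO), alt = c(altT, altO),
                     stringsAsFactors = FALSE)
    out[[arm]] <- df[order(df$pos), , drop = FALSE]
  }
  df <- do.call(rbind, out)
  if (is.null(df)) df <- data.frame(chrom = character(0), pos = integer(0),
                                    ref = character(0), alt = character(0),
                                    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

## simulator-side classification of an induced mutation, used to fill the
## truth table's intended-class column; written as a plain exon walk,
## structurally different from the annotator's vectorized path
.truthClass <- function(chrom, pos, ref, alt, reference, cdsSeqs) {
  models <- reference@genes
  code <- Biostrings::GENETIC_CODE
  n <- length(pos)
  cls <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  aa <- rep(NA_character_, n)
  spans <- geneSpans(models)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  hit <- suppressWarnings(GenomicRanges::findOverlaps(
    q, spans, select = "first", ignore.strand = TRUE))
  for (i in which(!is.na(hit))) {
    g <- S4Vectors::mcols(spans)$gene_id[hit[i]]
    gene[i] <- g
    e <- models@cds[[g]]
    st <- models@strand[[g]]
    exS <- GenomicRanges::start(e); exE <- GenomicRanges::end(e)
    inExon <- which(pos[i] >= exS & pos[i] <= exE)
    if (!length(inExon)) {
      near <- any(abs(pos[i] - c(exE[-length(exE)] + 0.5,
                                 exS[-1] - 0.5)) <= 2)
      cls[i] <- if (near) "splice_site" else "intronic"
      if (cls[i] == "intronic") next
      next
    }
    j <- inExon[1]
    cdsPos <- if (st == "+") {
      sum(exE[seq_len(j - 1)] - exS[seq_len(j - 1)] + 1L) +
        (pos[i] - exS[j] + 1L)
    } else {
      later <- seq_len(length(exS)) > j
      sum(exE[later] - exS[later] + 1L) + (exE[j] - pos[i] + 1L)
    }
    ci <- (cdsPos + 2L) %/% 3L
    pic <- cdsPos - 3L * (ci - 1L)
    codon <- substr(cdsSeqs[[g]], 3L * ci - 2L, 3L * ci)
    altC <- if (st == "+") alt[i] else .COMPLEMENT[[alt[i]]]
    newCodon <- codon
    substr(newCodon, pic, pic) <- altC
    aaO <- code[[codon]]; aaN <- code[[newCodon]]
    cls[i] <- if (aaN == "*" && aaO != "*") "nonsense"
              else if (aaO == aaN) "synonymous" else "nonsynonymous"
    aa[i] <- paste0(aaO, ci, aaN)
  }
  data.frame(class = cls, gene_id = gene, aa_change = aa,
             stringsAsFactors = FALSE)
}

.dfToCalls <- function(df, qual, sampleName, role) {
  VariantCalls(chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
               qual = qual$qual, geno = df$zygosity, gq = qual$gq,
               depth = qual$dp, samples = sampleName, role = role)
}

.sortVariantDf <- function(df, armOrder) {
  df[order(match(df$chrom, armOrder), df$pos), , drop = FALSE]
}

## per-arm exclusion list from the causative plan
.planExclusions <- function(plan) {
  split(plan$pos, plan$chrom)
}

#' Generate the background strain's variant calls
#'
#' Places Poisson(`backgroundDensity` x arm-Mbp) SNVs per arm at uniform
#' positions with random alternate alleles, a het/hom genotype mixture and
#' GQ/QUAL draws under which most calls pass the default thresholds.
#' Positions reserved for causative lesions are excluded.
#'
#' @param config a [SimulationConfig].
#' @param reference a [ScreenReference] from [generateReference()].
#' @param plan internal causative plan; computed from the configuration
#'   when omitted (it is deterministic given the config seed).
#' @return a [VariantCalls] with sample `"background"`.
#' @export
generateBackground <- function(config, reference, plan = NULL) {
  stopifnot(is(reference, "ScreenReference"))
  if (is.null(plan)) plan <- .planCausatives(reference)
  set.seed(config@seed + 101L)
  df <- .drawNaturalVariants(config, reference, .planExclusions(plan))
  df <- .sortVariantDf(df, names(config@arms))
  .dfToCalls(df, .drawQuality(nrow(df)), "background", "background")
}

#' Mutagenize one strain over the background chromosome
#'
#' The mutant strain's calls contain every background variant (mutants are
#' heterozygous animals crossed over the original background chromosome)
#' plus Poisson(`emsRate` x genome-kb) new heterozygous EMS mutations, each
#' a G->A / C->T transition with probability `transitionFraction` (at a G/C
#' site) and otherwise a uniform draw over the remaining substitutions --
#' plus exactly one planted causative nonsense mutation in the designated
#' gene, at a conserved position distinct from every other strain's.  The
#' planted lesion is asserted at generation time to satisfy every default
#' filter predicate.
#'
#' @param config a [SimulationConfig].
#' @param reference a [ScreenReference].
#' @param background the background [VariantCalls] from
#'   [generateBackground()].
#' @param strainIndex which mutant (1-based).
#' @param plan internal causative plan (recomputed when omitted).
#' @return list with `calls` (a [VariantCalls], sample `mut<i>`) and
#'   `truth` (data.frame of induced mutations: chrom, pos, ref, alt,
#'   intended class, gene, aa change, is_causative).
#' @export
mutagenize <- function(config, reference, background, strainIndex,
                       plan = NULL) {
  stopifnot(is(reference, "ScreenReference"),
            strainIndex >= 1L, strainIndex <= config@nMutants)
  if (is.null(plan)) plan <- .planCausatives(reference)
  set.seed(config@seed + 1000L + strainIndex)
  bgPos <- split(GenomicRanges::start(background@sites),
                 as.character(GenomicRanges::seqnames(background@sites)))
  exclude <- .planExclusions(plan)
  for (arm in names(bgPos))
    exclude[[arm]] <- c(exclude[[arm]], bgPos[[arm]])
  ems <- .drawEmsMutations(config, reference, exclude)
  caus <- plan[plan$strain == strainIndex, , drop = FALSE]

  armChars <- .armChars(reference@sequences)
  cdsSeqs <- .cdsSequences(reference@genes, armChars)
  truthEms <- cbind(ems, .truthClass(ems$chrom, ems$pos, ems$ref, ems$alt,
                                     reference, cdsSeqs))
  truthEms$is_causative <- FALSE
  truthCaus <- data.frame(chrom = caus$chrom, pos = caus$pos,
                          ref = caus$ref, alt = caus$alt,
                          class = "nonsense", gene_id = caus$gene_id,
                          aa_change = caus$aa_change, is_causative = TRUE,
                          stringsAsFactors = FALSE)
  truth <- rbind(truthEms, truthCaus)
  truth$strain <- paste0("mut", strainIndex)
  truth <- .sortVariantDf(truth, names(config@arms))
  rownames(truth) <- NULL

  ## assemble the strain's VCF content: background copy + induced
  bgDf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(background@sites)),
    pos = GenomicRanges::start(background@sites),
    ref = refAllele(background), alt = altAllele(background),
    zygosity = background@geno[, 1], stringsAsFactors = FALSE)
  indDf <- truth[, c("chrom", "pos", "ref", "alt")]
  indDf$zygosity <- "het"
  df <- rbind(bgDf, indDf)
  qual <- .drawQuality(nrow(df))
  ## the causative call is a clean high-confidence het
  causRow <- nrow(bgDf) + which(truth$is_causative)
  qual$gq[causRow] <- 99L
  qual$qual[causRow] <- round(200 + stats::rgamma(length(causRow), 2,
                                                  scale = 300), 1)
  o <- order(match(df$chrom, names(config@arms)), df$pos)
  df <- df[o, , drop = FALSE]
  qual <- lapply(qual, `[`, o)
  calls <- .dfToCalls(df, qual, paste0("mut", strainIndex), "mutant")

  ## generation-time assertions: the planted lesion passes every default
  ## filter and is absent from the background
  ck <- .vcKeys(caus$chrom, caus$pos, caus$ref, caus$alt)
  stopifnot(
    isEmsTransition(caus$ref, caus$alt),
    conservationAt(reference@conservation, caus$chrom, caus$pos) > 0.5,
    !ck %in% variantKeys(background),
    all(qual$gq[match(ck, variantKeys(calls))] >= 75L),
    all(qualScores(calls)[match(ck, variantKeys(calls))] >= 100))
  list(calls = calls, truth = truth)
}

## an unrelated genome: freshly resampled natural variation plus its own
## EMS load, no causative lesion
.generateUnrelated <- function(config, reference, plan, j) {
  set.seed(config@seed + 20000L + j)
  nat <- .drawNaturalVariants(config, reference, .planExclusions(plan))
  natPos <- split(nat$pos, nat$chrom)
  exclude <- .planExclusions(plan)
  for (arm in names(natPos))
    exclude[[arm]] <- c(exclude[[arm]], natPos[[arm]])
  ems <- .drawEmsMutations(config, reference, exclude)
  if (nrow(ems)) ems$zygosity <- "het"
  df <- rbind(nat, ems[, c("chrom", "pos", "ref", "alt", "zygosity")])
  df <- .sortVariantDf(df, names(config@arms))
  .dfToCalls(df, .drawQuality(nrow(df)), paste0("unrel", j), "unrelated")
}

#' Generate a complete synthetic screen directory
#'
#' Writes reference FASTA, GFF3 gene models, fixed-step WIG conservation,
#' one VCF per sample (background, `nMutants` mutants, `nUnrelated`
#' unrelated genomes), a YAML manifest, the tab-delimited truth table of
#' every induced mutation, and a YAML echo of the configuration (including
#' the seed).  Identical configurations produce byte-identical directories.
#'
#' @param config a [SimulationConfig].
#' @param dir output directory (created if needed).
#' @return (invisibly) a list with the in-memory objects: `reference`,
#'   `background`, `mutants`, `unrelated`, `truth`, `manifest`, `plan`,
#'   and `dir`.
#' @seealso [runAnalyze()] for the matching analysis entry point.
#' @export
generateScreen <- function(config = simulationConfig(), dir = tempfile()) {
  stopifnot(is(config, "SimulationConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reference <- generateReference(config, dir = dir)
  plan <- .planCausatives(reference)
  background <- generateBackground(config, reference, plan)
  mutants <- list()
  truths <- list()
  for (i in seq_len(config@nMutants)) {
    m <- mutagenize(config, reference, background, i, plan)
    mutants[[paste0("mut", i)]] <- m$calls
    truths[[i]] <- m$truth
  }
  unrelated <- list()
  for (j in seq_len(config@nUnrelated))
    unrelated[[paste0("unrel", j)]] <- .generateUnrelated(config, reference,
                                                          plan, j)
  truth <- do.call(rbind, truths)
  manifest <- screenManifest("background", names(mutants),
                             names(unrelated), region = config@causativeArm)
  writeVariantCalls(background, file.path(dir, "background.vcf"))
  for (nm in names(mutants))
    writeVariantCalls(mutants[[nm]], file.path(dir, paste0(nm, ".vcf")))
  for (nm in names(unrelated))
    writeVariantCalls(unrelated[[nm]], file.path(dir, paste0(nm, ".vcf")))
  writeScreenManifest(manifest, file.path(dir, "manifest.yaml"))
  utils::write.table(
    truth[, c("strain", "chrom", "pos", "ref", "alt", "class", "gene_id",
              "aa_change", "is_causative")],
    file.path(dir, "truth_table.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  yaml::write_yaml(list(
    arms = as.list(config@arms), geneCount = config@geneCount,
    meanGeneLength = config@meanGeneLength,
    backgroundDensity = config@backgroundDensity, emsRate = config@emsRate,
    transitionFraction = config@transitionFraction,
    homFraction = config@homFraction,
    conservedCdsFraction = config@conservedCdsFraction,
    nMutants = config@nMutants, nUnrelated = config@nUnrelated,
    causativeArm = config@causativeArm, seed = config@seed),
    file.path(dir, "config.yaml"))
  invisible(list(dir = dir, reference = reference, plan = plan,
                 background = background, mutants = mutants,
                 unrelated = unrelated, truth = truth, manifest = manifest))
}

#' Read a simulator truth table
#'
#' @param path path to `truth_table.tsv` in a screen directory.
#' @return data.frame of induced mutations with intended classes and the
#'   `is_causative` flag.
#' @export
readTruthTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(is_causative = "logical"))
}
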