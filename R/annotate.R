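#' Is a substitution an EMS-signature transition?
#'
#' EMS alkylates guanine, inducing predominantly G->A (and, on the other
#' strand, C->T) transitions.  Vectorized over substitutions.
#'
#' @param ref,alt single upper-case bases, `alt != ref`.
#' @return logical vector: `TRUE` iff (ref, alt) is (G, A) or (C, T).
#' @examples
#' isEmsTransition("G", "A")  # TRUE
#' isEmsTransition(c("A", "G"), c("G", "T"))  # FALSE FALSE
#' @export
isEmsTransition <- function(ref, alt) {
  if (!all(ref %in% .BASES) || !all(alt %in% .BASES))
    stop("ref and alt must be single bases A/C/G/T")
  if (any(ref == alt)) stop("alt must differ from ref")
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## map CDS coordinates (1-based, transcription order) of coding hits.
## exons in genomic order; for "-" genes transcription runs right-to-left.
.cdsPositions <- function(exons, strand, pos) {
  s <- GenomicRanges::start(exons)
  e <- GenomicRanges::end(exons)
  w <- e - s + 1L
  j <- findInterval(pos, s)          # exon index containing pos (genomic)
  if (strand == "+") {
    before <- c(0L, cumsum(w))[j]
    before + (pos - s[j] + 1L)
  } else {
    wTx <- rev(w)                    # transcription order widths
    jTx <- length(w) - j + 1L
    before <- c(0L, cumsum(wTx))[jTx]
    before + (e[j] - pos + 1L)
  }
}

## inverse: genomic position of a 1-based CDS coordinate
.genomicPosition <- function(exons, strand, cdsPos) {
  s <- GenomicRanges::start(exons)
  e <- GenomicRanges::end(exons)
  w <- e - s + 1L
  if (strand == "+") {
    cum <- c(0L, cumsum(w))
    j <- findInterval(cdsPos - 1L, cum, rightmost.closed = FALSE)
    s[j] + (cdsPos - cum[j] - 1L)
  } else {
    wTx <- rev(w)
    cum <- c(0L, cumsum(wTx))
    jTx <- findInterval(cdsPos - 1L, cum)
    j <- length(w) - jTx + 1L
    e[j] - (cdsPos - cum[jTx] - 1L)
  }
}

#' Classify variant functional effects against gene models
#'
#' Re-implements variant effect prediction for biallelic SNVs: one
#' annotation per overlapping gene.  Coding positions are translated with
#' the standard genetic code on the coding strand; a change producing a stop
#' codon is `nonsense`, the same amino acid `synonymous`, otherwise
#' `nonsynonymous`; a position within the 2 intronic bases flanking an
#' internal CDS exon junction is `splice_site`; other positions inside a
#' gene span are `intronic`; variants overlapping no gene get a single
#' `intergenic` annotation.  Amino-acid changes are reported as e.g.
#' `"Q23*"`.
#'
#' @param x a [VariantCalls] object.
#' @param models a [GeneModels] object.
#' @param reference a named [Biostrings::DNAStringSet] of arm sequences.
#'   The reference base at each site must equal the record's `ref` (checked;
#'   a mismatch is a consistency error naming the site).
#' @return a [S4Vectors::DataFrame] with columns `variant` (row index in
#'   `x`), `gene_id`, `class`, `aa_change`.
#' @seealso [annotateVariants()]
#' @importFrom Biostrings GENETIC_CODE
#' @export
classifyVariants <- function(x, models, reference) {
  stopifnot(is(x, "VariantCalls"), is(models, "GeneModels"))
  n <- length(x)
  if (n == 0) return(.emptyAnnotations()[, 1:4])
  chrom <- as.character(GenomicRanges::seqnames(x@sites))
  pos <- GenomicRanges::start(x@sites)
  ref <- refAllele(x)
  alt <- altAllele(x)
  armChars <- .armChars(reference)
  genomeBase <- rep(NA_character_, n)
  for (arm in unique(chrom)) {
    i <- chrom == arm
    if (!arm %in% names(armChars))
      stop("variants on unknown sequence: ", arm)
    genomeBase[i] <- substring(armChars[[arm]], pos[i], pos[i])
  }
  bad <- which(genomeBase != ref)
  if (length(bad))
    stop("reference mismatch at ", variantKeys(x)[bad[1]],
         " (reference has ", genomeBase[bad[1]], ")")

  sites <- GenomicRanges::granges(x@sites)
  cdsFlat <- unlist(models@cds, use.names = FALSE)
  cdsGene <- rep(geneIds(models), S4Vectors::elementNROWS(models@cds))
  covHits <- GenomicRanges::findOverlaps(sites, cdsFlat, ignore.strand = TRUE)
  spliceHits <- GenomicRanges::findOverlaps(sites, models@spliceWindows,
                                            ignore.strand = TRUE)
  spanHits <- GenomicRanges::findOverlaps(sites, models@spans,
                                          ignore.strand = TRUE)

  out <- list()
  ## --- coding annotations -------------------------------------------------
  if (length(covHits)) {
    vi <- S4Vectors::queryHits(covHits)
    gi <- cdsGene[S4Vectors::subjectHits(covHits)]
    cdsSeqs <- .cdsSequences(models, armChars)
    cp <- integer(length(vi))
    for (g in unique(gi)) {
      sel <- gi == g
      cp[sel] <- .cdsPositions(models@cds[[g]], models@strand[[g]], pos[vi][sel])
    }
    strandG <- models@strand[gi]
    codonIdx <- (cp + 2L) %/% 3L
    posInCodon <- cp - 3L * (codonIdx - 1L)
    codon <- substring(cdsSeqs[gi], 3L * codonIdx - 2L, 3L * codonIdx)
    altC <- ifelse(strandG == "+", alt[vi], .COMPLEMENT[alt[vi]])
    refC <- ifelse(strandG == "+", ref[vi], .COMPLEMENT[ref[vi]])
    if (any(substr(codon, posInCodon, posInCodon) != refC))
      stop("internal error: CDS sequence inconsistent with reference")
    newCodon <- codon
    substr(newCodon, posInCodon, posInCodon) <- altC
    code <- Biostrings::GENETIC_CODE
    aaOld <- unname(code[codon])
    aaNew <- unname(code[newCodon])
    cl <- ifelse(aaNew == "*" & aaOld != "*", "nonsense",
                 ifelse(aaOld == aaNew, "synonymous", "nonsynonymous"))
    out$coding <- S4Vectors::DataFrame(
      variant = vi, gene_id = gi, class = cl,
      aa_change = paste0(aaOld, codonIdx, aaNew))
  }
  ## --- splice-site annotations -------------------------------------------
  if (length(spliceHits)) {
    vi <- S4Vectors::queryHits(spliceHits)
    gi <- S4Vectors::mcols(models@spliceWindows)$gene_id[
      S4Vectors::subjectHits(spliceHits)]
    d <- !duplicated(paste(vi, gi))
    out$splice <- S4Vectors::DataFrame(
      variant = vi[d], gene_id = gi[d], class = "splice_site",
      aa_change = NA_character_)
  }
  ## --- intronic: inside a gene span but neither coding nor splice ---------
  if (length(spanHits)) {
    vi <- S4Vectors::queryHits(spanHits)
    gi <- S4Vectors::mcols(models@spans)$gene_id[
      S4Vectors::subjectHits(spanHits)]
    pairKey <- paste(vi, gi)
    used <- character(0)
    if (!is.null(out$coding))
      used <- c(used, paste(out$coding$variant, out$coding$gene_id))
    if (!is.null(out$splice))
      used <- c(used, paste(out$splice$variant, out$splice$gene_id))
    keep <- !(pairKey %in% used) & !duplicated(pairKey)
    if (any(keep))
      out$intronic <- S4Vectors::DataFrame(
        variant = vi[keep], gene_id = gi[keep], class = "intronic",
        aa_change = NA_character_)
  }
  ann <- do.call(rbind, unname(out))
  if (is.null(ann))
    ann <- S4Vectors::DataFrame(variant = integer(0), gene_id = character(0),
                                class = character(0),
                                aa_change = character(0))
  ## --- intergenic: everything not annotated yet ---------------------------
  hitVars <- unique(ann$variant)
  rest <- setdiff(seq_len(n), hitVars)
  if (length(rest))
    ann <- rbind(ann, S4Vectors::DataFrame(
      variant = rest, gene_id = NA_character_, class = "intergenic",
      aa_change = NA_character_))
  ann <- ann[order(ann$variant, ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Annotate all records with effects and conservation scores
#'
#' Attaches [classifyVariants()] annotations plus the per-base conservation
#' score to every record.  Never changes record count or order; every
#' record ends up with at least one annotation.
#'
#' @param x a [VariantCalls] object.
#' @param models a [GeneModels] object.
#' @param reference a named [Biostrings::DNAStringSet].
#' @param track a [ConservationTrack], or `NULL` to leave conservation
#'   absent.
#' @return `x` with annotations filled in ([isAnnotated()] becomes `TRUE`).
#' @export
annotateVariants <- function(x, models, reference, track = NULL) {
  ann <- classifyVariants(x, models, reference)
  cons <- rep(NA_real_, nrow(ann))
  if (!is.null(track) && nrow(ann) > 0) {
    chrom <- as.character(GenomicRanges::seqnames(x@sites))[ann$variant]
    pos <- GenomicRanges::start(x@sites)[ann$variant]
    cons <- conservationAt(track, chrom, pos)
  }
  ann$conservation <- cons
  .setAnnotations(x, ann)
}
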