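## Build the derived structures (spans, splice windows) from per-gene CDS
## exon lists. Splice windows are the 2 intronic bases on either side of
## every internal CDS exon junction -- the donor/acceptor dinucleotides.
.buildGeneModels <- function(cdsList, strand) {
  grl <- if (is(cdsList, "GRangesList")) cdsList
         else GenomicRanges::GRangesList(cdsList)
  flat <- unlist(grl, use.names = FALSE)
  ids0 <- names(grl)
  gene <- rep(ids0, S4Vectors::elementNROWS(grl))
  o <- order(match(gene, ids0), GenomicRanges::start(flat))
  flat <- GenomicRanges::granges(flat)[o]
  S4Vectors::mcols(flat) <- NULL
  GenomicRanges::strand(flat) <- "*"   # strand lives in the strand slot
  gene <- gene[o]
  cds <- S4Vectors::split(flat, factor(gene, ids0))
  spans <- unlist(range(cds), use.names = FALSE)
  S4Vectors::mcols(spans)$gene_id <- ids0
  names(spans) <- ids0
  ## splice windows: 2 intronic bases on each side of internal junctions
  n <- S4Vectors::elementNROWS(cds)
  rk <- sequence(n)
  notLast <- rk != rep(n, n)
  notFirst <- rk != 1L
  chromFlat <- as.character(GenomicRanges::seqnames(flat))
  dEnds <- GenomicRanges::end(flat)[notLast]       # donor side
  aStarts <- GenomicRanges::start(flat)[notFirst]  # acceptor side
  sw <- GenomicRanges::GRanges(
    seqnames = c(chromFlat[notLast], chromFlat[notFirst]),
    ranges = IRanges::IRanges(start = c(dEnds + 1L, aStarts - 2L),
                              end = c(dEnds + 2L, aStarts - 1L)))
  S4Vectors::mcols(sw)$gene_id <- c(gene[notLast], gene[notFirst])
  new("GeneModels", cds = cds, strand = strand[ids0], spans = spans,
      spliceWindows = sw)
}

#' Construct gene models from per-gene CDS exon intervals
#'
#' @param cdsList a named list (or [GenomicRanges::GRangesList]) of CDS exon
#'   ranges per gene, 1-based inclusive coordinates.
#' @param strand named character vector (`"+"`/`"-"`) per gene.
#' @return a [GeneModels] object.
#' @export
geneModels <- function(cdsList, strand) {
  obj <- .buildGeneModels(cdsList, strand)
  validObject(obj)
  obj
}

#' Read gene models from a GFF3 file
#'
#' Expects standard `gene`/`mRNA`/`CDS` features with `ID`/`Parent`
#' attributes; 1-based inclusive coordinates (converted internally where
#' needed).  One transcript per gene is used: the first mRNA chain
#' encountered.  Each gene's total CDS length must be divisible by 3.
#'
#' @param path path to a GFF3 file.
#' @return a [GeneModels] object.
#' @importFrom rtracklayer import
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  mrna <- gr[type == "mRNA"]
  cds <- gr[type == "CDS"]
  firstOf <- function(x) {
    n <- S4Vectors::elementNROWS(x)
    out <- rep(NA_character_, length(x))
    out[n > 0] <- unlist(x, use.names = FALSE)[cumsum(n) - n + 1][n > 0]
    out
  }
  mrnaGene <- firstOf(mrna$Parent)
  names(mrnaGene) <- mrna$ID
  keepTx <- mrna$ID[!duplicated(mrnaGene)]
  cdsTx <- firstOf(cds$Parent)
  cds <- cds[cdsTx %in% keepTx]
  cdsTx <- cdsTx[cdsTx %in% keepTx]
  geneOf <- mrnaGene[cdsTx]
  if (!length(cds)) stop("no CDS features found in ", path)
  cdsBare <- GenomicRanges::granges(cds)
  S4Vectors::mcols(cdsBare) <- NULL
  cdsList <- S4Vectors::split(cdsBare, geneOf)
  strandFlat <- as.character(GenomicRanges::strand(cds))
  strand <- vapply(split(strandFlat, geneOf), `[`, character(1), 1)
  geneModels(cdsList, strand)
}

#' Write gene models to a GFF3 file
#'
#' Deterministic GFF3 emitter (no date stamp) producing `gene`, `mRNA` and
#' `CDS` rows with correct per-exon coding phase.
#'
#' @param models a [GeneModels] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  stopifnot(is(models, "GeneModels"))
  lines <- "##gff-version 3"
  for (g in geneIds(models)) {
    e <- models@cds[[g]]
    st <- models@strand[[g]]
    chrom <- as.character(GenomicRanges::seqnames(e))[1]
    s <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
    ## phase: transcription order is genomic for "+", reversed for "-"
    ord <- if (st == "+") seq_along(e) else rev(seq_along(e))
    w <- GenomicRanges::width(e)[ord]
    phase <- integer(length(e))
    phase[ord] <- c(0L, (3L - cumsum(w)[-length(w)] %% 3L) %% 3L)
    lines <- c(lines,
      sprintf("%s\tEMSscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s", chrom,
              min(s), max(en), st, g),
      sprintf("%s\tEMSscreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              chrom, min(s), max(en), st, g, g),
      sprintf("%s\tEMSscreen\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s.t1",
              chrom, s, en, st, phase, g, g))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname GeneModels-class
#' @export
setMethod("geneIds", "GeneModels", function(x) names(x@cds))

#' @rdname GeneModels-class
#' @export
setMethod("cdsExons", "GeneModels", function(x) x@cds)

#' @rdname GeneModels-class
#' @export
setMethod("geneSpans", "GeneModels", function(x) x@spans)

#' @rdname GeneModels-class
#' @export
setMethod("spliceWindows", "GeneModels", function(x) x@spliceWindows)

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels with %d genes on %d sequence(s)\n",
              length(object@cds),
              length(unique(as.character(
                GenomicRanges::seqnames(object@spans))))))
  invisible(NULL)
})

## Spliced coding-strand CDS sequence per gene, as a named character vector.
## armChars: named list of arm sequences as single character strings.
.cdsSequences <- function(models, armChars) {
  ids <- geneIds(models)
  flat <- unlist(models@cds, use.names = FALSE)
  geneOf <- rep(ids, S4Vectors::elementNROWS(models@cds))
  chrom <- as.character(GenomicRanges::seqnames(flat))
  pieces <- character(length(flat))
  for (arm in unique(chrom)) {
    i <- chrom == arm
    pieces[i] <- substring(armChars[[arm]], GenomicRanges::start(flat)[i],
                           GenomicRanges::end(flat)[i])
  }
  out <- vapply(split(pieces, factor(geneOf, ids)), paste, character(1),
                collapse = "")
  minus <- models@strand[ids] == "-"
  if (any(minus))
    out[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(out[minus])))
  out
}

## arm sequences of a DNAStringSet as plain character strings
.armChars <- function(reference) {
  out <- as.list(as.character(reference))
  names(out) <- names(reference)
  out
}
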