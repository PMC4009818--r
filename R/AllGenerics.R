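#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges GRangesList
#' @importClassesFrom S4Vectors DataFrame
NULL

#' @rdname VariantCalls-class
#' @param x a `VariantCalls` object.
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname VariantCalls-class
#' @export
setGeneric("variantSites", function(x) standardGeneric("variantSites"))

#' @rdname VariantCalls-class
#' @export
setGeneric("refAllele", function(x) standardGeneric("refAllele"))

#' @rdname VariantCalls-class
#' @export
setGeneric("altAllele", function(x) standardGeneric("altAllele"))

#' @rdname VariantCalls-class
#' @export
setGeneric("qualScores", function(x) standardGeneric("qualScores"))

#' @rdname VariantCalls-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname VariantCalls-class
#' @export
setGeneric("genotypeQuality", function(x) standardGeneric("genotypeQuality"))

#' @rdname VariantCalls-class
#' @export
setGeneric("readDepths", function(x) standardGeneric("readDepths"))

#' @rdname VariantCalls-class
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname VariantCalls-class
#' @export
setGeneric("sampleRole", function(x) standardGeneric("sampleRole"))

#' @rdname VariantCalls-class
#' @export
setGeneric("variantAnnotations", function(x) standardGeneric("variantAnnotations"))

#' @rdname VariantCalls-class
#' @export
setGeneric("isAnnotated", function(x) standardGeneric("isAnnotated"))

#' @rdname VariantCalls-class
#' @export
setGeneric("skipLog", function(x) standardGeneric("skipLog"))

#' @rdname GeneModels-class
#' @param x a `GeneModels` object.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneModels-class
#' @export
setGeneric("cdsExons", function(x) standardGeneric("cdsExons"))

#' @rdname GeneModels-class
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))

#' @rdname GeneModels-class
#' @export
setGeneric("spliceWindows", function(x) standardGeneric("spliceWindows"))

#' @rdname CohortMatrix-class
#' @param x a `CohortMatrix` object.
#' @export
setGeneric("cohortKeys", function(x) standardGeneric("cohortKeys"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("cohortStatus", function(x) standardGeneric("cohortStatus"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("altCounts", function(x) standardGeneric("altCounts"))
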