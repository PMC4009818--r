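#' Create a screen manifest
#'
#' @param background background (unmutagenized parental) sample name.
#' @param mutants ordered mutant strain names; one complementation group.
#' @param unrelated unrelated cohort genome names.
#' @param region mapped chromosome arm, or `NA` for genome-wide analysis.
#' @return a [ScreenManifest].
#' @export
screenManifest <- function(background, mutants, unrelated = character(0),
                           region = NA_character_) {
  obj <- new("ScreenManifest", background = background,
             mutants = as.character(mutants),
             unrelated = as.character(unrelated),
             region = as.character(region))
  validObject(obj)
  obj
}

#' Read / write a screen manifest (YAML)
#'
#' The manifest names each sample's role: `background` (one name),
#' `mutants` (ordered list), `unrelated` (list) and an optional `region`
#' arm.
#'
#' @param path path to a YAML manifest.
#' @return [readScreenManifest()]: a [ScreenManifest];
#'   [writeScreenManifest()]: `path`, invisibly.
#' @importFrom yaml read_yaml write_yaml
#' @export
readScreenManifest <- function(path) {
  y <- yaml::read_yaml(path)
  screenManifest(background = y$background,
                 mutants = unlist(y$mutants),
                 unrelated = if (is.null(y$unrelated)) character(0)
                             else unlist(y$unrelated),
                 region = if (is.null(y$region)) NA_character_ else y$region)
}

#' @rdname readScreenManifest
#' @param manifest a [ScreenManifest].
#' @export
writeScreenManifest <- function(manifest, path) {
  yaml::write_yaml(list(
    background = manifest@background,
    mutants = as.list(manifest@mutants),
    unrelated = as.list(manifest@unrelated),
    region = if (is.na(manifest@region)) NULL else manifest@region), path)
  invisible(path)
}

setMethod("show", "ScreenManifest", function(object) {
  cat(sprintf(
    "ScreenManifest: background=%s; %d mutant(s): %s; %d unrelated%s\n",
    object@background, length(object@mutants),
    paste(object@mutants, collapse = ", "), length(object@unrelated),
    if (!is.na(object@region)) paste0("; region=", object@region) else ""))
  invisible(NULL)
})

#' Collapse filtered records to genes
#'
#' Maps each gene to the variants having a qualifying annotation in it.  A
#' variant overlapping two genes contributes to both; a gene counts once
#' per strain regardless of how many variants support it.
#'
#' @param x an annotated [VariantCalls] object (typically post-filtering).
#' @param classes annotation classes that qualify a variant for a gene.
#' @return named list: gene id -> character vector of variant keys.
#' @export
collapseToGenes <- function(x, classes = c("nonsynonymous", "nonsense",
                                           "splice_site")) {
  if (length(x) == 0) return(stats::setNames(list(), character(0)))
  if (!isAnnotated(x))
    stop("records must be annotated before collapsing to genes")
  ann <- x@annotations
  sel <- ann$class %in% classes & !is.na(ann$gene_id)
  if (!any(sel)) return(stats::setNames(list(), character(0)))
  keys <- variantKeys(x)
  lapply(split(keys[ann$variant[sel]], ann$gene_id[sel]), unique)
}

#' Intersect candidate genes across non-complementing strains
#'
#' Returns genes qualifying in at least `k` strains, with each strain's
#' supporting variants.  With upstream cohort-uniqueness filtering active,
#' supporting variants are automatically distinct across strains.
#'
#' @param perStrainGenes named list: strain -> ([collapseToGenes()] result).
#' @param k required number of supporting strains (`1 <= k <= #strains`).
#' @return named list: gene -> named list (strain -> supporting variant
#'   keys).  Use [candidateTable()] for a tidy rendering.
#' @export
intersectStrains <- function(perStrainGenes, k) {
  if (k < 1) stop("k must be >= 1")
  if (k > length(perStrainGenes))
    stop("k exceeds the number of strains")
  geneStrain <- list()
  for (s in names(perStrainGenes))
    for (g in names(perStrainGenes[[s]]))
      geneStrain[[g]][[s]] <- perStrainGenes[[s]][[g]]
  if (!length(geneStrain)) return(stats::setNames(list(), character(0)))
  hits <- geneStrain[vapply(geneStrain, length, integer(1)) >= k]
  if (!length(hits)) return(stats::setNames(list(), character(0)))
  hits[order(names(hits))]
}

#' Tidy table of candidate genes
#'
#' @param candidates result of [intersectStrains()].
#' @return data.frame with columns `gene`, `n_strains`, `strains`
#'   (semicolon-joined) and `variants` (per-strain `strain:key` pairs).
#' @export
candidateTable <- function(candidates) {
  if (length(candidates) == 0)
    return(data.frame(gene = character(0), n_strains = integer(0),
                      strains = character(0), variants = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    gene = names(candidates),
    n_strains = vapply(candidates, length, integer(1)),
    strains = vapply(candidates, function(x)
      paste(names(x), collapse = ";"), character(1)),
    variants = vapply(candidates, function(x)
      paste(vapply(names(x), function(s)
        paste0(s, ":", paste(x[[s]], collapse = ",")), character(1)),
        collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the cascade report across strains
#'
#' Runs the [runCascade()] filter cascade for every mutant strain, collapses
#' survivors to genes at each step, and fills the steps-by-k matrix: cell
#' (row, k) is the number of genes with a qualifying variant in each of at
#' least k strains after the row's cumulative filters.  The cohort
#' uniqueness row reflects adding the unrelated cohort genomes.
#'
#' @param manifest a [ScreenManifest].
#' @param records named list of annotated [VariantCalls] (mutants and
#'   background at least).
#' @param spec a [FilterSpec]; its region defaults to the manifest's.
#' @param cohort a [CohortMatrix] over all samples, or `NULL`.
#' @return a list with `report` (a [CascadeReport]), `cascades` (per-strain
#'   [runCascade()] results) and `candidates` (the [intersectStrains()]
#'   result at `k = ` number of mutants on the final step).
#' @export
buildCascadeReport <- function(manifest, records, spec = filterSpec(),
                               cohort = NULL) {
  stopifnot(is(manifest, "ScreenManifest"))
  if (is.na(spec@region[1]) && !is.na(manifest@region))
    spec@region <- manifest@region
  bg <- records[[manifest@background]]
  cascades <- lapply(manifest@mutants, function(m) {
    runCascade(records[[m]], spec, background = bg, cohort = cohort,
               sample = m)
  })
  names(cascades) <- manifest@mutants
  stepLabels <- cascades[[1]]$counts$step
  nm <- length(manifest@mutants)
  geneCounts <- matrix(0L, nrow = length(stepLabels), ncol = nm,
                       dimnames = list(stepLabels, paste0("k", seq_len(nm))))
  variantCounts <- matrix(0L, nrow = length(stepLabels), ncol = nm,
                          dimnames = list(stepLabels, manifest@mutants))
  for (i in seq_along(stepLabels)) {
    sets <- lapply(cascades, function(cc) cc$geneSets[[i]])
    support <- table(unlist(sets))
    for (k in seq_len(nm))
      geneCounts[i, k] <- sum(support >= k)
    variantCounts[i, ] <- vapply(cascades, function(cc)
      cc$counts$variants[i], integer(1))
  }
  report <- new("CascadeReport", steps = stepLabels,
                geneCounts = geneCounts, variantCounts = variantCounts,
                strains = manifest@mutants)
  validObject(report)
  finalGenes <- lapply(cascades, function(cc)
    collapseToGenes(cc$records, spec@classes))
  candidates <- intersectStrains(finalGenes, k = nm)
  list(report = report, cascades = cascades, candidates = candidates)
}

setMethod("show", "CascadeReport", function(object) {
  cat("CascadeReport (genes with >=1 qualifying variant in >=k strains)\n")
  m <- cbind(object@geneCounts, object@variantCounts)
  colnames(m) <- c(colnames(object@geneCounts),
                   paste0("v:", colnames(object@variantCounts)))
  print(m)
  invisible(NULL)
})

#' Serialize a cascade report
#'
#' Writes the gene-count and per-strain variant-count matrices as one
#' tab-delimited table, plus (optionally) a human-readable rendering.
#'
#' @param x a [CascadeReport].
#' @param path output TSV path.
#' @param textPath optional path for a plain-text rendering.
#' @return `path`, invisibly.
#' @export
writeCascadeReport <- function(x, path, textPath = NULL) {
  df <- data.frame(step = x@steps, x@geneCounts, x@variantCounts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("step", colnames(x@geneCounts),
                    paste0("variants_", colnames(x@variantCounts)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(textPath)) {
    con <- file(textPath, "wt")
    sink(con)
    show(x)
    sink()
    close(con)
  }
  invisible(path)
}

#' Per-sample sequencing-metrics summary
#'
#' Emits, per sample, the SNV counts at each analysis tier: total SNVs,
#' high-quality SNVs (GQ/QUAL thresholds), NS/SS coding SNVs, NS/SS on the
#' mapped arm, and cohort-unique NS/SS on the arm; plus a totals row
#' summing the mutant rows (see [metricsTotals()]).
#'
#' @param records named list of annotated [VariantCalls] covering the
#'   manifest's background and mutant samples.
#' @param manifest a [ScreenManifest].
#' @param spec a [FilterSpec] supplying thresholds and classes.
#' @param cohort optional [CohortMatrix] for the uniqueness tier (omitted
#'   tier reported as `NA` without it).
#' @return data.frame, one row per sample plus a `total_in_mutants` row.
#' @export
summarizeMetrics <- function(records, manifest, spec = filterSpec(),
                             cohort = NULL) {
  region <- if (!is.na(spec@region[1])) spec@region else manifest@region
  samples <- c(manifest@background, manifest@mutants)
  roles <- c("background", rep("mutant", length(manifest@mutants)))
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[i]
    x <- records[[s]]
    hq <- filterQuality(x, spec@minGQ, spec@minQual, sample = s)
    nsss <- filterClass(hq, spec@classes)
    onArm <- if (!is.na(region[1])) filterRegion(nsss, region) else nsss
    uniq <- if (!is.null(cohort))
      length(filterCohortUnique(onArm, cohort, s, spec@maxCohortCount))
    else NA_integer_
    data.frame(sample = s, role = roles[i], snvs = length(x),
               high_quality_snvs = length(hq), nsss_csnvs = length(nsss),
               nsss_on_region = length(onArm), unique_nsss_on_region = uniq,
               stringsAsFactors = FALSE)
  })
  metricsTotals(do.call(rbind, rows))
}

#' Append the mutant totals row to a metrics table
#'
#' Sums every numeric column over rows with `role == "mutant"` and appends
#' the result as a `total_in_mutants` row -- the arithmetic identity a
#' published per-sample metrics table satisfies.
#'
#' @param df data.frame with a `role` column and numeric tier columns.
#' @return `df` with one extra row.
#' @export
metricsTotals <- function(df) {
  stopifnot("role" %in% colnames(df))
  mut <- df[df$role == "mutant", , drop = FALSE]
  tot <- df[1, , drop = FALSE]
  tot$sample <- "total_in_mutants"
  tot$role <- "total"
  for (cn in colnames(df))
    if (is.numeric(df[[cn]])) tot[[cn]] <- sum(mut[[cn]])
  rbind(df, tot)
}
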