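---
title: "Methods: variant filtering and gene identification in EMS screens"
author: "EMSscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant filtering and gene identification in EMS screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the model behind the filtering cascade, the simulator that stands in for
real screen genomes, the numerical and design choices that were genuinely
open, and what the tests do and do not establish about real data.

## The model

An EMS screen yields recessive mutant strains in one complementation
group, each carrying an induced point lesion in the same (unknown) gene,
sequenced as heterozygotes over the unmutagenized background chromosome.
Whole-genome variant calls for the background strain, the mutant strains,
and a set of unrelated genomes are the inputs. The causative lesion is
characterized by a conjunction of independent per-variant predicates:

* it is a single-nucleotide variant — EMS induces point mutations, so the
  analysis is restricted to SNVs and multi-allelic VCF rows are split into
  biallelic records keyed by (chrom, pos, ref, alt);
* it is a confident call: genotype quality GQ ≥ 75 and site quality
  QUAL ≥ 100, both Phred-scaled (`phredToProb(q)` = 10^(−q/10); the
  package follows the standard Phred convention, under which a score of 10
  means a 1-in-10 error chance);
* it is heterozygous in the focal strain (mutants ride over one background
  chromosome);
* it damages a protein: nonsynonymous, nonsense or splice-site ("NS/SS")
  by the internal annotator;
* it bears the EMS signature: G→A or C→T (guanine alkylation);
* it is absent from the background strain and from every other cohort
  genome (0 other carriers by default);
* it falls at a conserved base (score > 0.5) — damaging a conserved
  position is more plausibly causal;
* it lies on the mapped arm, when mapping data exist.

Each strain's survivors are collapsed to genes (a gene counts once per
strain however many variants support it; a variant overlapping two genes
supports both) and genes qualifying in ≥ k strains are candidates. With
three non-complementing strains the intersection is typically a single
gene, because independent EMS lesions rarely hit the same gene by chance
when the candidate sets are small relative to the gene count.

## The annotator

The effect annotator replaces an external variant-effect service so the
toolkit runs offline. It classifies one annotation per overlapping gene:

* **Coding** positions are translated with the standard genetic code on
  the coding strand; a stop-producing change is `nonsense`, a silent one
  `synonymous`, otherwise `nonsynonymous`; changes are reported as e.g.
  `Q23*`.
* **Splice sites** are the 2 intronic bases flanking each *internal* CDS
  exon junction — the donor/acceptor dinucleotides, the minimal
  VEP-style definition. The boundaries of first/last exons face
  non-intronic sequence and get no window.
* Everything else inside a gene span is `intronic`; a variant overlapping
  no gene gets a single `intergenic` annotation.

One transcript per gene (the first mRNA chain in the GFF3) is used: the
analysis is gene-level, and multi-isoform logic adds no distinguishable
behaviour at that level. A strand-symmetry property test asserts that a
reverse-strand gene produces the identical amino-acid change as its
forward-strand construction.

The reference base at every variant site is checked against the supplied
FASTA; a mismatch is an error naming the site, because silently
mis-phased references would corrupt every downstream codon.

## Conservation

Conservation scores (PhastCons-style, in [0, 1]) are read from fixed-step
WIG or a 3-column table and looked up at the single variant base. The
filter keeps scores **strictly** greater than 0.5. Positions the track
does not cover have *absent* scores, and absent fails the filter by
default (`keepMissingConservation = FALSE`): the cascade is a shrinking
funnel, and an uncovered base offers no positive evidence of constraint.
The choice is configurable because real tracks vary in coverage.

## Backfilling and the cohort matrix

For every site observed in any sample, the cohort matrix assigns each
sample `alt`, `ref` or `missing`. A `ref` status requires positive
evidence: an explicit covering call at that position (hom-ref or an
other-allele call from a split multi-allelic row), or, when per-sample
well-covered intervals are supplied, coverage at the conventional 8×
minimum. A site simply absent from a sample's VCF is `missing`, never
`ref` — single-sample variant files omit uncovered positions, and
treating absence as reference would overstate uniqueness. Frequency
counts exclude the queried sample itself; background subtraction,
separately, removes any variant the background carries *at any quality*,
because the background is typically sequenced at lower depth and
demanding high-quality background evidence would under-subtract.

## The simulator

`generateScreen()` emulates the measured statistics of a real fly screen
at desk scale, so that the full pipeline (including file I/O in every
standard format) is exercised end to end against a known answer. The
defaults are the study conditions; per parameter:

* **Genome**: one 2 Mb arm ("3L", carrying the causative gene) plus one
  1 Mb arm ("2R"). 3 Mb keeps a full generate-analyze cycle around half a
  minute; all densities are per-Mb, so conclusions scale linearly.
* **Genes**: 225 total — the fly's ~75 protein-coding genes per Mb —
  with 3–5 CDS exons, intact start/stop codons, no internal stops, total
  CDS divisible by 3, and short introns. Gene spans average ~700 bp
  (~430 bp CDS): compact relative to real fly genes, keeping the coding
  fraction of the scaled-down genome near 3% so that per-gene hit counts
  stay in a regime where a three-strain intersection is decisive, as it
  is in a full-size genome.
* **Background variation**: 10,000 variants/Mbp, inside the ~8,100–11,000
  autosomal range observed in real data; 70% homozygous (an inbred
  stock), the rest heterozygous.
* **EMS load**: Poisson(0.6/kb × genome kb) induced heterozygous
  mutations per strain; each is a forced G→A/C→T transition at a random
  G/C site with probability 0.8 (the 70–100% literature range; a real
  screen's *observed* NS/SS transition share can sit lower when only one
  parental genome is available for subtraction — the simulator documents
  rather than reproduces that anomaly). Non-transition draws are uniform
  over the *remaining* substitutions, so the realized transition fraction
  is unbiased — otherwise accidental G→A draws would push it above the
  configured value and the calibration property would fail by
  construction.
* **Quality scores**: GQ/QUAL mixtures under which ~60% of calls pass
  GQ ≥ 75 ∧ QUAL ≥ 100 jointly, echoing the ~52% high-quality fraction
  real screens report; the quality filter therefore does real work in
  tests.
* **Conservation track**: covers the genic footprint only. Within each
  CDS exon one contiguous conserved block (scores 0.55–0.99) covers 25%
  of the exon; the rest of the exon scores 0.05–0.45 and introns 0–0.40.
  An all-high CDS track was rejected deliberately: in real data the
  conservation filter removes well over half of the candidate genes, so
  a track that every coding variant passes would silence the filter and
  misrepresent the cascade's behaviour.
* **Causative plan**: before any variant is placed, the planner
  enumerates, per gene on the causative arm, codons that a single
  coding-strand C→T or G→A converts to a stop (CAA/CAG/CGA at base 1;
  TGG at bases 2 or 3), keeps those at conserved positions, picks the
  best-endowed gene, and assigns one distinct position per strain. All
  background, unrelated and other-strain draws exclude these reserved
  positions, so the planted lesion is private by construction — and each
  lesion is asserted at generation time to satisfy every default filter.
* **Mutant strains** carry the complete background variant set (they are
  heterozygotes over the background chromosome), so background
  subtraction is genuinely load-bearing; **unrelated genomes** get
  freshly resampled natural variation plus their own EMS load and no
  causative lesion.

All randomness derives from the single config seed (sub-generators use
fixed offsets), and every writer is deterministic — no date stamps — so
identical configurations produce byte-identical directories. The emitted
truth table of induced mutations, with intended effect classes computed
by a separate exon-walking code path, is the oracle for the annotator and
the end-to-end tests.

What the simulator does **not** model: read-level artifacts (alignment
error, mapping bias, coverage troughs), indels/SVs/CNVs, linked selection
or recombination structure, multi-isoform genes, UTRs and non-coding
exons, and position-dependent EMS context preferences. Passing tests
therefore demonstrate the *logic* of the cascade and the intersection on
statistically faithful inputs, not robustness to the full messiness of
real sequencing data.

## Numerical and interface choices

* Coordinates are 1-based inclusive in VCF/GFF3/WIG and 0-based
  half-open in BED, converted only at format boundaries (a variant at
  1-based p exports as the interval [p−1, p)).
* Thresholds are inclusive where written with ≥ (GQ 75, QUAL 100) and
  strict where written with > (conservation 0.5); the tests pin both
  boundaries.
* Quality-filter failures due to a missing GQ on a called genotype are
  logged, not raised: heterogeneous cohort VCFs are expected input.
* Multi-allelic rows are split sharing the row QUAL; a sample carrying a
  *different* alt at the site counts as `ref` evidence for the split
  allele under backfilling.
* GQ values above 99 in foreign VCFs are capped at 99 (the conventional
  ceiling).
* Filters are pure per-record predicates; the cascade's narrative order
  is cosmetic for the final set (asserted under 10 random orderings) and
  chosen to make the intermediate funnel informative.
* An unknown region arm yields an empty result with a warning rather
  than an error, so iterative filter exploration does not crash on typos.
* VCF and GFF3 *reading* go through VariantAnnotation and rtracklayer;
  *writing* of VCF/GFF3/WIG is done by small deterministic emitters
  (standard writers stamp dates, which would break the simulator's
  byte-identity contract), and fixed-step WIG parsing is a dedicated
  vectorized reader because the general-dialect importer is an order of
  magnitude too slow for a per-screen track on the analysis hot path.

## Problem sizes used by the tests

The module tests run on a 0.45 Mb two-arm screen (34 genes, 2 unrelated
genomes) generated once and shared across files. The acceptance-style
checks use the full default configuration: one 3 Mb screen for simulator
calibration (≥ 5,000 induced mutations) and twenty seeded 3 Mb screens
for end-to-end recovery, each analyzed from its files through
`runAnalyze()`. These sizes were chosen so the whole suite completes in
well under half an hour on one core while leaving every stage —
generation, serialization, parsing, annotation, cohort construction,
cascade, intersection — on its production code path.

## Known limitations

* The gene-level intersection reports no statistical significance for
  candidates; with very small gene universes or very high EMS loads,
  chance multi-strain hits become possible (the cascade report's k = 1
  and k = 2 columns make the ambient hit rate visible).
* The annotator's class set is deliberately coarse (no stop-loss,
  start-loss or splice-region-beyond-2bp categories); such variants fall
  into the nearest coarse class.
* Backfilling from coverage intervals trusts the caller's depth
  threshold; it does not model mapping quality.
* The simulator plants nonsense lesions only — the hardest class to
  miss, but also the easiest; a screen whose lesion is a subtle missense
  change in a poorly conserved residue would not survive the default
  conservation filter, in simulation or in reality.
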