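# EMSscreen

Gene identification in EMS mutagenesis screens from whole-genome variant
calls.

## The problem

Forward genetic screens in *Drosophila melanogaster* use ethyl
methanesulfonate (EMS) to induce random point mutations, then select flies
showing a phenotype of interest. Finding the causative gene afterwards is
the bottleneck: each mutant genome differs from the reference at hundreds
of thousands of positions, almost all of them natural variation shared with
the unmutagenized parental ("background") stock. EMSscreen implements the
whole-genome-sequencing analysis route for this problem, for fly
geneticists who have per-sample VCFs from a standard alignment +
variant-calling pipeline and want candidate genes, not bioinformatics.

The method rests on four observations:

1. **EMS chemistry is distinctive.** EMS alkylates guanine, so 70–100% of
   induced lesions are G→A (equivalently C→T on the other strand)
   transitions. Filtering single-nucleotide variants (SNVs) for this
   signature discards most natural variation.
2. **The background strain is sequenced too.** Any variant carried by the
   parental stock (at any quality) cannot be the induced lesion; mutants
   were sequenced as heterozygotes crossed over the original background
   chromosome, so the lesion itself is a heterozygous call absent from the
   background.
3. **Unrelated genomes give frequency leverage.** A variant observed in
   other, unrelated sequenced genomes is not the strain-specific lesion.
   A backfilled cohort matrix records, for every observed site and every
   sample, `alt` / `ref` / `missing` status — absence of a site from a
   sample's VCF is never silently treated as reference — and supports
   anonymous carrier counts.
4. **Non-complementation is the decisive filter.** Mutant strains in one
   lethal complementation group carry *different* lesions in the *same*
   gene. Collapsing each strain's surviving variants to genes and
   intersecting across strains (gene must qualify in ≥ k strains) isolates
   the causative gene, typically uniquely at k = 3.

The step-wise cascade applied per strain, with inclusive quality
thresholds, is:

| step | predicate |
|---|---|
| quality | genotype quality GQ ≥ 75 and site quality QUAL ≥ 100 (both Phred-scaled; GQ capped at 99) |
| class | ≥ 1 annotation in {nonsynonymous, nonsense, splice site} ("NS/SS"; nonsense ⊂ NS) |
| zygosity | heterozygous in the focal strain |
| background | identity key (chrom, pos, ref, alt) absent from background carriers |
| EMS | (ref, alt) ∈ {(G, A), (C, T)} |
| conservation | PhastCons-style score strictly > 0.5 (absent score fails) |
| cohort | ≤ 0 other carriers across the whole cohort |
| region | mapped chromosome arm, if the screen was mapped |

All filters are independent per-record predicates, so the final candidate
set does not depend on their order (asserted in the test suite); only the
intermediate counts do.

Because real screen genomes are large and private, the package ships a
first-class synthetic screen simulator (`generateScreen()`): a random
multi-arm reference with compact intron-containing gene models, a
fixed-step WIG conservation track, a background strain at realistic
variant density, mutant strains carrying the full background variant set
plus a calibrated EMS load, a planted causative gene with a distinct
nonsense lesion per strain, and a truth table for every induced mutation.
Every stage of the pipeline is testable against that truth table.

## Worked example

Simulate a default screen (2 Mb arm "3L" + 1 Mb arm "2R", 225 genes,
10,000 background variants/Mbp, 0.6 induced mutations/kb at 80%
transitions, 3 mutants + 8 unrelated genomes) and analyze it:

```r
library(EMSscreen)
scr <- generateScreen(simulationConfig(seed = 7), dir = "screen")
res <- runAnalyze("screen")
res$report
```

```
CascadeReport (genes with >=1 qualifying variant in >=k strains)
               k1  k2  k3 v:mut1 v:mut2 v:mut3
input         223 223 223  31692  31719  31679
quality       223 217 195  18868  18886  19036
class         213 207 178    490    484    507
zygosity      164 123  70    163    163    160
background     67  10   1     26     28     27
ems            55   7   1     21     19     25
conservation   10   1   1      2      4      6
cohort_unique  10   1   1      2      4      6
region          5   1   1      2      2      3
```

Read the matrix like a funnel: each row adds one filter; column `k` counts
genes with a qualifying variant in at least k of the 3 mutant strains; the
`v:` columns are per-strain surviving variant counts. Here ~31,700 SNVs
per strain collapse to a single gene supported by all three strains —
and it is the planted one:

```r
names(res$candidates)
#> [1] "gene0054"
unique(scr$truth$gene_id[scr$truth$is_causative])
#> [1] "gene0054"
```

`runAnalyze()` writes `candidates.tsv`, per-strain variant tables,
`cascade_report.tsv`/`.txt`, per-sample tier metrics (`metrics.tsv`, with
a mutant totals row), and per-strain UCSC custom-track BED files of the
surviving variants.

The same workflow is available from the shell via the installed script:

```sh
Rscript exec/ems-screen simulate --seed 7 --out screen
Rscript exec/ems-screen analyze --dir screen --k 3
```

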