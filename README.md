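# mtLHON

Leber's hereditary optic neuropathy (LHON) is a maternally inherited optic
neuropathy caused by mitochondrial DNA point mutations in the complex-I (ND)
subunit genes. Over 90% of cases carry one of three common mutations
(m.11778G>A, m.3460G>A, m.14484T>C); the remainder carry rare variants whose
pathogenicity must be argued case by case. **mtLHON** implements the
analytical pipeline used to make that argument for whole-mtDNA-sequenced
cohorts, and to flag background polymorphisms that may act synergistically.

The package is aimed at mitochondrial geneticists and methodologists who
want the individual steps of such an analysis as tested, reusable functions
rather than one-off scripts.

## What it computes

Evidence that a rare variant is a *primary* LHON mutation is aggregated from
four criteria plus one supporting observation:

1. **Independent origins** — the variant arose repeatedly on different mtDNA
   backgrounds. Carrier states at the tips of a reference phylogeny are
   analysed by gains-only (Camin–Sokal) parsimony: the minimal number of
   0 → 1 transitions, with reversions disallowed (a reversible
   minimum-change mode is available). A nested non-carrier lineage forces
   two gains rather than gain-plus-reversion, which is exactly how a control
   sequence inside a carrier clade demonstrates independent acquisition.
2. **Conservation** — the affected residue is conserved across species. Per
   position of a pre-aligned protein set (eukaryotes / vertebrates /
   mammals), the modal residue's prevalence among non-gap rows is computed;
   a position is conserved when prevalence is strictly over the 70%
   threshold. Two further rules catch residues in conserved context: a
   ±10-residue window whose mean prevalence *and* conserved-position density
   both exceed the whole protein's, and proximity (≤ 4 residues) to an
   invariant (100%) position.
3. **Population rarity** — at most a couple of carrier records in large
   population haplotype collections.
4. **Disease association** — strict association with LHON; carriers with
   extra-ocular phenotypes define the separate "LHON-plus" category.
5. **Heteroplasmy** (supporting, never required) — quantified in silico by a
   PCR-RFLP assay: amplicon extraction from the circular genome, restriction
   digestion with allele-diagnostic fragments, and densitometric mutant-load
   estimation under the mass model (intensity ∝ molarity × length), so the
   mutant fraction is Σ(I/L) over mutant bands ÷ Σ(I/L) over all diagnostic
   bands.

Around these sit a parser for the compact variant dialect used on mtDNA
phylogeny figures (`3700`, `14482A`, `@263`, suffixes `s/ns/h/~t/~r/+/d`) and
HGVS-like `m.` labels, protein-consequence annotation under the vertebrate
mitochondrial genetic code (light-strand genes handled), haplogroup
assignment by mutational-motif matching, clade enrichment against population
frequencies, and seed-deterministic simulators (alignments, cohorts on known
trees, population collections, gel intensities) that generate every input
with recorded ground truth.

The packaged reference genome is a clearly labelled deterministic synthetic
stand-in for the 16,569-bp human reference: real gene coordinates, with the
reference bases and codons relevant to the packaged cohort planted so all
documented nucleotide → protein consequences hold exactly.

## Worked example

```r
library(mtLHON)

g <- readMitoGenome(mtFixture("rcrs_synthetic.fasta"),
                    mtFixture("rcrs_genemap.tsv"))

# variant parsing and annotation
v <- parseVariantLabel("3700", g)     # shorthand: implied transition
variantLabel(v, "hgvs")
#> [1] "m.3700G>A"
proteinLabel(annotateProteinChange(v, g))
#> [1] "p.A132T"

# full cohort analysis on the packaged fixtures
rep <- runFullAnalysis(
  cohortFile    = mtFixture("lhon_cohort.tsv"),
  treeFile      = mtFixture("lhon_cohort_tree.txt"),
  genomeFile    = mtFixture("rcrs_synthetic.fasta"),
  geneMapFile   = mtFixture("rcrs_genemap.tsv"),
  predictorFile = mtFixture("lhon_evidence_table.tsv"))

rep$nProbands                                   # 16
rep$nDistinctRare                               # 9
rep$rareMutations[["m.14568C>T"]]$nCarriers     # 5
rep$rareMutations[["m.14568C>T"]]$nOriginsCohort  # 5 independent origins
rep$rareMutations[["m.3700G>A"]]$nOriginsCohort   # 2
100 * rep$enrichment$cohortFraction             # 37.5 (% J1c+J2b probands)
rep$predictorConcordance$percentBoth            # 67 (% flagged by both tools)
rep$rareMutations[["m.14459G>A"]]$classification  # "LHON-plus"
rep$rareMutations[["m.14568C>T"]]$classification  # "confirmed primary"
```

The numbers read: 16 probands carry 9 distinct rare candidate mutations;
m.14568C>T is carried by five probands on five independent branches of the
cohort phylogeny (sharing by recurrence, not descent); 37.5% of probands sit
on the J1c/J2b backgrounds against ~6.2% in the general Western European
population; six of the nine mutations (67%) are flagged by both in-silico
predictors; and the rubric separates the LHON-plus prototype m.14459G>A from
the confirmed primary mutations.

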