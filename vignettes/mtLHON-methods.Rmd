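---
title: "Classifying rare mtDNA variants as primary LHON mutations: methods"
author: "mtLHON authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying rare mtDNA variants as primary LHON mutations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtLHON)
```

## The problem

Leber's hereditary optic neuropathy (LHON) is a maternally inherited
blinding disorder caused by mtDNA point mutations in the complex-I ND
subunit genes. When the three common mutations are absent, whole-mtDNA
sequencing of suspected probands turns up rare candidate variants, and the
case that such a variant is a *primary* pathogenic mutation — rather than a
private polymorphism — rests on converging population-genetic and
evolutionary evidence. This package implements each line of that evidence
as a tested function, plus simulators that generate every input with known
ground truth.

## Variant model

Variants are differences from the circular 1-based mitochondrial reference
frame. Two notations are parsed: the compact dialect used on mtDNA
phylogeny figures, where a bare position denotes a transition (the alternate
base is the transition partner of the reference base, so resolution requires
the genome), an appended base denotes the explicit alternate
(`14482A` = m.14482C>A), `@` marks reversions, and suffixes annotate
synonymy (`s`/`ns`), heteroplasmy (`h`), locus (`~t`, `~r`) and indels
(`+`, `d`); and the HGVS-like `m.<pos><ref>><alt>` substitution form, whose
reference base is checked against the genome. Variants compare across
haplotypes, tree branches and population records through a canonical key
(position + alternate) that deliberately drops heteroplasmy and effect
hints, so a heteroplasmic and a homoplasmic record of the same change
match.

Protein consequences are computed under the vertebrate mitochondrial
genetic code (ATA = Met, TGA = Trp, AGA/AGG = stop). Light-strand genes are
translated from the reverse complement of the genomic span with residue 1
at the high-coordinate end. Gene-map CDS spans are required to be codon
multiples; the packaged map therefore excludes the incomplete stop codons
that several mitochondrial genes complete by polyadenylation, a choice that
leaves every residue index used in the packaged analyses unchanged. Indels
parse but their consequences are not computed. Positions 8860 and 15326 are
held in a configurable exclusion list: they are private mutations of the
reference sequence itself and would otherwise appear in every haplotype.

The packaged genome is a *synthetic stand-in* for the human reference: the
true length and gene coordinates, with reference bases and full codons
planted at every position the packaged fixtures touch, and seeded random
sequence elsewhere (`tools/make_rcrs_fixture.R` regenerates it byte for
byte). Analyses of real data should substitute the real reference FASTA;
every function takes the genome as an argument.

## Independent origins on a reference phylogeny

The key phylogenetic argument is that a pathogenic variant recurs: carriers
share it by independent mutational events, not by descent. Given a rooted
tree whose branches carry mutation labels (two interchangeable dialects: an
indented-text format and Newick with bracketed annotations) and 0/1 carrier
states at the leaves, `countIndependentOrigins()` defaults to gains-only
(Camin–Sokal) parsimony: reversions are disallowed and the minimal number
of gains equals the number of maximal carrier-pure subtrees. This default
is deliberate. When a non-carrier control lineage is nested between two
carriers inside one clade, gains-only parsimony is forced to two
independent gains, which is precisely the design of including a control
sequence inside a carrier haplogroup; minimum-change parsimony with free
reversions could otherwise explain the pattern as one gain plus one loss.
The reversible mode (Sankoff minimum-change, reporting the gain count of
the gain-maximal most-parsimonious reconstruction, with a carrier-state
root counting as one origin) is available for sensitivity analysis. Each
gain is reported on the branch above the MRCA of the carriers it explains;
on a chain of single-descendant branches any placement is equally
parsimonious and the tipward-most is reported. Both modes are verified
against exhaustive enumeration of all internal labelings on random trees of
up to ten leaves.

Haplogroup assignment scores each named node by its accumulated
root-to-node motif: `matched − missing` expected mutations, with private
variants neither rewarded nor penalised (weight configurable); ties break
toward the less derived node. Because the packaged cohort encodes only
non-synonymous changes, haplogroups distinguished solely by synonymous or
control-region markers collapse onto their nearest marked ancestor — the
packaged tree documents this in its header, and it is why two haplogroup-U
samples attach to the tree as separate lineages, keeping their five-carrier
variant's independent origins recoverable from leaf states alone. A
carried variant is classified *ancient* when it lies on the assigned
haplogroup's defining path and *recent* (private) otherwise.

Clade enrichment divides the cohort fraction of target-clade members
(membership by subtree of the named node when the clade is in the tree,
name-prefix otherwise) by a user-supplied population frequency. The default
population frequency for the J1c+J2b computation, 6.2%, is the Western
European average reported in population surveys; it is a parameter, not a
constant.

## Conservation and the possibly-synergistic rules

Conservation profiles are computed from pre-aligned protein sets for three
taxon sets (eukaryotes, vertebrates, mammals); alignment construction and
database retrieval are out of scope. Columns map to residue positions
through the ungapped reference row. At each position the modal residue and
its prevalence are computed over non-gap rows. Choices the field's
conventions leave open, with the defaults taken here:

* **Gap handling.** Gaps are excluded from the denominator; positions with
  non-gap coverage below 0.5 of the rows are *indeterminate* (never
  silently unconserved) and cannot be invariant.
* **Reference row.** Included in the counts; it shifts estimates by at most
  1/n and keeps single-row edge cases well defined.
* **Threshold.** "Over the 70% threshold" is read strictly (`>`);
  a `strict = FALSE` switch gives `>=` for sensitivity analysis.
* **Modal ties.** Broken alphabetically, for determinism.

A variant position is **possibly synergistic** when any of three rules
fires on the chosen taxon set (mammals by default, since invariance in
mammals is the operative signal for these proteins): (1) prevalence over
the threshold; (2) the ±10-residue window around the position beats the
whole protein on *both* mean prevalence and conserved-position density —
densities (count ÷ length) rather than raw counts, because a 21-residue
window cannot be compared to a whole protein by count; windows truncate at
protein ends and keep their truncated length as denominator; (3) an
invariant (100%, adequately covered) position lies within ±4 residues —
distance at least 1, since a position that is itself invariant is already
caught by rule (1). All supporting numbers are returned with the decision.

## Evidence rubric

`evaluatePrimaryStatus()` combines per-variant evidence: (i) independent
origins ≥ 2; (ii) conservation — over threshold or, when the rubric admits
it, near-invariant (this is what lets a poorly conserved residue flanked by
invariant stretches satisfy the criterion); (iii) at most 2 carrier records
in population collections ("virtually absent"; the confirmed mutations show
0–2 matches in 10⁴-record collections); (iv) strict LHON association, with
carriers expressing extra-ocular phenotypes classified apart as LHON-plus
on clinical grounds, not inferred from the variant. Heteroplasmy (v) is
recorded as supporting evidence and never required. All four criteria give
"confirmed primary"; (ii)–(iv) with a single origin give "provisional".
The numeric cutoffs for (i) and (iii) are stated rubric defaults, flagged
as decisions in the report manifest and configurable. Origin counts may
include reported occurrences outside the analysed cohort
(`prior_occurrences` in the evidence table), since recurrence across
published pedigrees carries the same weight as recurrence within one
cohort.

## In-silico RFLP heteroplasmy

The wet-lab assay digests a PCR amplicon spanning the variant with an
enzyme whose site the variant creates or destroys, and quantifies band
intensities densitometrically. In silico: primers match exactly (assay
fixtures are designed unique; no mismatch tolerance), amplicons may wrap
the circular origin, recognition sites (IUPAC degeneracy allowed) are
searched on both strands with palindromic sites counted once, and each
site yields one duplex cut coordinate — staggered-end geometry cannot
change fragment lengths and is ignored. Fragment lengths always sum to the
amplicon length (asserted on every digest). Intensities follow the mass
model, intensity ∝ molarity × length, as ethidium staining scales with
mass; the estimator therefore converts each diagnostic band to molar units
(I/L) and reports the mutant share as a percentage. The model is a
documented choice and the estimator takes plain band tables, so other
models can be swapped in upstream. Gel-image processing is out of scope;
intensities arrive as numbers.

## Simulators and what passing tests show

Every analysis input can be generated with recorded truth, deterministic
under an integer seed (the caller's RNG state is restored):

* **Alignments** plant a per-position modal probability; non-modal residues
  are uniform over the remaining 19 amino acids — no substitution-matrix
  realism, which is immaterial because the conservation statistic depends
  only on modal prevalence.
* **Cohorts** evolve haplotypes down a known tree (Poisson background
  mutations per branch, floor one, positions drawn without global
  replacement so background recurrence cannot confound planted counts) and
  plant a focal variant on designated, pairwise non-nested branches. The
  recorded truth includes the parsimony-recoverable origin count, which can
  fall below the planted count when planted branches jointly cover a whole
  clade.
* **Populations** plant exact carrier counts among records with independent
  background variants at disjoint positions.
* **Gels** draw band intensities as molarity × length × lognormal noise.

Simulated data emulate the *structure* of the real inputs, not their
biology: no molecular clock, selection, rate heterogeneity, alignment
error, or gel artefacts. Tests passing on simulations therefore validate
the estimators and counting algorithms, not the upstream measurement
processes. Likewise, published per-position conservation percentages
depend on the protein-database snapshot they were computed from and are
consumed here as inputs rather than recomputed; the conservation engine is
instead validated by exact agreement with brute-force counting and by
recovery of planted modal probabilities within three binomial standard
errors at n = 500 rows.

Problem sizes used by the test-suite: parsimony oracles on 400 random
trees of 3–10 leaves per mode; 100 seeded alignment replicates at n = 500
rows for prevalence recovery; 200 seeded gel replicates at a 41% planted
mutant load (estimates within ±5 percentage points, matching the
resolution one expects of densitometric quantification); 200 seeded cohort
replicates for haplogroup recovery. These sizes give stable pass/fail
behaviour at interactive runtimes.

## Known limitations

* Indel consequences and incomplete stop codons are not modelled.
* The haplogroup scorer matches motifs on a user-supplied tree; it does not
  ship or maintain the full published human mtDNA phylogeny.
* Population-rarity evidence is only as strong as the collection searched;
  an empty collection returns zero with a warning to that effect.
* The synthetic reference genome supports every packaged analysis exactly,
  but real-data work must supply the real reference sequence.

## Session info

```{r}
sessionInfo()
```
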