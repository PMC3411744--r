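Package: mtLHON
Title: Classification of Rare Mitochondrial DNA Variants as Primary LHON Mutations
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether rare mitochondrial DNA variants found in
    Leber's hereditary optic neuropathy (LHON) probands are primary pathogenic
    mutations and whether background polymorphisms are possibly synergistic.
    Implements variant parsing and annotation against the mitochondrial reference
    frame under the vertebrate mitochondrial genetic code, haplogroup assignment by
    motif matching, counting of independent mutational origins on a reference
    phylogeny by gains-only (Camin-Sokal) and reversible parsimony, per-residue
    interspecies conservation scoring with threshold, local-window and
    invariant-proximity rules, an evidence rubric aggregating origins, conservation,
    population rarity, disease association and heteroplasmy, and an in-silico
    PCR-RFLP assay with densitometric heteroplasmy estimation. Ships simulators for
    alignments, cohorts evolved on known trees, population collections and gel
    band intensities, each with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
biocViews: Genetics, SNP, Phylogenetics, SequenceMatching, VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'parse.R'
    'genome.R'
    'conservation.R'
    'phylo.R'
    'evidence.R'
    'io.R'
    'mtLHON-package.R'
    'rflp.R'
    'simulate.R'
    'workflow.R'
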