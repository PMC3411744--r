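#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

#' A single mitochondrial DNA variant
#'
#' One difference from the mitochondrial reference frame: a substitution,
#' insertion or deletion at a 1-based position on the circular genome.
#' Substitutions written in the shorthand branch dialect without an explicit
#' base are transitions by convention; resolving the implied reference and
#' alternate base requires the genome (see [parseVariantLabel()]).
#'
#' @slot position 1-based coordinate on the circular reference.
#' @slot ref reference base (`NA` while unresolved).
#' @slot alt alternate base, or inserted/deleted bases for indels (`NA` while
#'   unresolved, or for deletions written without bases).
#' @slot kind one of `"transition"`, `"transversion"`, `"insertion"`,
#'   `"deletion"`.
#' @slot isReversion `TRUE` for back mutations (prefix `@`).
#' @slot isHeteroplasmic `TRUE` when the label carries the `h` suffix.
#' @slot locusHint optional locus annotation from the `~t`/`~r` suffixes.
#' @slot effectHint optional `s`/`ns` effect annotation.
#' @slot resolved `FALSE` when a shorthand transition was parsed without a
#'   genome, so `ref`/`alt` are still unknown.
#' @export
setClass("MitoVariant",
  representation(position = "integer", ref = "character", alt = "character",
                 kind = "character", isReversion = "logical",
                 isHeteroplasmic = "logical", locusHint = "character",
                 effectHint = "character", resolved = "logical"))

setValidity("MitoVariant", function(object) {
  msg <- NULL
  if (length(object@position) != 1L || is.na(object@position) ||
      object@position < 1L)
    msg <- c(msg, "position must be a single positive integer")
  if (!object@kind %in% c("transition", "transversion", "insertion", "deletion"))
    msg <- c(msg, "unknown variant kind")
  if (object@resolved && object@kind %in% c("transition", "transversion")) {
    if (is.na(object@ref) || is.na(object@alt))
      msg <- c(msg, "resolved substitution must carry ref and alt")
    else if (object@ref == object@alt)
      msg <- c(msg, "ref and alt must differ for a substitution")
    else if (classifySubstitution(object@ref, object@alt) != object@kind)
      msg <- c(msg, "kind inconsistent with ref/alt bases")
  }
  if (is.null(msg)) TRUE else msg
})

#' Mitochondrial reference genome with gene map
#'
#' Bundles the circular reference sequence, the gene map (a [GenomicRanges::GRanges]
#' with `gene` and `product` metadata columns; 1-based inclusive coordinates,
#' light-strand genes on `-`), the control-region bounds and the list of
#' reference-private positions excluded from haplotype comparisons.
#'
#' @slot seq a [Biostrings::DNAString], the heavy-strand sequence.
#' @slot geneMap a `GRanges` with `gene` and `product` columns.
#' @slot controlRegionStart,controlRegionEnd the control region spans the
#'   circular origin: positions `>= controlRegionStart` or `<= controlRegionEnd`.
#' @slot excludedPositions positions treated as private mutations of the
#'   reference itself, dropped when comparing haplotypes to it.
#' @export
setClass("MitoGenome",
  representation(seq = "ANY", geneMap = "ANY",
                 controlRegionStart = "integer", controlRegionEnd = "integer",
                 excludedPositions = "integer"))

#' Protein-level consequence of a variant
#'
#' Returned by [annotateProteinChange()].  `consequence` is one of
#' `"missense"`, `"synonymous"`, `"noncoding"` or `"indel"`; residue fields are
#' populated for coding substitutions only.  Missense changes print as
#' `p.<ref><index><alt>`, e.g. `p.A132T`.
#'
#' @export
setClass("ProteinChange",
  representation(gene = "character", residueIndex = "integer",
                 refAA = "character", altAA = "character",
                 codonPosition = "integer", consequence = "character",
                 locusType = "character"))

#' A sample's haplotype as differences from the reference
#'
#' @slot sampleId sample identifier.
#' @slot variants list of [MitoVariant-class] objects (exclusion list already
#'   applied).
#' @slot rareVariants canonical keys of the variants designated rare
#'   disease-candidate mutations for this sample (the bold entries of a cohort
#'   table), a subset of `variants`.
#' @slot phenotype one of `affected`, `unaffected`, `control`, `unknown`.
#' @slot origin free-text geographic origin.
#' @export
setClass("HaplotypeProfile",
  representation(sampleId = "character", variants = "list",
                 rareVariants = "character", phenotype = "character",
                 origin = "character"))

setValidity("HaplotypeProfile", function(object) {
  keys <- vapply(object@variants, variantKey, character(1))
  if (anyDuplicated(keys))
    return("duplicate variants (same position and alternate base)")
  TRUE
})

#' Reference phylogeny with branch mutations
#'
#' A rooted tree stored as a parent vector.  Each node carries the mutations of
#' its incoming branch (raw labels plus canonical keys) and optionally a
#' haplogroup name; leaves are nodes without children and represent samples
#' when the tree encodes a cohort.
#'
#' @slot label node labels (sample ids at leaves).
#' @slot parent parent index per node (`NA` at the root).
#' @slot haplogroup haplogroup name per node (`NA` when unnamed).
#' @slot mutations list of raw branch-mutation labels per node.
#' @slot mutationKeys list of canonical keys parallel to `mutations`.
#' @export
setClass("MitoPhylo",
  representation(label = "character", parent = "integer",
                 haplogroup = "character", mutations = "list",
                 mutationKeys = "list"))

setValidity("MitoPhylo", function(object) {
  n <- length(object@label)
  if (length(object@parent) != n || length(object@haplogroup) != n ||
      length(object@mutations) != n || length(object@mutationKeys) != n)
    return("slot lengths differ")
  if (sum(is.na(object@parent)) != 1L)
    return("exactly one root (parent NA) required")
  hg <- object@haplogroup[!is.na(object@haplogroup)]
  if (anyDuplicated(hg))
    return("haplogroup names must be unique")
  # every node reaches the root
  root <- which(is.na(object@parent))
  for (i in seq_len(n)) {
    seen <- integer(0); j <- i
    while (!is.na(object@parent[j])) {
      if (j %in% seen) return("cycle in parent vector")
      seen <- c(seen, j); j <- object@parent[j]
    }
    if (j != root) return("node not reachable from root")
  }
  TRUE
})

#' Count of independent mutational origins
#'
#' Result of [countIndependentOrigins()]: the minimal number of separate
#' acquisitions of a variant on a reference phylogeny, with the branches
#' (named by their child node) carrying them.
#'
#' @export
setClass("OriginCount",
  representation(variant = "character", nOrigins = "integer",
                 originBranches = "character", mode = "character"))

setValidity("OriginCount", function(object) {
  if (length(object@originBranches) != object@nOrigins)
    return("nOrigins must equal the number of origin branches")
  TRUE
})

#' Pre-aligned protein sequences for one taxon set
#'
#' @slot aln a [Biostrings::AAStringSet] of equal-width aligned rows.
#' @slot referenceRow name of the human reference row.
#' @slot taxonSet one of `eukaryotes`, `vertebrates`, `mammals`.
#' @export
setClass("TaxonAlignment",
  representation(aln = "ANY", referenceRow = "character",
                 taxonSet = "character"))

#' Per-residue conservation profile
#'
#' One row per ungapped position of the reference row: the modal residue among
#' non-gap rows, its prevalence as a percentage of non-gap rows, the number of
#' rows counted, a low-coverage flag and invariant status (prevalence 100 at
#' adequate coverage).  Classification parameters travel with the profile.
#'
#' @export
setClass("ConservationProfile",
  representation(data = "data.frame", taxonSet = "character", params = "list"))

#' Synergy classification of a polymorphic variant
#'
#' Decision from [classifySynergistic()]: a variant is possibly synergistic if
#' its position is over the conservation threshold, sits in a window more
#' conserved than the whole protein, or lies within the proximity radius of an
#' invariant position.
#'
#' @export
setClass("SynergyDecision",
  representation(position = "integer", overThreshold = "logical",
                 localExceedsGlobal = "logical", nearInvariant = "logical",
                 possiblySynergistic = "logical", support = "list"))

#' Evidence rubric for primary-mutation status
#'
#' Thresholds for the classification criteria: minimum independent origins,
#' maximum carrier records in population collections, the conservation rule
#' (over-threshold or near-invariant), and whether strict disease association
#' is required.  Heteroplasmy is reported as supporting evidence, never
#' required.
#'
#' @export
setClass("EvidenceRubric",
  representation(minOrigins = "integer", maxPopulationMatches = "integer",
                 conservationRule = "character",
                 requireStrictAssociation = "logical"))

#' Aggregated per-variant evidence
#'
#' @slot variant canonical variant label.
#' @slot nOrigins independent origins (phylogeny-derived plus any prior
#'   occurrences supplied).
#' @slot conservation named numeric of per-taxon-set prevalences (percent).
#' @slot nearInvariant `TRUE` when the residue lies within the proximity
#'   radius of an invariant position (`NA` when unknown).
#' @slot populationMatches carrier records in the consulted collection.
#' @slot heteroplasmy list of observations (sample, tissue, fraction/state).
#' @slot association `"strict"`, `"lhon_plus"` or `"none"`.
#' @slot predictors optional list with `polyphen2` and `sift` class labels.
#' @export
setClass("VariantDossier",
  representation(variant = "character", nOrigins = "integer",
                 conservation = "numeric", nearInvariant = "logical",
                 populationMatches = "integer", heteroplasmy = "list",
                 association = "character", predictors = "list"))

#' Restriction enzyme definition
#'
#' `recognition` may use IUPAC degeneracy codes; `cutOffset` is the number of
#' top-strand bases of the site left of the duplex cut (`G^AATTC` has offset
#' 1).  Staggered-end geometry is irrelevant to fragment lengths and is
#' ignored.
#'
#' @export
setClass("RestrictionEnzyme",
  representation(name = "character", recognition = "character",
                 cutOffset = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- NULL
  if (nchar(object@recognition) < 4L)
    msg <- c(msg, "recognition site must be at least 4 bp")
  if (object@cutOffset < 0L || object@cutOffset > nchar(object@recognition))
    msg <- c(msg, "cut offset must lie within the recognition site")
  if (is.null(msg)) TRUE else msg
})

#' Fragments of one allele's digest
#'
#' Ordered fragment lengths along the amplicon; they always sum to the
#' amplicon length.
#'
#' @export
setClass("DigestResult",
  representation(allele = "character", fragments = "integer",
                 ampliconLength = "integer"))

setValidity("DigestResult", function(object) {
  if (sum(object@fragments) != object@ampliconLength)
    return("fragment lengths must sum to the amplicon length")
  TRUE
})
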