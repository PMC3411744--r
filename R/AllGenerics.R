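#' @include AllClasses.R
NULL

#' Accessors for mtLHON classes
#'
#' Small accessor generics: slot access from user code should go through
#' these rather than `@`.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantPosition", function(x) standardGeneric("variantPosition"))
#' @rdname accessors
#' @export
setGeneric("refBase", function(x) standardGeneric("refBase"))
#' @rdname accessors
#' @export
setGeneric("altBase", function(x) standardGeneric("altBase"))
#' @rdname accessors
#' @export
setGeneric("variantKind", function(x) standardGeneric("variantKind"))
#' @rdname accessors
#' @export
setGeneric("isReversion", function(x) standardGeneric("isReversion"))
#' @rdname accessors
#' @export
setGeneric("isHeteroplasmic", function(x) standardGeneric("isHeteroplasmic"))
#' @rdname accessors
#' @export
setGeneric("isResolved", function(x) standardGeneric("isResolved"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("geneMap", function(x) standardGeneric("geneMap"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("excludedPositions", function(x) standardGeneric("excludedPositions"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("haplotypeVariants", function(x) standardGeneric("haplotypeVariants"))
#' @rdname accessors
#' @export
setGeneric("rareVariants", function(x) standardGeneric("rareVariants"))
#' @rdname accessors
#' @export
setGeneric("nOrigins", function(x) standardGeneric("nOrigins"))
#' @rdname accessors
#' @export
setGeneric("originBranches", function(x) standardGeneric("originBranches"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("profileData", function(x) standardGeneric("profileData"))
#' @rdname accessors
#' @export
setGeneric("taxonSet", function(x) standardGeneric("taxonSet"))
#' @rdname accessors
#' @export
setGeneric("possiblySynergistic", function(x) standardGeneric("possiblySynergistic"))

#' Canonical serialisations
#'
#' `variantLabel` renders a [MitoVariant-class] either in the shorthand branch
#' dialect (`style = "short"`, e.g. `"14482A"`, `"@263"`) or in HGVS-like form
#' (`style = "hgvs"`, e.g. `"m.14482C>A"`; requires a resolved variant).
#' `variantKey` returns the canonical matching key used to compare variants
#' across haplotypes, branches and population records: heteroplasmy and
#' effect/locus hints are dropped, so labels differing only in those collapse.
#'
#' @param x a `MitoVariant`.
#' @param style `"short"` or `"hgvs"`.
#' @export
setGeneric("variantLabel", function(x, style = c("short", "hgvs"))
  standardGeneric("variantLabel"))

#' @rdname variantLabel
#' @export
setGeneric("variantKey", function(x) standardGeneric("variantKey"))

#' @rdname accessors
#' @export
setGeneric("proteinLabel", function(x) standardGeneric("proteinLabel"))

# -- accessor methods -------------------------------------------------------

#' @rdname accessors
setMethod("variantPosition", "MitoVariant", function(x) x@position)
#' @rdname accessors
setMethod("refBase", "MitoVariant", function(x) x@ref)
#' @rdname accessors
setMethod("altBase", "MitoVariant", function(x) x@alt)
#' @rdname accessors
setMethod("variantKind", "MitoVariant", function(x) x@kind)
#' @rdname accessors
setMethod("isReversion", "MitoVariant", function(x) x@isReversion)
#' @rdname accessors
setMethod("isHeteroplasmic", "MitoVariant", function(x) x@isHeteroplasmic)
#' @rdname accessors
setMethod("isResolved", "MitoVariant", function(x) x@resolved)

#' @rdname accessors
setMethod("genomeSeq", "MitoGenome", function(x) x@seq)
#' @rdname accessors
setMethod("geneMap", "MitoGenome", function(x) x@geneMap)
#' @rdname accessors
setMethod("genomeLength", "MitoGenome", function(x) length(x@seq))
#' @rdname accessors
setMethod("excludedPositions", "MitoGenome", function(x) x@excludedPositions)

#' @rdname accessors
setMethod("sampleId", "HaplotypeProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("haplotypeVariants", "HaplotypeProfile", function(x) x@variants)
#' @rdname accessors
setMethod("rareVariants", "HaplotypeProfile", function(x) x@rareVariants)

#' @rdname accessors
setMethod("nOrigins", "OriginCount", function(x) x@nOrigins)
#' @rdname accessors
setMethod("originBranches", "OriginCount", function(x) x@originBranches)

#' @rdname accessors
setMethod("fragments", "DigestResult", function(x) x@fragments)

#' @rdname accessors
setMethod("profileData", "ConservationProfile", function(x) x@data)
#' @rdname accessors
setMethod("taxonSet", "ConservationProfile", function(x) x@taxonSet)
#' @rdname accessors
setMethod("taxonSet", "TaxonAlignment", function(x) x@taxonSet)
#' @rdname accessors
setMethod("possiblySynergistic", "SynergyDecision",
          function(x) x@possiblySynergistic)

# -- show methods -----------------------------------------------------------

setMethod("show", "MitoVariant", function(object) {
  lab <- if (object@resolved &&
             object@kind %in% c("transition", "transversion"))
    variantLabel(object, "hgvs") else variantLabel(object, "short")
  cat("MitoVariant ", lab, " [", object@kind,
      if (object@isHeteroplasmic) ", heteroplasmic" else "",
      if (object@isReversion) ", reversion" else "",
      if (!object@resolved) ", unresolved" else "", "]\n", sep = "")
})

setMethod("show", "MitoGenome", function(object) {
  cat("MitoGenome of length", length(object@seq), "bp with",
      length(object@geneMap), "gene-map entries\n")
})

setMethod("show", "ProteinChange", function(object) {
  if (object@consequence == "missense")
    cat("ProteinChange", object@gene, proteinLabel(object),
        sprintf("(codon position %d)\n", object@codonPosition))
  else if (object@consequence == "synonymous")
    cat("ProteinChange", object@gene, "synonymous at residue",
        object@residueIndex, "\n")
  else cat("ProteinChange:", object@consequence,
           if (!is.na(object@locusType)) paste0("(", object@locusType, ")"),
           "\n")
})

setMethod("show", "HaplotypeProfile", function(object) {
  cat("HaplotypeProfile", object@sampleId, "with",
      length(object@variants), "variants (",
      length(object@rareVariants), "rare )\n")
})

setMethod("show", "MitoPhylo", function(object) {
  leaves <- sum(!seq_along(object@parent) %in% object@parent)
  cat("MitoPhylo with", length(object@label), "nodes (", leaves, "leaves ),",
      sum(lengths(object@mutations)), "branch mutations\n")
})

setMethod("show", "OriginCount", function(object) {
  cat("OriginCount:", object@variant, "arose", object@nOrigins,
      "time(s) [", object@mode, "] on branches:",
      paste(object@originBranches, collapse = ", "), "\n")
})

setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile (", object@taxonSet, "):",
      nrow(object@data), "positions,",
      sum(object@data$invariant), "invariant\n")
})

setMethod("show", "SynergyDecision", function(object) {
  cat("SynergyDecision at position", object@position, ":",
      if (isTRUE(object@possiblySynergistic)) "possibly synergistic"
      else "not synergistic",
      sprintf("(threshold=%s, window=%s, proximity=%s)\n",
              object@overThreshold, object@localExceedsGlobal,
              object@nearInvariant))
})

setMethod("show", "EvidenceRubric", function(object) {
  cat("EvidenceRubric: origins >=", object@minOrigins,
      "; population matches <=", object@maxPopulationMatches,
      "; conservation rule:", object@conservationRule,
      "; strict association", if (object@requireStrictAssociation)
        "required" else "optional", "\n")
})

setMethod("show", "VariantDossier", function(object) {
  cat("VariantDossier", object@variant, ": origins =", object@nOrigins,
      ", population matches =", object@populationMatches,
      ", association =", object@association, "\n")
})

setMethod("show", "DigestResult", function(object) {
  cat("DigestResult (", object@allele, "):",
      paste(object@fragments, collapse = " + "), "bp\n")
})

setMethod("show", "RestrictionEnzyme", function(object) {
  cat("RestrictionEnzyme", object@name, object@recognition,
      "cut offset", object@cutOffset, "\n")
})

#' @rdname accessors
setMethod("proteinLabel", "ProteinChange", function(x) {
  if (x@consequence != "missense")
    stop("protein label is defined for missense changes only")
  sprintf("p.%s%d%s", x@refAA, x@residueIndex, x@altAA)
})
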