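#' @include phylo.R
NULL

#' Construct an evidence rubric
#'
#' Defaults reflect how confirmed primary mutations behave in practice: at
#' least two independent origins, at most two carrier records in large
#' population collections ("virtually absent"), conservation satisfied either
#' by the over-threshold rule or by invariant proximity, and strict disease
#' association required.  Heteroplasmy is supporting evidence only.
#'
#' @param minOrigins minimum independent origins for confirmed status.
#' @param maxPopulationMatches maximum carrier records tolerated.
#' @param conservationRule `"threshold_or_near_invariant"` or
#'   `"threshold_only"`.
#' @param requireStrictAssociation require strict disease association.
#' @export
evidenceRubric <- function(minOrigins = 2L, maxPopulationMatches = 2L,
                           conservationRule = c("threshold_or_near_invariant",
                                                "threshold_only"),
                           requireStrictAssociation = TRUE) {
  conservationRule <- match.arg(conservationRule)
  if (minOrigins < 1L || maxPopulationMatches < 0L)
    stop("rubric thresholds must be positive")
  new("EvidenceRubric", minOrigins = as.integer(minOrigins),
      maxPopulationMatches = as.integer(maxPopulationMatches),
      conservationRule = conservationRule,
      requireStrictAssociation = requireStrictAssociation)
}

#' Assemble a per-variant evidence dossier
#'
#' @param variant canonical variant label (e.g. `"m.3700G>A"`).
#' @param nOrigins independent origins (phylogeny-derived, plus any prior
#'   occurrences outside the analysed cohort).
#' @param conservation named numeric of prevalences (percent) per taxon set;
#'   must include `mammals`.
#' @param populationMatches carrier records in the consulted collection.
#' @param association `"strict"`, `"lhon_plus"` or `"none"`.
#' @param nearInvariant `TRUE` when the residue lies near an invariant
#'   position (`NA` when not assessed).
#' @param heteroplasmy list of observations, each a list with `sample` and
#'   `fraction` (percent) or `state`.
#' @param predictors optional list with `polyphen2` and `sift` labels.
#' @export
variantDossier <- function(variant, nOrigins, conservation,
                           populationMatches, association,
                           nearInvariant = NA, heteroplasmy = list(),
                           predictors = list()) {
  for (obs in heteroplasmy) {
    if (!is.null(obs$fraction) &&
        (obs$fraction < 0 || obs$fraction > 100))
      stop("heteroplasmic mutant fractions must lie in [0, 100] percent")
  }
  new("VariantDossier", variant = variant, nOrigins = as.integer(nOrigins),
      conservation = conservation, nearInvariant = nearInvariant,
      populationMatches = as.integer(populationMatches),
      heteroplasmy = heteroplasmy, association = association,
      predictors = predictors)
}

#' Count carrier records of a variant in a population collection
#'
#' Counts records carrying the exact nucleotide change (same position and
#' alternate base, heteroplasmy flags ignored).  The collection must be in
#' the same reference frame as the variant, with the exclusion list applied.
#'
#' @param variant a [MitoVariant-class] or label.
#' @param collection list of [HaplotypeProfile-class] objects, or a list of
#'   character vectors of labels.
#' @param genome optional genome for label resolution.
#' @return integer count.
#' @export
countPopulationMatches <- function(variant, collection, genome = NULL) {
  if (is.character(variant)) variant <- parseVariantLabel(variant, genome)
  key <- variantKey(variant)
  if (!length(collection)) {
    warning("empty population collection: absence evidence is weak")
    return(0L)
  }
  hits <- vapply(collection, function(rec) {
    keys <- .haplotype_keys(rec, genome)
    key %in% keys
  }, logical(1))
  sum(hits)
}

#' Evaluate primary-mutation status from a dossier
#'
#' Applies the classification criteria: (i) multiple independent origins on
#' different backgrounds; (ii) conservation of the affected residue (over
#' threshold, or near an invariant position when the rubric admits it);
#' (iii) virtual absence from population collections; (iv) strict disease
#' association.  Heteroplasmy (v) is reported as supporting evidence, never
#' required.
#'
#' Classifications: `"confirmed primary"` when (i)-(iv) all hold;
#' `"provisional"` when (ii)-(iv) hold but the variant has arisen only once;
#' `"LHON-plus"` when the carrier phenotype extends beyond isolated optic
#' neuropathy; otherwise `"polymorphism/non-primary"`.
#'
#' @param dossier a [VariantDossier-class].
#' @param rubric an [EvidenceRubric-class].
#' @param thresholdPercent conservation threshold (percent) for criterion (ii).
#' @return list with `classification` and `satisfied` (named logical of
#'   criteria), plus `supporting` notes.
#' @export
evaluatePrimaryStatus <- function(dossier, rubric = evidenceRubric(),
                                  thresholdPercent = 70) {
  for (field in c("nOrigins", "populationMatches", "association")) {
    if (!length(slot(dossier, field)) || anyNA(slot(dossier, field)))
      stop("incomplete dossier: missing field '", field, "'")
  }
  if (!"mammals" %in% names(dossier@conservation))
    stop("incomplete dossier: missing field 'conservation[mammals]'")

  mam <- dossier@conservation[["mammals"]]
  consOK <- mam > thresholdPercent
  if (rubric@conservationRule == "threshold_or_near_invariant")
    consOK <- consOK || isTRUE(dossier@nearInvariant)

  crit <- c(
    origins = dossier@nOrigins >= rubric@minOrigins,
    conservation = consOK,
    rarity = dossier@populationMatches <= rubric@maxPopulationMatches,
    association = if (rubric@requireStrictAssociation)
      dossier@association == "strict" else dossier@association != "none")
  heteroplasmic <- length(dossier@heteroplasmy) > 0L

  classification <-
    if (dossier@association == "lhon_plus") "LHON-plus"
    else if (all(crit)) "confirmed primary"
    else if (crit[["conservation"]] && crit[["rarity"]] &&
             crit[["association"]] && dossier@nOrigins == 1L) "provisional"
    else "polymorphism/non-primary"

  list(classification = classification, satisfied = crit,
       supporting = list(heteroplasmic = heteroplasmic,
                         nHeteroplasmyObservations = length(dossier@heteroplasmy),
                         mammalsPrevalence = mam,
                         nearInvariant = dossier@nearInvariant))
}

.PP2_CLASSES <- c("benign", "possibly damaging", "probably damaging")
.SIFT_CLASSES <- c("tolerated", "not tolerated")

#' Concordance of in-silico pathogenicity predictors
#'
#' A variant is flagged by PolyPhen2 when classed possibly or probably
#' damaging, and by SIFT when classed not tolerated.  Percentages are rounded
#' to the nearest integer for reporting.
#'
#' @param labels data.frame with columns `polyphen2` and `sift` (class labels,
#'   case-insensitive).
#' @return list with `nFlaggedByBoth`, `nFlaggedByAtLeastOne`, `percentBoth`,
#'   `n`.
#' @export
predictorConcordance <- function(labels) {
  if (!all(c("polyphen2", "sift") %in% names(labels)))
    stop("labels must have columns 'polyphen2' and 'sift'")
  if (!nrow(labels))
    return(list(nFlaggedByBoth = 0L, nFlaggedByAtLeastOne = 0L,
                percentBoth = 0L, n = 0L))
  pp2 <- tolower(trimws(labels$polyphen2))
  sift <- tolower(trimws(labels$sift))
  if (!all(pp2 %in% .PP2_CLASSES))
    stop("unknown PolyPhen2 class token(s): ",
         paste(unique(pp2[!pp2 %in% .PP2_CLASSES]), collapse = ", "))
  if (!all(sift %in% .SIFT_CLASSES))
    stop("unknown SIFT class token(s): ",
         paste(unique(sift[!sift %in% .SIFT_CLASSES]), collapse = ", "))
  fp <- pp2 %in% c("possibly damaging", "probably damaging")
  fs <- sift == "not tolerated"
  both <- sum(fp & fs); either <- sum(fp | fs)
  list(nFlaggedByBoth = as.integer(both),
       nFlaggedByAtLeastOne = as.integer(either),
       percentBoth = as.integer(round(100 * both / nrow(labels))),
       n = nrow(labels))
}

#' Summarise a cohort of haplotype profiles
#'
#' Counts probands and distinct rare mutations (different substitutions at
#' the same position count separately), lists carriers per rare mutation and
#' tallies haplogroups.
#'
#' @param cohort list of [HaplotypeProfile-class] objects.
#' @param haplogroups optional named character of per-sample haplogroup
#'   names (from the cohort table or from [assignHaplogroup()]).
#' @return list with `nProbands`, `nDistinctRare`, `rareCarriers` (named list
#'   key -> sample ids), `haplogroupTally`.
#' @export
summarizeCohort <- function(cohort, haplogroups = NULL) {
  ids <- vapply(cohort, sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  rare <- lapply(cohort, rareVariants)
  keys <- sort(unique(unlist(rare)))
  carriers <- lapply(keys, function(k) ids[vapply(rare, function(r) k %in% r,
                                                  logical(1))])
  names(carriers) <- keys
  list(nProbands = length(cohort),
       nDistinctRare = length(keys),
       rareCarriers = carriers,
       haplogroupTally = if (!is.null(haplogroups))
         table(haplogroups[ids]) else NULL)
}
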