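#' @include io.R simulate.R
NULL

# "-" -> none; "+ (41%)" / "-/+ (60-90%)" / "-/+" -> observations
.parse_heteroplasmy <- function(s) {
  if (is.na(s) || !nzchar(trimws(s)) || trimws(s) == "-") return(list())
  pct <- regmatches(s, gregexpr("[0-9.]+(?=%)", s, perl = TRUE))[[1]]
  if (length(pct))
    lapply(as.numeric(pct), function(p) list(state = "heteroplasmic",
                                             fraction = p))
  else list(list(state = "heteroplasmic"))
}

.truthy <- function(x) {
  !is.na(x) & tolower(trimws(as.character(x))) %in%
    c("yes", "true", "1", "y")
}

#' Run the full cohort analysis
#'
#' Orchestrates all stages on file inputs: parses the genome, cohort and
#' reference phylogeny, summarises the cohort, counts independent origins of
#' every rare mutation on the phylogeny, computes haplogroup enrichment
#' against a population frequency, evaluates predictor concordance, and
#' classifies each rare mutation under the evidence rubric.  The run is
#' fully deterministic: identical inputs give an identical report.
#'
#' @param cohortFile cohort variant table (see [readCohort()]).
#' @param treeFile reference phylogeny (see [parsePhylogeny()]).
#' @param genomeFile reference genome FASTA.
#' @param geneMapFile gene-map TSV.
#' @param predictorFile optional predictor/evidence table
#'   (see [readPredictorTable()]).
#' @param targetClades haplogroup clades for the enrichment computation.
#' @param populationFrequency their combined general-population frequency.
#' @param rubric an [EvidenceRubric-class].
#' @param includePriorOccurrences add the table's `prior_occurrences`
#'   (independent occurrences reported outside this cohort) to the
#'   tree-derived origin counts when evaluating the rubric.
#' @param originMode parsimony mode for [countIndependentOrigins()].
#' @return a report list with elements `manifest`, `nProbands`,
#'   `nDistinctRare`, `rareMutations` (per-mutation carriers, origin counts,
#'   protein consequence, classification), `haplogroupTally`, `enrichment`,
#'   and `predictorConcordance`.
#' @examples
#' rep <- runFullAnalysis(
#'   cohortFile = mtFixture("lhon_cohort.tsv"),
#'   treeFile = mtFixture("lhon_cohort_tree.txt"),
#'   genomeFile = mtFixture("rcrs_synthetic.fasta"),
#'   geneMapFile = mtFixture("rcrs_genemap.tsv"),
#'   predictorFile = mtFixture("lhon_evidence_table.tsv"))
#' rep$nProbands
#' @export
runFullAnalysis <- function(cohortFile, treeFile, genomeFile, geneMapFile,
                            predictorFile = NULL,
                            targetClades = c("J1c", "J2b"),
                            populationFrequency = 0.062,
                            rubric = evidenceRubric(),
                            includePriorOccurrences = TRUE,
                            originMode = "irreversible") {
  genome <- readMitoGenome(genomeFile, geneMapFile)
  cohort <- readCohort(cohortFile, genome)
  haplogroups <- attr(cohort, "haplogroups")
  phylo <- parsePhylogeny(treeFile, genome)
  predictors <- if (!is.null(predictorFile)) readPredictorTable(predictorFile)

  summary <- summarizeCohort(cohort, haplogroups)
  ids <- vapply(cohort, sampleId, character(1))
  treeLeaves <- leafLabels(phylo)
  if (!all(ids %in% treeLeaves))
    stop("stage 'origins' failed: cohort sample(s) absent from the tree: ",
         paste(setdiff(ids, treeLeaves), collapse = ", "))

  rareMutations <- lapply(names(summary$rareCarriers), function(key) {
    carriers <- summary$rareCarriers[[key]]
    # recover the variant object from any carrier
    prof <- cohort[[match(carriers[1], ids)]]
    v <- prof@variants[[match(key, .haplotype_keys(prof))]]
    states <- stats::setNames(treeLeaves %in% carriers, treeLeaves)
    oc <- countIndependentOrigins(phylo, states, mode = originMode,
                                  variant = variantLabel(v, "hgvs"))
    pc <- annotateProteinChange(v, genome)
    entry <- list(key = key, label = variantLabel(v, "hgvs"),
                  gene = pc@gene,
                  proteinChange = if (pc@consequence == "missense")
                    proteinLabel(pc) else pc@consequence,
                  carriers = carriers, nCarriers = length(carriers),
                  nOriginsCohort = nOrigins(oc),
                  originBranches = originBranches(oc))
    if (!is.null(predictors)) {
      row <- match(entry$label, predictors$mutation)
      if (!is.na(row)) {
        prior <- if (includePriorOccurrences &&
                     "prior_occurrences" %in% names(predictors))
          predictors$prior_occurrences[row] else 0L
        dossier <- variantDossier(
          variant = entry$label,
          nOrigins = nOrigins(oc) + prior,
          conservation = c(
            eukaryotes = predictors$cons_eukaryotes[row],
            vertebrates = predictors$cons_vertebrates[row],
            mammals = predictors$cons_mammals[row]),
          populationMatches = predictors$matches_genbank[row],
          association = if ("association" %in% names(predictors))
            predictors$association[row] else "strict",
          nearInvariant = if ("near_invariant" %in% names(predictors))
            .truthy(predictors$near_invariant[row]) else NA,
          heteroplasmy = .parse_heteroplasmy(
            if ("heteroplasmy" %in% names(predictors))
              predictors$heteroplasmy[row] else NA_character_),
          predictors = list(polyphen2 = predictors$polyphen2[row],
                            sift = predictors$sift[row]))
        ev <- evaluatePrimaryStatus(dossier, rubric)
        entry$nOriginsTotal <- dossier@nOrigins
        entry$populationMatches <- dossier@populationMatches
        entry$classification <- ev$classification
        entry$criteria <- as.list(ev$satisfied)
        entry$heteroplasmic <- ev$supporting$heteroplasmic
      }
    }
    entry
  })
  names(rareMutations) <- vapply(rareMutations, `[[`, character(1), "label")

  enrichment <- if (!is.null(haplogroups))
    haplogroupEnrichment(unname(haplogroups[ids]), targetClades,
                         populationFrequency, phylo)
  concordance <- if (!is.null(predictors)) predictorConcordance(predictors)

  list(
    manifest = list(
      inputs = list(cohort = cohortFile, tree = treeFile,
                    genome = genomeFile, geneMap = geneMapFile,
                    predictors = predictorFile),
      parameters = list(targetClades = targetClades,
                        populationFrequency = populationFrequency,
                        originMode = originMode,
                        includePriorOccurrences = includePriorOccurrences,
                        rubric = list(
                          minOrigins = rubric@minOrigins,
                          maxPopulationMatches = rubric@maxPopulationMatches,
                          conservationRule = rubric@conservationRule,
                          requireStrictAssociation =
                            rubric@requireStrictAssociation)),
      version = as.character(utils::packageVersion("mtLHON"))),
    nProbands = summary$nProbands,
    nDistinctRare = summary$nDistinctRare,
    rareMutations = rareMutations,
    haplogroupTally = if (!is.null(summary$haplogroupTally))
      as.list(summary$haplogroupTally),
    enrichment = enrichment,
    predictorConcordance = concordance)
}

#' Write an analysis report
#'
#' Writes the machine-readable JSON report (full precision) and a
#' tab-separated per-mutation summary.
#'
#' @param report result of [runFullAnalysis()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  rows <- do.call(rbind, lapply(report$rareMutations, function(m)
    data.frame(mutation = m$label, gene = m$gene,
               protein_change = m$proteinChange,
               n_carriers = m$nCarriers,
               n_origins_cohort = m$nOriginsCohort,
               classification = if (!is.null(m$classification))
                 m$classification else NA_character_)))
  writeTSV(rows, file.path(dir, "rare_mutations.tsv"))
  invisible(dir)
}
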