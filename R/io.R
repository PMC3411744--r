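#' @include evidence.R
NULL

.read_tsv_checked <- function(file, required) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(basename(file), ": missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

.split_labels <- function(x) {
  x <- as.character(x)  # bare numeric positions read as integers
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  v <- trimws(strsplit(x, ",")[[1]])
  v[v != ""]
}

#' Read a cohort variant table
#'
#' Tab-separated, one row per proband: `sample_id`, `variants` (comma list of
#' labels in the shorthand or `m.` dialects), and optionally `rare_variants`
#' (the designated rare disease-candidate mutations, a subset of `variants`),
#' `haplogroup`, `phenotype`, `origin`.  Variants at the genome's excluded
#' positions (private mutations of the reference itself) are dropped.
#'
#' @param file path to the TSV.
#' @param genome optional [MitoGenome-class] used to resolve labels and apply
#'   the exclusion list.
#' @return list of [HaplotypeProfile-class]; per-sample haplogroups, when
#'   present, are attached as the `haplogroups` attribute (named character).
#' @export
readCohort <- function(file, genome = NULL) {
  df <- .read_tsv_checked(file, c("sample_id", "variants"))
  if (!nrow(df)) stop("input error: cohort table has no rows")
  if (anyDuplicated(df$sample_id))
    stop("input error: duplicate sample_id in cohort table")
  excl <- if (!is.null(genome)) excludedPositions(genome) else integer(0)
  profiles <- lapply(seq_len(nrow(df)), function(i) {
    labels <- .split_labels(df$variants[i])
    vars <- parseVariantLabels(labels, genome)
    keep <- !vapply(vars, variantPosition, integer(1)) %in% excl
    vars <- vars[keep]
    rare <- character(0)
    if ("rare_variants" %in% names(df)) {
      rlab <- .split_labels(df$rare_variants[i])
      rare <- vapply(parseVariantLabels(rlab, genome), variantKey,
                     character(1))
    }
    new("HaplotypeProfile", sampleId = df$sample_id[i], variants = vars,
        rareVariants = rare,
        phenotype = if ("phenotype" %in% names(df)) df$phenotype[i]
                    else "unknown",
        origin = if ("origin" %in% names(df)) df$origin[i] else "")
  })
  if ("haplogroup" %in% names(df))
    attr(profiles, "haplogroups") <-
      stats::setNames(df$haplogroup, df$sample_id)
  profiles
}

#' Read a predictor/evidence table
#'
#' One row per rare mutation, mirroring the structure of a published
#' conservation table: `mutation` (HGVS-like label), `gene`, `aa_change`,
#' `heteroplasmy`, `matches_genbank`, `cons_eukaryotes`, `cons_vertebrates`,
#' `cons_mammals`, `polyphen2`, `sift`, `families` (comma list of carrier
#' sample ids) and optionally `association`, `near_invariant`,
#' `prior_occurrences`.
#'
#' @param file path to the TSV.
#' @return data.frame with `families` split into a list column.
#' @export
readPredictorTable <- function(file) {
  df <- .read_tsv_checked(file, c("mutation", "polyphen2", "sift"))
  if ("families" %in% names(df))
    df$families <- lapply(df$families, .split_labels)
  df
}

#' Read a population haplotype collection
#'
#' Tab-separated with columns `record_id` and `variants` (comma list of
#' labels).
#'
#' @inheritParams readCohort
#' @return list of character label vectors, named by record id.
#' @export
readPopulationCollection <- function(file, genome = NULL) {
  df <- .read_tsv_checked(file, c("record_id", "variants"))
  out <- lapply(df$variants, .split_labels)
  names(out) <- df$record_id
  out
}

#' Write a profile or table as TSV
#'
#' @param x data.frame.
#' @param file output path.
#' @export
writeTSV <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
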