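# Shared fixtures and independent oracles for the test suite.

ref_genome <- local({
  g <- NULL
  function() {
    if (is.null(g))
      g <<- readMitoGenome(mtFixture("rcrs_synthetic.fasta"),
                           mtFixture("rcrs_genemap.tsv"))
    g
  }
})

cohort_tree <- function(genome = ref_genome())
  parsePhylogeny(mtFixture("lhon_cohort_tree.txt"), genome)

cohort_profiles <- function(genome = ref_genome())
  readCohort(mtFixture("lhon_cohort.tsv"), genome)

# carrier-state vector over the tree leaves for a shorthand variant label
carrier_states <- function(label, cohort = cohort_profiles(),
                           phylo = cohort_tree(), genome = ref_genome()) {
  key <- variantKey(parseVariantLabel(label, genome))
  ids <- vapply(cohort, sampleId, character(1))
  carrying <- ids[vapply(cohort, function(h)
    key %in% vapply(haplotypeVariants(h), variantKey, character(1)),
    logical(1))]
  lv <- leafLabels(phylo)
  stats::setNames(lv %in% carrying, lv)
}

# Brute-force parsimony oracle: exhaustive enumeration over all internal-node
# labelings.  Conventions match the package: gains are 0->1 edges plus one if
# the root itself is in the carrier state; irreversible mode forbids 1->0
# edges and minimises gains; reversible mode minimises total state changes
# and, among minimal labelings, reports the maximal gain count.
oracle_origins <- function(phylo, states, mode = "irreversible") {
  parent <- phylo@parent
  n <- length(parent)
  leaves <- setdiff(seq_len(n), parent[!is.na(parent)])
  internal <- setdiff(seq_len(n), leaves)
  root <- which(is.na(parent))
  st <- rep(NA_integer_, n)
  st[leaves] <- as.integer(states[phylo@label[leaves]])
  if (!any(st[leaves] == 1L)) return(0L)
  nonroot <- setdiff(seq_len(n), root)
  best <- NULL
  grid <- if (length(internal))
    as.matrix(expand.grid(rep(list(0:1), length(internal)))) else
    matrix(integer(0), nrow = 1, ncol = 0)
  for (r in seq_len(nrow(grid))) {
    st[internal] <- grid[r, ]
    up <- st[parent[nonroot]]
    gains <- sum(up == 0L & st[nonroot] == 1L) + (st[root] == 1L)
    losses <- sum(up == 1L & st[nonroot] == 0L)
    if (mode == "irreversible") {
      if (losses > 0L) next
      if (is.null(best) || gains < best) best <- gains
    } else {
      changes <- sum(up != st[nonroot])
      if (is.null(best) || changes < best[1] ||
          (changes == best[1] && gains > best[2]))
        best <- c(changes, gains)
    }
  }
  if (mode == "irreversible") best else best[2]
}

# exhaustive per-column counting oracle for conservation profiles
oracle_profile <- function(alignment) {
  mat <- as.matrix(alignment@aln)
  ref <- mat[alignment@referenceRow, ]
  cols <- which(!ref %in% c("-", "."))
  t(vapply(cols, function(j) {
    col <- mat[, j]
    col <- col[!col %in% c("-", ".")]
    tab <- sort(table(col), decreasing = TRUE)
    c(prevalence = 100 * as.numeric(tab[1]) / length(col),
      n = length(col))
  }, c(prevalence = 0, n = 0)))
}

# small genome + single-gene map written to temp files, for toy annotation
# and circular-codon cases
toy_genome <- function(seq, map) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">toy", seq), fa)
  tsv <- tempfile(fileext = ".tsv")
  utils::write.table(map, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  readMitoGenome(fa, tsv, controlRegion = c(nchar(seq) + 1L, 0L),
                 excludedPositions = integer(0))
}

# build a ConservationProfile realising a given per-position prevalence
# vector exactly: 100 rows per column, `prevalence` of them modal
make_profile <- function(prevalence, invariantAt = integer(0), ...) {
  n <- length(prevalence)
  prevalence[invariantAt] <- 100
  nr <- 100L
  mat <- matrix("", nr, n)
  for (j in seq_len(n)) {
    k <- round(nr * prevalence[j] / 100)
    mat[, j] <- c(rep("A", k), rep(c("C", "D", "E"), length.out = nr - k))
  }
  rows <- apply(mat, 1, paste, collapse = "")
  names(rows) <- c("Homo_sapiens", sprintf("sp%03d", seq_len(nr - 1L)))
  aln <- TaxonAlignment(Biostrings::AAStringSet(rows), "Homo_sapiens",
                        "mammals")
  computeProfile(aln, ...)
}
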