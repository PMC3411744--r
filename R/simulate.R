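#' @include phylo.R conservation.R rflp.R
NULL

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

#' Simulate a pre-aligned protein set with planted conservation
#'
#' Each column has a planted modal residue and modal probability: every row
#' draws the modal residue with that probability and otherwise a uniform
#' draw from the remaining 19 amino acids; gaps are drawn independently.
#' The reference row is generated like any other row but ungapped, so every
#' column maps to a position.  The returned truth table records the planted
#' probabilities; the conservation estimator can be checked against it by
#' exact binomial reasoning.
#'
#' @param nRows rows (species) in the alignment.
#' @param modalProb either a single probability recycled across positions or
#'   a vector, one per position.
#' @param nPositions protein length (ignored when `modalProb` is a vector).
#' @param gapProb per-cell gap probability (non-reference rows).
#' @param taxonSet taxon set label for the alignment.
#' @param seed integer seed; the same seed reproduces the alignment exactly.
#' @return list with `alignment` ([TaxonAlignment-class]) and `truth`
#'   (data.frame of position, modal residue, planted probability).
#' @export
simulateAlignment <- function(nRows, modalProb = 0.8, nPositions = 100L,
                              gapProb = 0.05,
                              taxonSet = c("mammals", "vertebrates",
                                           "eukaryotes"),
                              seed = 1L) {
  taxonSet <- match.arg(taxonSet)
  if (nRows < 1L) stop("config error: alignment needs at least one row")
  if (any(modalProb < 0 | modalProb > 1) || gapProb < 0 || gapProb > 1)
    stop("config error: probabilities must lie in [0, 1]")
  p <- if (length(modalProb) > 1L) modalProb else rep(modalProb, nPositions)
  n <- length(p)
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed())
  modal <- sample(.AA20, n, replace = TRUE)
  rows <- matrix("", nrow = nRows, ncol = n)
  for (j in seq_len(n)) {
    isModal <- stats::runif(nRows) < p[j]
    other <- sample(setdiff(.AA20, modal[j]), nRows, replace = TRUE)
    col <- ifelse(isModal, modal[j], other)
    gap <- stats::runif(nRows) < gapProb
    gap[1L] <- FALSE  # reference row stays ungapped
    col[gap] <- "-"
    rows[, j] <- col
  }
  seqs <- apply(rows, 1L, paste, collapse = "")
  names(seqs) <- c("Homo_sapiens",
                   sprintf("species_%03d", seq_len(nRows - 1L)))[seq_len(nRows)]
  aln <- Biostrings::AAStringSet(seqs)
  list(alignment = TaxonAlignment(aln, "Homo_sapiens", taxonSet),
       truth = data.frame(position = seq_len(n), modal = modal,
                          modalProb = p, seed = seed))
}

# run code under a temporary RNG state
.with_seed <- function(seed) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Random rooted bifurcating topology
#'
#' Coalescent-style random join of `nLeaves` labelled tips; internal nodes
#' are named `node<k>` and every node carries an empty mutation list.
#'
#' @param nLeaves number of tips.
#' @param leafLabels optional tip labels.
#' @param seed integer seed.
#' @return a [MitoPhylo-class].
#' @export
randomTopology <- function(nLeaves, leafLabels = NULL, seed = 1L) {
  if (nLeaves < 2L) stop("config error: need at least two leaves")
  restore <- .with_seed(seed)
  on.exit(restore())
  if (is.null(leafLabels)) leafLabels <- sprintf("t%d", seq_len(nLeaves))
  n <- 2L * nLeaves - 1L
  label <- c(leafLabels, sprintf("node%d", seq_len(nLeaves - 1L)))
  parent <- rep(NA_integer_, n)
  open <- seq_len(nLeaves)
  nxt <- nLeaves + 1L
  while (length(open) > 1L) {
    pick <- sample(length(open), 2L)
    parent[open[pick]] <- nxt
    open <- c(open[-pick], nxt)
    nxt <- nxt + 1L
  }
  .mp_new(label, parent, rep(NA_character_, n),
          rep(list(character(0)), n))
}

#' Simulate a cohort evolved on a known tree
#'
#' Background mutations are dropped on every branch (a Poisson count with a
#' floor of one, at positions drawn uniformly over the genome and written as
#' shorthand transitions); the focal variant, when given, is placed on
#' exactly the designated branches, which must be pairwise non-nested so the
#' planted origin count is recoverable.  Leaves inherit all mutations on
#' their root path.  Internal nodes are named as haplogroups `HG<k>` so
#' haplogroup recovery can be scored against the recorded truth.
#'
#' @param nLeaves leaves (samples) in the cohort tree.
#' @param meanMutations mean background mutations per branch (Poisson, floor
#'   one).
#' @param focalVariant shorthand label of the planted variant, or `NULL`.
#' @param originBranches node labels of the branches gaining the focal
#'   variant.
#' @param genomeLength genome length for background position draws.
#' @param seed integer seed.
#' @return list with `phylogeny`, `cohort` (list of
#'   [HaplotypeProfile-class]), and `truth` (origin count, per-leaf planted
#'   haplogroup and carrier status).
#' @export
simulateCohort <- function(nLeaves = 12L, meanMutations = 2,
                           focalVariant = NULL, originBranches = character(0),
                           genomeLength = 16569L, seed = 1L) {
  phylo <- randomTopology(nLeaves, seed = seed)
  restore <- .with_seed(seed + 1L)
  on.exit(restore())
  n <- length(phylo@label)
  leaves <- .mp_leaves(phylo)
  root <- .mp_root(phylo)
  # name internal nodes as haplogroups
  hg <- rep(NA_character_, n)
  internal <- setdiff(seq_len(n), leaves)
  hg[internal] <- sprintf("HG%d", seq_along(internal))
  # background mutations per branch (root keeps none: it is the reference)
  muts <- rep(list(character(0)), n)
  used <- if (!is.null(focalVariant))
    variantPosition(parseVariantLabel(focalVariant)) else integer(0)
  for (i in setdiff(seq_len(n), root)) {
    k <- max(1L, stats::rpois(1L, meanMutations))
    pos <- sample(setdiff(seq_len(genomeLength), used), k)
    used <- c(used, pos)   # avoid accidental recurrence of backgrounds
    muts[[i]] <- as.character(sort(pos))
  }
  if (!is.null(focalVariant)) {
    ob <- match(originBranches, phylo@label)
    if (anyNA(ob)) stop("config error: unknown origin branch label(s)")
    for (a in ob) for (b in ob) {
      if (a != b && a %in% .mp_path(phylo, b))
        stop("config error: planted origin branches are nested; the planted ",
             "count would be unrecoverable")
    }
    for (i in ob) muts[[i]] <- c(muts[[i]], focalVariant)
  }
  phylo <- .mp_new(phylo@label, phylo@parent, hg, muts)
  focalKey <- if (!is.null(focalVariant))
    variantKey(parseVariantLabel(focalVariant)) else NA_character_
  cohort <- lapply(leaves, function(lf) {
    labels <- unlist(lapply(.mp_path(phylo, lf), function(i) muts[[i]]))
    new("HaplotypeProfile", sampleId = phylo@label[lf],
        variants = parseVariantLabels(labels),
        rareVariants = character(0), phenotype = "unknown",
        origin = "simulated")
  })
  plantedHg <- vapply(leaves, function(lf) {
    path <- rev(.mp_path(phylo, lf))
    named <- path[!is.na(hg[path])]
    if (length(named)) hg[named[1]] else NA_character_
  }, character(1))
  carrier <- vapply(cohort, function(h)
    focalKey %in% .haplotype_keys(h), logical(1))
  names(carrier) <- phylo@label[leaves]
  names(plantedHg) <- phylo@label[leaves]
  # planted origins equal the parsimony count unless the planted branches
  # jointly cover a whole clade; record both so tests can tell
  recoverable <- if (any(carrier))
    nOrigins(countIndependentOrigins(phylo, carrier)) else 0L
  list(phylogeny = phylo, cohort = cohort,
       truth = list(nOrigins = length(originBranches),
                    originBranches = originBranches,
                    nOriginsRecoverable = recoverable,
                    plantedHaplogroup = plantedHg,
                    carriers = carrier, seed = seed))
}

#' Simulate a population haplotype collection with planted carriers
#'
#' Exactly `k` records carry each planted variant; background variants are
#' drawn independently per record at positions disjoint from the planted
#' ones, so planted carrier counts are exact.
#'
#' @param nRecords number of records.
#' @param planted named integer: shorthand variant label -> planted carrier
#'   count.
#' @param meanBackground mean background variants per record (Poisson).
#' @param genomeLength genome length for background position draws.
#' @param seed integer seed.
#' @return list with `collection` (list of character label vectors) and
#'   `truth` (named carrier counts and carrier record indices).
#' @export
simulatePopulation <- function(nRecords, planted = integer(0),
                               meanBackground = 3, genomeLength = 16569L,
                               seed = 1L) {
  if (any(planted > nRecords))
    stop("config error: planted carrier count exceeds the collection size")
  if (any(planted < 0)) stop("config error: negative carrier count")
  restore <- .with_seed(seed)
  on.exit(restore())
  plantedPos <- vapply(names(planted), function(l)
    variantPosition(parseVariantLabel(l)), integer(1))
  pool <- setdiff(seq_len(genomeLength), plantedPos)
  collection <- lapply(seq_len(nRecords), function(i) {
    k <- stats::rpois(1L, meanBackground)
    as.character(sort(sample(pool, k)))
  })
  carrierIdx <- list()
  for (l in names(planted)) {
    idx <- if (planted[[l]] > 0L) sort(sample(nRecords, planted[[l]]))
           else integer(0)
    carrierIdx[[l]] <- idx
    for (i in idx) collection[[i]] <- c(collection[[i]], l)
  }
  list(collection = collection,
       truth = list(planted = planted, carriers = carrierIdx, seed = seed))
}

#' Simulate gel band intensities at a known mutant fraction
#'
#' Intensity per band is molarity x fragment length x a lognormal
#' multiplicative noise term (`exp(rnorm(0, sigma))`): the mass model of
#' ethidium staining.  Mutant-diagnostic bands have molarity equal to the
#' true mutant fraction, wild-type bands the complement.
#'
#' @param trueFraction true mutant fraction in `[0, 1]`.
#' @param wildLengths,mutantLengths diagnostic fragment lengths (bp) per
#'   allele.
#' @param sigma multiplicative noise standard deviation (log scale), `>= 0`.
#' @param seed integer seed.
#' @return data.frame of bands (`band`, `allele`, `length`, `intensity`)
#'   with the true fraction attached as attribute `truth`.
#' @export
simulateGel <- function(trueFraction, wildLengths, mutantLengths,
                        sigma = 0.05, seed = 1L) {
  if (sigma < 0) stop("config error: sigma must be non-negative")
  if (trueFraction < 0 || trueFraction > 1)
    stop("config error: fraction must lie in [0, 1]")
  if (any(c(wildLengths, mutantLengths) <= 0))
    stop("config error: fragment lengths must be positive")
  restore <- .with_seed(seed)
  on.exit(restore())
  lens <- c(wildLengths, mutantLengths)
  allele <- c(rep("wild", length(wildLengths)),
              rep("mutant", length(mutantLengths)))
  molar <- ifelse(allele == "mutant", trueFraction, 1 - trueFraction)
  noise <- exp(stats::rnorm(length(lens), 0, sigma))
  bands <- data.frame(band = sprintf("b%d", seq_along(lens)),
                      allele = allele, length = lens,
                      intensity = molar * lens * noise)
  attr(bands, "truth") <- trueFraction
  bands
}
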