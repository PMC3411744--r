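#' @include genome.R
NULL

#' Read a pre-aligned protein set for one taxon set
#'
#' @param fastaFile aligned FASTA (gaps as `-` or `.`).
#' @param referenceRow name of the human reference row (default: first record).
#' @param taxonSet `"eukaryotes"`, `"vertebrates"` or `"mammals"`.
#' @return a [TaxonAlignment-class].
#' @export
readTaxonAlignment <- function(fastaFile, referenceRow = NULL,
                               taxonSet = c("mammals", "vertebrates",
                                            "eukaryotes")) {
  taxonSet <- match.arg(taxonSet)
  aln <- Biostrings::readAAStringSet(fastaFile)
  TaxonAlignment(aln, referenceRow, taxonSet)
}

#' Construct a TaxonAlignment from an AAStringSet
#'
#' @param aln an [Biostrings::AAStringSet] of aligned rows (equal widths).
#' @inheritParams readTaxonAlignment
#' @export
TaxonAlignment <- function(aln, referenceRow = NULL,
                           taxonSet = c("mammals", "vertebrates",
                                        "eukaryotes")) {
  taxonSet <- match.arg(taxonSet)
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("ragged alignment: rows have unequal widths")
  if (is.null(referenceRow)) referenceRow <- names(aln)[1]
  if (!referenceRow %in% names(aln))
    stop("reference row '", referenceRow, "' not present in the alignment")
  new("TaxonAlignment", aln = aln, referenceRow = referenceRow,
      taxonSet = taxonSet)
}

.GAPS <- c("-", ".")

#' Compute a per-residue conservation profile
#'
#' Alignment columns are mapped to protein positions through the ungapped
#' reference row (columns where the reference is gapped map to no position
#' and are skipped).  At each position the modal residue among non-gap rows
#' (reference included) and its prevalence as a percentage of non-gap rows
#' are recorded.  Positions whose non-gap coverage falls below
#' `minCoverageFraction` of the rows are flagged low-coverage and excluded
#' from invariant status.
#'
#' @param alignment a [TaxonAlignment-class].
#' @param thresholdPercent conservation threshold; the strict rule calls a
#'   position conserved only when prevalence is *over* this value.
#' @param localWindowRadius half-width of the local window (residues).
#' @param invariantProximityRadius proximity radius to invariant positions.
#' @param minCoverageFraction minimum non-gap coverage for a position to be
#'   assessable.
#' @param strict if `TRUE` (default) "conserved" means prevalence strictly
#'   greater than the threshold; `FALSE` uses greater-or-equal.
#' @return a [ConservationProfile-class].
#' @export
computeProfile <- function(alignment, thresholdPercent = 70,
                           localWindowRadius = 10L,
                           invariantProximityRadius = 4L,
                           minCoverageFraction = 0.5, strict = TRUE) {
  stopifnot(is(alignment, "TaxonAlignment"))
  mat <- as.matrix(alignment@aln)
  ref <- mat[alignment@referenceRow, ]
  cols <- which(!ref %in% .GAPS)
  nrows <- nrow(mat)
  floorN <- minCoverageFraction * nrows
  modal <- character(length(cols)); prev <- numeric(length(cols))
  ncount <- integer(length(cols))
  for (j in seq_along(cols)) {
    col <- mat[, cols[j]]
    col <- col[!col %in% .GAPS]
    ncount[j] <- length(col)
    if (!length(col)) { modal[j] <- NA_character_; prev[j] <- NA_real_; next }
    tab <- table(col)
    # deterministic tie-break: alphabetically first among co-modal residues
    top <- names(tab)[tab == max(tab)]
    modal[j] <- sort(top)[1]
    prev[j] <- 100 * max(tab) / length(col)
  }
  lowcov <- ncount < floorN
  data <- data.frame(
    position = seq_along(cols), column = cols, modal = modal,
    prevalence = prev, nCounted = ncount, lowCoverage = lowcov,
    invariant = !lowcov & !is.na(prev) & prev == 100)
  new("ConservationProfile", data = data, taxonSet = alignment@taxonSet,
      params = list(thresholdPercent = thresholdPercent,
                    localWindowRadius = as.integer(localWindowRadius),
                    invariantProximityRadius = as.integer(invariantProximityRadius),
                    minCoverageFraction = minCoverageFraction,
                    strict = strict))
}

.prof_conserved <- function(profile) {
  d <- profile@data; p <- profile@params
  ok <- if (p$strict) d$prevalence > p$thresholdPercent
        else d$prevalence >= p$thresholdPercent
  ok[d$lowCoverage] <- NA
  ok
}

#' Is a position conserved?
#'
#' `TRUE` iff the modal-residue prevalence is over the profile's threshold
#' (strictly, under the default strict rule).  Low-coverage positions return
#' `NA` — indeterminate, never silently `FALSE`.
#'
#' @param profile a [ConservationProfile-class].
#' @param position 1-based residue position.
#' @export
isConserved <- function(profile, position) {
  d <- profile@data
  if (position < 1L || position > nrow(d)) stop("position out of range")
  .prof_conserved(profile)[position]
}

#' Local-versus-global window statistics
#'
#' Compares the window of `localWindowRadius` residues either side of a
#' position (truncated at the protein ends) against the whole protein: mean
#' prevalence, and the *density* of conserved positions (count divided by
#' window or protein length, so the two are comparable).  The flag is `TRUE`
#' only when both the local mean and the local conserved density strictly
#' exceed their global counterparts.
#'
#' @inheritParams isConserved
#' @return list with `localMean`, `globalMean`, `localDensity`,
#'   `globalDensity`, `windowStart`, `windowEnd`, `localExceedsGlobal`.
#' @export
localWindowStats <- function(profile, position) {
  d <- profile@data; p <- profile@params
  n <- nrow(d)
  if (position < 1L || position > n) stop("position out of range")
  lo <- max(1L, position - p$localWindowRadius)
  hi <- min(n, position + p$localWindowRadius)
  win <- lo:hi
  cons <- .prof_conserved(profile)
  usable_w <- win[!d$lowCoverage[win]]
  usable_g <- which(!d$lowCoverage)
  if (!length(usable_w))
    return(list(localMean = NA_real_, globalMean = NA_real_,
                localDensity = NA_real_, globalDensity = NA_real_,
                windowStart = lo, windowEnd = hi,
                localExceedsGlobal = NA))
  localMean <- mean(d$prevalence[usable_w])
  globalMean <- mean(d$prevalence[usable_g])
  localDensity <- sum(cons[win], na.rm = TRUE) / length(win)
  globalDensity <- sum(cons, na.rm = TRUE) / n
  list(localMean = localMean, globalMean = globalMean,
       localDensity = localDensity, globalDensity = globalDensity,
       windowStart = lo, windowEnd = hi,
       localExceedsGlobal = localMean > globalMean &&
         localDensity > globalDensity)
}

#' Distance to the nearest invariant position
#'
#' Invariant means 100% prevalence at adequate coverage.  The flag is `TRUE`
#' when an invariant position lies within the proximity radius (distance 1 to
#' radius; the queried position itself being invariant is the threshold
#' rule's business, not this one's).
#'
#' @inheritParams isConserved
#' @return list with `distance` (`NA` when the protein has no invariant
#'   position other than the query) and `nearInvariant`.
#' @export
nearestInvariantDistance <- function(profile, position) {
  d <- profile@data; p <- profile@params
  if (position < 1L || position > nrow(d)) stop("position out of range")
  inv <- which(d$invariant)
  inv <- inv[inv != position]
  if (!length(inv))
    return(list(distance = NA_integer_, nearInvariant = FALSE))
  dist <- min(abs(inv - position))
  list(distance = as.integer(dist),
       nearInvariant = dist >= 1L && dist <= p$invariantProximityRadius)
}

#' Classify a variant position as possibly synergistic
#'
#' Applies the three rules in order on the chosen taxon set (mammals by
#' default): (1) the threshold rule — prevalence over the conservation
#' threshold; for positions not over the threshold, (2) the local-window rule
#' — both local mean prevalence and local conserved density strictly above
#' the protein-wide values; and (3) the invariant-proximity rule — an
#' invariant position within the proximity radius.  A variant is possibly
#' synergistic when any rule fires; all supporting numbers are returned.
#'
#' @param variant a [ProteinChange-class] (its `residueIndex` is used) or a
#'   residue position.
#' @param profiles a single [ConservationProfile-class] or a named list of
#'   them keyed by taxon set.
#' @param useTaxonSet taxon set consulted for the rules.
#' @return a [SynergyDecision-class].
#' @export
classifySynergistic <- function(variant, profiles, useTaxonSet = "mammals") {
  position <- if (is(variant, "ProteinChange")) variant@residueIndex
              else as.integer(variant)
  prof <- if (is(profiles, "ConservationProfile")) profiles
          else profiles[[useTaxonSet]]
  if (is.null(prof))
    stop("no conservation profile available for taxon set '", useTaxonSet, "'")
  over <- isConserved(prof, position)
  win <- localWindowStats(prof, position)
  prox <- nearestInvariantDistance(prof, position)
  flags <- c(isTRUE(over), isTRUE(win$localExceedsGlobal),
             isTRUE(prox$nearInvariant))
  new("SynergyDecision", position = as.integer(position),
      overThreshold = isTRUE(over),
      localExceedsGlobal = isTRUE(win$localExceedsGlobal),
      nearInvariant = isTRUE(prox$nearInvariant),
      possiblySynergistic = any(flags),
      support = list(prevalence = prof@data$prevalence[position],
                     localMean = win$localMean, globalMean = win$globalMean,
                     localDensity = win$localDensity,
                     globalDensity = win$globalDensity,
                     distanceToInvariant = prox$distance,
                     taxonSet = prof@taxonSet))
}
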