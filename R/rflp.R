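#' @include genome.R
NULL

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param recognition recognition sequence, IUPAC degeneracy allowed.
#' @param cutOffset top-strand bases of the site left of the duplex cut
#'   (EcoRI `G^AATTC` has offset 1).
#' @export
restrictionEnzyme <- function(name, recognition, cutOffset) {
  new("RestrictionEnzyme", name = name,
      recognition = toupper(recognition), cutOffset = as.integer(cutOffset))
}

.as_dna <- function(x) {
  if (is(x, "MitoGenome")) genomeSeq(x)
  else if (is(x, "DNAString")) x
  else Biostrings::DNAString(x)
}

# all match start positions of `pattern` on the circular sequence `subject`,
# reported in 1..L
.circular_matches <- function(pattern, subject, fixed = TRUE) {
  L <- length(subject)
  k <- nchar(as.character(pattern))
  doubled <- Biostrings::xscat(subject,
                               Biostrings::subseq(subject, 1L, min(k - 1L, L)))
  hits <- Biostrings::start(Biostrings::matchPattern(pattern, doubled,
                                                     fixed = fixed))
  sort(unique(((hits - 1L) %% L) + 1L))
}

#' Simulate PCR amplification from a circular genome
#'
#' Exact-match primer search: the forward primer is matched on the top
#' strand, the reverse primer as its reverse complement.  Each must match
#' exactly once; the amplicon runs from the forward-primer start to the end
#' of the reverse-primer binding site, inclusive of both primers, wrapping
#' across the circular origin when needed.
#'
#' @param genome a [MitoGenome-class], `DNAString` or character sequence.
#' @param forward,reverse primer sequences, both written 5'->3'.
#' @return list with `amplicon` (a `DNAString`), `start`, `end` (genomic,
#'   1-based; `end` may be numerically smaller than `start` when the
#'   amplicon wraps the origin) and `length`.
#' @export
simulateAmplicon <- function(genome, forward, reverse) {
  subject <- .as_dna(genome)
  L <- length(subject)
  fwd <- Biostrings::DNAString(toupper(as.character(forward)))
  rev <- Biostrings::DNAString(toupper(as.character(reverse)))
  revRC <- Biostrings::reverseComplement(rev)
  if (as.character(fwd) == as.character(revRC))
    stop("ambiguous primer design: the forward primer equals the reverse ",
         "complement of the reverse primer")
  fhits <- .circular_matches(fwd, subject)
  if (!length(fhits)) stop("forward primer not found in the genome")
  if (length(fhits) > 1L) stop("ambiguous forward primer: ", length(fhits),
                               " matches")
  rhits <- .circular_matches(revRC, subject)
  if (!length(rhits)) stop("reverse primer not found in the genome")
  if (length(rhits) > 1L) stop("ambiguous reverse primer: ", length(rhits),
                               " matches")
  start <- fhits
  rend <- rhits + length(revRC) - 1L  # may exceed L (wrap)
  rendMod <- ((rend - 1L) %% L) + 1L
  len <- ((rendMod - start) %% L) + 1L
  if (len < length(fwd) + length(rev))
    stop("primers overlap or face the wrong way: amplicon shorter than the ",
         "primers")
  idx <- .circ_index(start:(start + len - 1L), L)
  amplicon <- Biostrings::DNAString(
    paste(strsplit(as.character(subject), "")[[1]][idx], collapse = ""))
  list(amplicon = amplicon, start = start, end = rendMod, length = len)
}

#' Digest an amplicon with a restriction enzyme
#'
#' Recognition sites are searched on the top strand and, for non-palindromic
#' recognition sequences, as the reverse complement (the enzyme bound to the
#' bottom strand); each site yields one duplex cut coordinate via the cut
#' offset.  Fragment lengths are reported left to right along the linear
#' amplicon and always sum to its length; a cut falling exactly on a
#' boundary produces a zero-length fragment, reported with a warning.
#'
#' @param amplicon a `DNAString` or character sequence (linear).
#' @param enzyme a [RestrictionEnzyme-class].
#' @param allele label stored in the result.
#' @return a [DigestResult-class].
#' @export
digestAmplicon <- function(amplicon, enzyme, allele = "allele") {
  amp <- .as_dna(amplicon)
  len <- length(amp)
  rec <- Biostrings::DNAString(enzyme@recognition)
  recRC <- Biostrings::reverseComplement(rec)
  palindromic <- as.character(rec) == as.character(recRC)
  top <- Biostrings::start(Biostrings::matchPattern(rec, amp, fixed = FALSE))
  cuts <- top + enzyme@cutOffset - 1L
  if (!palindromic) {
    bot <- Biostrings::matchPattern(recRC, amp, fixed = FALSE)
    # enzyme on the bottom strand: offset counts from the site's other end
    cuts <- c(cuts, Biostrings::end(bot) - enzyme@cutOffset)
  }
  cuts <- sort(unique(cuts))
  cuts <- cuts[cuts >= 0L & cuts <= len]
  frag <- diff(c(0L, cuts, len))
  if (any(frag == 0L))
    warning("degenerate digest: cut at a fragment boundary yields a ",
            "zero-length fragment")
  new("DigestResult", allele = allele, fragments = as.integer(frag),
      ampliconLength = as.integer(len))
}

#' Differential digest of wild-type and mutant alleles
#'
#' Amplifies the wild-type genome and the genome carrying the variant with
#' the same primer pair, digests both, and reports the fragments together
#' with the allele-diagnostic bands (the multiset symmetric difference of
#' the two fragment lists).
#'
#' @param genome wild-type [MitoGenome-class] or `DNAString`.
#' @param variant a resolved substitution [MitoVariant-class].
#' @param forward,reverse the primer pair.
#' @param enzyme a [RestrictionEnzyme-class].
#' @return list with `wild`, `mutant` ([DigestResult-class]s) and
#'   `diagnostic` (list of per-allele diagnostic fragment lengths).
#' @export
differentialDigest <- function(genome, variant, forward, reverse, enzyme) {
  subject <- .as_dna(genome)
  wildAmp <- simulateAmplicon(subject, forward, reverse)
  L <- length(subject)
  offset <- ((variant@position - wildAmp$start) %% L)
  if (offset >= wildAmp$length)
    stop("assay design error: the variant lies outside the amplicon")
  mutSeq <- applyVariant(subject, variant)
  mutAmp <- simulateAmplicon(mutSeq, forward, reverse)
  wild <- digestAmplicon(wildAmp$amplicon, enzyme, allele = "wild")
  mut <- digestAmplicon(mutAmp$amplicon, enzyme, allele = "mutant")
  diagW <- .multiset_diff(fragments(wild), fragments(mut))
  diagM <- .multiset_diff(fragments(mut), fragments(wild))
  if (!length(diagW) && !length(diagM))
    stop("uninformative assay: wild-type and mutant digests are identical")
  list(wild = wild, mutant = mut,
       diagnostic = list(wild = diagW, mutant = diagM))
}

.multiset_diff <- function(a, b) {
  out <- integer(0)
  bb <- b
  for (x in a) {
    i <- match(x, bb)
    if (is.na(i)) out <- c(out, x) else bb <- bb[-i]
  }
  out
}

#' Estimate heteroplasmy from densitometric band intensities
#'
#' Under the mass model (stain intensity proportional to molarity times
#' fragment length), the molar amount of each band is `intensity / length`.
#' The mutant load is the summed molar amount of mutant-diagnostic bands over
#' that of all diagnostic bands, as a percentage.
#'
#' @param bands data.frame with columns `allele` (`"wild"`/`"mutant"`;
#'   other values are treated as shared, non-diagnostic bands and ignored),
#'   `length` (bp) and `intensity` (arbitrary units, non-negative).
#' @return mutant fraction in percent.
#' @examples
#' estimateHeteroplasmy(data.frame(
#'   allele = c("wild", "mutant"), length = c(200, 200),
#'   intensity = c(1, 1)))  # 50
#' @export
estimateHeteroplasmy <- function(bands) {
  need <- c("allele", "length", "intensity")
  if (!all(need %in% names(bands)))
    stop("bands must have columns: ", paste(need, collapse = ", "))
  if (any(bands$intensity < 0)) stop("negative band intensity")
  diag <- bands[bands$allele %in% c("wild", "mutant"), , drop = FALSE]
  if (!nrow(diag) || !any(diag$allele == "wild") ||
      !any(diag$allele == "mutant"))
    stop("need at least one diagnostic band per allele")
  if (all(diag$intensity == 0)) stop("no signal: all intensities are zero")
  molar <- diag$intensity / diag$length
  100 * sum(molar[diag$allele == "mutant"]) / sum(molar)
}

#' Read an RFLP assay definition table
#'
#' Tab-separated table with columns `mutation`, `forward`, `reverse`,
#' `enzyme`, `recognition`, `cut_offset` (the structure of a published
#' primer/enzyme supplement).
#'
#' @param file path to the TSV.
#' @return list of assays; each has `mutation`, `forward`, `reverse` and an
#'   `enzyme` ([RestrictionEnzyme-class]).
#' @export
readAssayTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("mutation", "forward", "reverse", "enzyme", "recognition",
            "cut_offset")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("assay table is missing required column(s): ",
         paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    list(mutation = df$mutation[i], forward = df$forward[i],
         reverse = df$reverse[i],
         enzyme = restrictionEnzyme(df$enzyme[i], df$recognition[i],
                                    df$cut_offset[i])))
}
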