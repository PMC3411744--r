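#' @include AllGenerics.R
NULL

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")
TRANSITION_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")

#' Classify a substitution as transition or transversion
#'
#' Transitions exchange bases within the purines (`A`,`G`) or within the
#' pyrimidines (`C`,`T`); every other exchange is a transversion.
#'
#' @param ref,alt single nucleotides.
#' @return `"transition"` or `"transversion"`.
#' @examples
#' classifySubstitution("G", "A")  # transition
#' classifySubstitution("C", "A")  # transversion
#' @export
classifySubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!ref %in% c(PURINES, PYRIMIDINES) || !alt %in% c(PURINES, PYRIMIDINES))
    stop("bases must be one of A, C, G, T")
  if (ref == alt)
    stop("invalid substitution: identical bases")
  if ((ref %in% PURINES) == (alt %in% PURINES)) "transition" else "transversion"
}

.genome_base <- function(genome, pos) {
  as.character(Biostrings::subseq(genomeSeq(genome), pos, pos))
}

#' Parse a variant label
#'
#' Accepts the shorthand branch dialect used on phylogeny figures and in
#' cohort tables, and the HGVS-like `m.` substitution form:
#'
#' * `"3700"` — transition at 3700 (alternate base implied: the transition
#'   partner of the reference base, so the genome is needed to resolve it);
#' * `"14482A"` — substitution to an explicitly indicated base;
#' * `"@263"` — reversion (back mutation) at 263;
#' * `"315+C"` — insertion; `"16166d"` — deletion;
#' * suffixes `s`/`ns` (synonymous / non-synonymous), `h` (heteroplasmic),
#'   `~t`/`~r` (tRNA / rRNA locus) are recorded as annotations;
#' * `"m.3733G>C"` — explicit substitution, checked against the genome.
#'
#' Without a genome a shorthand transition parses to a partially resolved
#' variant (`isResolved(x)` is `FALSE`).
#'
#' @param label a single label.
#' @param genome optional [MitoGenome-class] used to resolve implied bases and
#'   check explicit reference bases.
#' @return a [MitoVariant-class].
#' @examples
#' g <- readMitoGenome(mtFixture("rcrs_synthetic.fasta"),
#'                     mtFixture("rcrs_genemap.tsv"))
#' parseVariantLabel("3700", g)       # m.3700G>A
#' parseVariantLabel("14482A", g)     # m.14482C>A, transversion
#' @export
parseVariantLabel <- function(label, genome = NULL) {
  stopifnot(isSingleString(label))
  raw <- label
  label <- gsub("∼", "~", trimws(label))  # accept the typeset tilde

  reversion <- FALSE
  if (startsWith(label, "@")) {
    reversion <- TRUE
    label <- substring(label, 2L)
  }

  if (grepl("^m\\.", label)) {
    m <- regmatches(label, regexec("^m\\.([0-9]+)([ACGT])>([ACGT])$", label))[[1]]
    if (!length(m))
      stop("cannot parse variant label '", raw,
           "': malformed m. substitution form")
    pos <- as.integer(m[2]); ref <- m[3]; alt <- m[4]
    if (ref == alt)
      stop("invalid substitution in '", raw, "': identical bases")
    v <- new("MitoVariant", position = pos, ref = ref, alt = alt,
             kind = classifySubstitution(ref, alt), isReversion = reversion,
             isHeteroplasmic = FALSE, locusHint = NA_character_,
             effectHint = NA_character_, resolved = TRUE)
    .check_bounds_and_ref(v, genome, raw)
    return(v)
  }

  m <- regmatches(label, regexec("^([0-9]+)(.*)$", label))[[1]]
  if (!length(m) || m[2] == "")
    stop("cannot parse variant label '", raw, "': no position found")
  pos <- as.integer(m[2])
  rest <- m[3]

  altExplicit <- NA_character_
  kind <- NA_character_
  het <- FALSE
  locus <- NA_character_
  effect <- NA_character_
  inserted <- NA_character_

  while (nchar(rest) > 0L) {
    if (grepl("^ns", rest)) { effect <- "non-synonymous"; rest <- substring(rest, 3L) }
    else if (grepl("^s", rest)) { effect <- "synonymous"; rest <- substring(rest, 2L) }
    else if (grepl("^h", rest)) { het <- TRUE; rest <- substring(rest, 2L) }
    else if (grepl("^~t", rest)) { locus <- "tRNA"; rest <- substring(rest, 3L) }
    else if (grepl("^~r", rest)) { locus <- "rRNA"; rest <- substring(rest, 3L) }
    else if (grepl("^d", rest)) { kind <- "deletion"; rest <- substring(rest, 2L) }
    else if (grepl("^\\+[ACGT]+", rest)) {
      kind <- "insertion"
      inserted <- sub("^\\+([ACGT]+).*$", "\\1", rest)
      rest <- sub("^\\+[ACGT]+", "", rest)
    }
    else if (grepl("^[ACGT]", rest)) {
      if (!is.na(altExplicit))
        stop("cannot parse variant label '", raw,
             "': more than one alternate base")
      altExplicit <- substring(rest, 1L, 1L)
      rest <- substring(rest, 2L)
    }
    else stop("cannot parse variant label '", raw,
              "': unknown token '", rest, "'")
  }

  if (is.na(kind)) {  # substitution
    ref <- NA_character_; alt <- altExplicit; resolved <- FALSE
    if (!is.null(genome)) {
      .check_pos(pos, genome, raw)
      ref <- .genome_base(genome, pos)
      if (is.na(alt)) alt <- unname(TRANSITION_PARTNER[ref])
      if (alt == ref)
        stop("variant '", raw, "': explicit base equals the reference base")
      resolved <- TRUE
      kind <- classifySubstitution(ref, alt)
    } else {
      kind <- if (is.na(alt)) "transition" else "transversion"
      # an explicit base without genome is recorded but may turn out to be a
      # transition once resolved; shorthand without a base is a transition by
      # convention
      if (is.na(alt)) resolved <- FALSE else resolved <- FALSE
    }
    v <- new("MitoVariant", position = pos, ref = ref, alt = alt, kind = kind,
             isReversion = reversion, isHeteroplasmic = het,
             locusHint = locus, effectHint = effect, resolved = resolved)
  } else {
    if (!is.null(genome)) .check_pos(pos, genome, raw)
    v <- new("MitoVariant", position = pos, ref = NA_character_,
             alt = inserted, kind = kind, isReversion = reversion,
             isHeteroplasmic = het, locusHint = locus, effectHint = effect,
             resolved = !is.null(genome))
  }
  v
}

.check_pos <- function(pos, genome, raw) {
  if (pos < 1L || pos > genomeLength(genome))
    stop("position ", pos, " in '", raw, "' is outside 1..",
         genomeLength(genome))
}

.check_bounds_and_ref <- function(v, genome, raw) {
  if (is.null(genome)) return(invisible(v))
  .check_pos(v@position, genome, raw)
  g <- .genome_base(genome, v@position)
  if (!is.na(v@ref) && v@ref != g)
    stop("reference mismatch for '", raw, "': label says ", v@ref,
         " but the genome has ", g, " at ", v@position)
  invisible(v)
}

#' Parse a vector of variant labels
#'
#' @param labels character vector.
#' @inheritParams parseVariantLabel
#' @return list of [MitoVariant-class].
#' @export
parseVariantLabels <- function(labels, genome = NULL) {
  lapply(labels, parseVariantLabel, genome = genome)
}

#' @rdname variantLabel
setMethod("variantLabel", "MitoVariant", function(x, style = c("short", "hgvs")) {
  style <- match.arg(style)
  if (style == "hgvs") {
    if (x@kind %in% c("transition", "transversion")) {
      if (!x@resolved)
        stop("cannot write HGVS form of an unresolved shorthand variant")
      return(sprintf("m.%d%s>%s", x@position, x@ref, x@alt))
    }
    stop("HGVS serialisation implemented for substitutions only")
  }
  out <- as.character(x@position)
  if (x@kind == "insertion")
    out <- paste0(out, "+", if (is.na(x@alt)) "" else x@alt)
  else if (x@kind == "deletion")
    out <- paste0(out, "d")
  else if (x@kind == "transversion" ||
           (x@resolved && x@alt != TRANSITION_PARTNER[x@ref]))
    out <- paste0(out, x@alt)
  else if (!x@resolved && !is.na(x@alt))
    out <- paste0(out, x@alt)
  if (!is.na(x@effectHint))
    out <- paste0(out, if (x@effectHint == "synonymous") "s" else "ns")
  if (x@isHeteroplasmic) out <- paste0(out, "h")
  if (!is.na(x@locusHint))
    out <- paste0(out, if (x@locusHint == "tRNA") "~t" else "~r")
  if (x@isReversion) out <- paste0("@", out)
  out
})

#' @rdname variantLabel
setMethod("variantKey", "MitoVariant", function(x) {
  base <- switch(x@kind,
    insertion = paste0(x@position, ":+", if (is.na(x@alt)) "" else x@alt),
    deletion  = paste0(x@position, ":d"),
    paste0(x@position, ":", if (is.na(x@alt)) "ts" else x@alt))
  if (x@isReversion) paste0("@", base) else base
})
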