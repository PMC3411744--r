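#' @include parse.R
NULL

#' Path to a packaged fixture file
#'
#' @param name file name under `extdata/`.
#' @return absolute path.
#' @export
mtFixture <- function(name) {
  p <- system.file("extdata", name, package = "mtLHON", mustWork = TRUE)
  p
}

#' Read a mitochondrial reference genome and its gene map
#'
#' The genome is a single-record FASTA (heavy strand, circular by convention);
#' the gene map is a tab-separated table with columns `gene`, `start`, `end`,
#' `strand`, `product` in 1-based inclusive coordinates (a BED-like dialect,
#' but 1-based and inclusive).  No gene-map entry may span the circular
#' origin.
#'
#' The packaged reference (`mtFixture("rcrs_synthetic.fasta")`) is a
#' deterministic synthetic stand-in for the 16,569-bp human reference: real
#' gene coordinates and the reference bases relevant to the packaged cohort,
#' with seeded random sequence elsewhere.
#'
#' @param fastaFile path to the genome FASTA.
#' @param geneMapFile path to the gene-map TSV.
#' @param controlRegion integer pair `c(start, end)` of the control region
#'   spanning the origin (positions `>= start` or `<= end`).
#' @param excludedPositions positions that are private mutations of the
#'   reference sequence, excluded when comparing haplotypes to it.
#' @return a [MitoGenome-class].
#' @export
readMitoGenome <- function(fastaFile, geneMapFile,
                           controlRegion = c(16024L, 576L),
                           excludedPositions = c(8860L, 15326L)) {
  seqs <- Biostrings::readDNAStringSet(fastaFile)
  if (length(seqs) != 1L)
    stop("expected a single-record genome FASTA, got ", length(seqs),
         " records")
  gm <- utils::read.delim(geneMapFile, stringsAsFactors = FALSE)
  required <- c("gene", "start", "end", "strand", "product")
  missing <- setdiff(required, names(gm))
  if (length(missing))
    stop("gene map is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (any(gm$start > gm$end))
    stop("gene map has start > end; genes may not span the circular origin")
  gr <- GenomicRanges::GRanges(
    seqnames = "chrM",
    ranges = IRanges::IRanges(start = gm$start, end = gm$end),
    strand = gm$strand)
  S4Vectors::mcols(gr)$gene <- gm$gene
  S4Vectors::mcols(gr)$product <- gm$product
  new("MitoGenome", seq = seqs[[1]], geneMap = gr,
      controlRegionStart = as.integer(controlRegion[1]),
      controlRegionEnd = as.integer(controlRegion[2]),
      excludedPositions = as.integer(excludedPositions))
}

# circular 1-based indexing into the genome
.circ_index <- function(pos, L) ((pos - 1L) %% L) + 1L

.genome_bases <- function(genome, pos) {
  L <- genomeLength(genome)
  s <- strsplit(as.character(genomeSeq(genome)), "")[[1]]
  s[.circ_index(pos, L)]
}

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# vertebrate mitochondrial genetic code (SGC1): ATA=Met, TGA=Trp, AGA/AGG=stop
.mito_code <- function() Biostrings::getGeneticCode("SGC1")

.in_control_region <- function(genome, pos) {
  pos >= genome@controlRegionStart | pos <= genome@controlRegionEnd
}

#' Annotate the protein-level consequence of a variant
#'
#' Locates the variant in the gene map, extracts the codon (circularly, for
#' synthetic genomes whose genes span the origin), translates reference and
#' mutated codon under the vertebrate mitochondrial genetic code, and returns
#' a [ProteinChange-class].  Light-strand genes are translated from the
#' reverse complement of the genomic span, with residue 1 at the
#' high-coordinate end.
#'
#' Positions in tRNA/rRNA genes or the control region return a noncoding
#' marker; synonymous substitutions return a synonymous marker; indels are
#' parsed but their consequence is not computed.
#'
#' @param variant a resolved substitution [MitoVariant-class] (indels are
#'   passed through with `consequence = "indel"`).
#' @param genome a [MitoGenome-class].
#' @return a [ProteinChange-class].
#' @examples
#' g <- readMitoGenome(mtFixture("rcrs_synthetic.fasta"),
#'                     mtFixture("rcrs_genemap.tsv"))
#' annotateProteinChange(parseVariantLabel("m.3700G>A", g), g)  # MT-ND1 p.A132T
#' @export
annotateProteinChange <- function(variant, genome) {
  stopifnot(is(variant, "MitoVariant"), is(genome, "MitoGenome"))
  pos <- variant@position
  if (variant@kind %in% c("insertion", "deletion"))
    return(new("ProteinChange", gene = NA_character_,
               residueIndex = NA_integer_, refAA = NA_character_,
               altAA = NA_character_, codonPosition = NA_integer_,
               consequence = "indel", locusType = NA_character_))
  if (!variant@resolved)
    stop("variant must be resolved against the genome before annotation")

  gm <- geneMap(genome)
  hit <- which(GenomicRanges::start(gm) <= pos & GenomicRanges::end(gm) >= pos)
  if (!length(hit)) {
    if (.in_control_region(genome, pos))
      return(new("ProteinChange", gene = NA_character_,
                 residueIndex = NA_integer_, refAA = NA_character_,
                 altAA = NA_character_, codonPosition = NA_integer_,
                 consequence = "noncoding", locusType = "control-region"))
    stop("position ", pos, " falls in no gene-map entry and outside the ",
         "control region: unannotatable")
  }
  hit <- hit[1L]
  product <- S4Vectors::mcols(gm)$product[hit]
  gene <- S4Vectors::mcols(gm)$gene[hit]
  if (product %in% c("tRNA", "rRNA"))
    return(new("ProteinChange", gene = gene, residueIndex = NA_integer_,
               refAA = NA_character_, altAA = NA_character_,
               codonPosition = NA_integer_, consequence = "noncoding",
               locusType = product))

  st <- GenomicRanges::start(gm)[hit]; en <- GenomicRanges::end(gm)[hit]
  minus <- as.character(GenomicRanges::strand(gm))[hit] == "-"
  span <- en - st + 1L
  if (span %% 3L != 0L)
    stop("gene-map integrity error: span of ", gene,
         " is not divisible by 3")

  idx <- if (minus) en - pos + 1L else pos - st + 1L   # 1-based coding index
  residue <- (idx - 1L) %/% 3L + 1L
  codonPos <- idx - 3L * (residue - 1L)
  gpos <- if (minus) (en - 3L * (residue - 1L)) - 0:2
          else (st + 3L * (residue - 1L)) + 0:2
  bases <- .genome_bases(genome, gpos)
  codingRef <- if (minus) unname(.COMPLEMENT[bases]) else bases
  code <- .mito_code()
  refAA <- unname(code[paste(codingRef, collapse = "")])

  codingAlt <- codingRef
  codingAlt[codonPos] <- if (minus) unname(.COMPLEMENT[variant@alt]) else variant@alt
  altAA <- unname(code[paste(codingAlt, collapse = "")])

  new("ProteinChange", gene = gene, residueIndex = residue,
      refAA = refAA, altAA = altAA, codonPosition = codonPos,
      consequence = if (refAA == altAA) "synonymous" else "missense",
      locusType = NA_character_)
}

#' Apply a substitution variant to a genome sequence
#'
#' Returns a copy of the heavy-strand sequence with the alternate base
#' substituted; used by the annotation self-consistency checks and the
#' in-silico RFLP assay.
#'
#' @param genome a [MitoGenome-class] or [Biostrings::DNAString].
#' @param variant a resolved substitution [MitoVariant-class].
#' @return a [Biostrings::DNAString].
#' @export
applyVariant <- function(genome, variant) {
  s <- if (is(genome, "MitoGenome")) genomeSeq(genome) else genome
  if (!variant@kind %in% c("transition", "transversion"))
    stop("only substitutions can be applied")
  if (!variant@resolved) stop("variant must be resolved")
  cur <- as.character(Biostrings::subseq(s, variant@position, variant@position))
  if (cur != variant@ref)
    stop("reference mismatch at ", variant@position, ": genome has ", cur,
         ", variant expects ", variant@ref)
  Biostrings::replaceLetterAt(s, variant@position, variant@alt)
}

#' Translate a gene from a genome
#'
#' Direct translation of a gene-map entry under the vertebrate mitochondrial
#' code; the independent route used to cross-check [annotateProteinChange()].
#'
#' @param genome a [MitoGenome-class], or a `DNAString` together with
#'   `start`, `end`, `minus`.
#' @param gene gene name in the gene map.
#' @return an `AAString` of the protein.
#' @export
translateGene <- function(genome, gene) {
  gm <- geneMap(genome)
  i <- match(gene, S4Vectors::mcols(gm)$gene)
  if (is.na(i)) stop("gene ", gene, " not in the gene map")
  s <- Biostrings::subseq(genomeSeq(genome), GenomicRanges::start(gm)[i],
                          GenomicRanges::end(gm)[i])
  if (as.character(GenomicRanges::strand(gm))[i] == "-")
    s <- Biostrings::reverseComplement(s)
  Biostrings::translate(s, genetic.code = .mito_code())
}
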