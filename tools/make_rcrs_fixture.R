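# Builds inst/extdata/rcrs_synthetic.fasta and rcrs_genemap.tsv.
#
# The genome is a SYNTHETIC stand-in for the 16,569-bp human mitochondrial
# reference (rCRS): same length, real gene coordinates (CDS spans trimmed to
# codon multiples, incomplete stop codons excluded), and the reference bases /
# codons planted at every position the packaged fixtures refer to, so that the
# documented nucleotide -> protein consequences hold exactly under the
# vertebrate mitochondrial code.  Everything else is seeded random sequence.
# Rerunning this script reproduces the shipped files byte for byte.

set.seed(20120803L)

L <- 16569L

gene_map <- data.frame(
  gene = c("MT-TF", "MT-RNR1", "MT-TV", "MT-RNR2", "MT-TL1",
           "MT-ND1", "MT-TI", "MT-TM",
           "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6", "MT-CO3",
           "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB"),
  start = c(577L, 648L, 1602L, 1671L, 3230L,
            3307L, 4263L, 4402L,
            4470L, 5904L, 7586L, 8366L, 8527L, 9207L,
            10059L, 10470L, 10767L, 12337L, 14149L, 14747L),
  end   = c(647L, 1601L, 1670L, 3229L, 3304L,
            4260L, 4331L, 4469L,
            5510L, 7445L, 8269L, 8524L, 9204L, 9989L,
            10403L, 10766L, 12137L, 14148L, 14673L, 15886L),
  strand = c("+", "+", "+", "+", "+",
             "+", "+", "+",
             "+", "+", "+", "+", "+", "+",
             "+", "+", "+", "+", "-", "+"),
  product = c("tRNA", "rRNA", "tRNA", "rRNA", "tRNA",
              "protein", "tRNA", "tRNA",
              "protein", "protein", "protein", "protein", "protein", "protein",
              "protein", "protein", "protein", "protein", "protein", "protein"),
  stringsAsFactors = FALSE
)

# Genomic (heavy-strand) base constraints: every position a packaged fixture
# names, plus the full codons behind the nine documented protein consequences.
codon_plants <- list(
  c(3700L, "GCC"),   # MT-ND1  codon 132 Ala  -> 3700G>A gives p.A132T
  c(3733L, "GAA"),   # MT-ND1  codon 143 Glu  -> G>A p.E143K, G>C p.E143Q
  c(4171L, "CTA"),   # MT-ND1  codon 289 Leu  -> 4171C>A p.L289M, 4172T>A p.L289Q
  c(10662L, "GTA"),  # MT-ND4L codon 65  Val  -> 10663T>C p.V65A
  c(14458L, "GGC"),  # MT-ND6  codon 72  Ala (light strand) -> 14459G>A p.A72V
  c(14482L, "CAT"),  # MT-ND6  codon 64  Met  -> 14482C>A p.M64I (14484T>C p.M64V)
  c(14494L, "TAA"),  # MT-ND6  codon 60  Leu  -> 14495A>G p.L60S
  c(14566L, "GCC")   # MT-ND6  codon 36  Gly  -> 14568C>T p.G36S
)
base_plants <- c(
  "263" = "A",
  "4216" = "T", "5074" = "T", "7299" = "A", "7632" = "T", "7805" = "A",
  "7859" = "G", "8393" = "C", "8701" = "A", "8860" = "A", "9053" = "G",
  "9055" = "G", "9091" = "A", "10398" = "A", "11084" = "A", "13145" = "G",
  "13708" = "G", "13759" = "G", "13780" = "A", "13934" = "C", "13966" = "A",
  "14325" = "C", "14502" = "T", "14766" = "C", "14798" = "T", "14927" = "A",
  "15221" = "A", "15257" = "G", "15326" = "A", "15452" = "C", "15812" = "G"
)

constraint <- rep(NA_character_, L)
for (cp in codon_plants) {
  at <- as.integer(cp[[1]])
  constraint[at:(at + 2L)] <- strsplit(cp[[2]], "")[[1]]
}
for (nm in names(base_plants)) {
  at <- as.integer(nm)
  if (!is.na(constraint[at]) && constraint[at] != base_plants[[nm]])
    stop("conflicting constraint at ", at)
  constraint[at] <- base_plants[[nm]]
}

bases <- c("A", "C", "G", "T")
comp <- c(A = "T", C = "G", G = "C", T = "A")
genome <- sample(bases, L, replace = TRUE)

# Vertebrate mitochondrial code stops: TAA, TAG, AGA, AGG.
stops <- c("TAA", "TAG", "AGA", "AGG")
all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
ok_codons <- setdiff(all_codons, stops)

# Rewrite every protein-coding span codon by codon: uniform over non-stop
# codons consistent with the planted genomic bases (light-strand genes sample
# in coding sense, then write the reverse complement).
revcomp <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")

for (i in which(gene_map$product == "protein")) {
  st <- gene_map$start[i]; en <- gene_map$end[i]
  n_codon <- (en - st + 1L) %/% 3L
  minus <- gene_map$strand[i] == "-"
  for (k in seq_len(n_codon)) {
    # genomic positions of coding codon k, in coding order
    gpos <- if (minus) (en - 3L * (k - 1L)) - 0:2 else (st + 3L * (k - 1L)) + 0:2
    want <- constraint[gpos]                      # genomic-sense constraints
    want_coding <- if (minus) unname(comp[want]) else want
    cand <- ok_codons
    for (j in 1:3) {
      if (!is.na(want_coding[j]))
        cand <- cand[substr(cand, j, j) == want_coding[j]]
    }
    if (!length(cand)) stop("unsatisfiable codon at gene ", gene_map$gene[i], " codon ", k)
    codon <- sample(cand, 1L)
    cc <- strsplit(codon, "")[[1]]
    genome[gpos] <- if (minus) unname(comp[cc]) else cc
  }
}

# Non-coding planted bases (control region etc.)
noncoding <- which(!is.na(constraint))
in_cds <- logical(L)
for (i in which(gene_map$product == "protein"))
  in_cds[gene_map$start[i]:gene_map$end[i]] <- TRUE
for (at in noncoding[!in_cds[noncoding]]) genome[at] <- constraint[at]

stopifnot(identical(genome[!is.na(constraint)], constraint[!is.na(constraint)]))

seq <- paste(genome, collapse = "")
lines <- substring(seq, seq(1, L, 70), pmin(seq(1, L, 70) + 69, L))
out <- file.path("inst", "extdata")
writeLines(c(">rCRS_synthetic synthetic stand-in for the 16,569-bp human mtDNA reference (seeded; see tools/make_rcrs_fixture.R)",
             lines), file.path(out, "rcrs_synthetic.fasta"))
write.table(gene_map, file.path(out, "rcrs_genemap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(out, "rcrs_synthetic.fasta"), "and rcrs_genemap.tsv\n")
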