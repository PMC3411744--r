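test_that("shorthand and HGVS-like labels parse to fully resolved variants", {
  g <- ref_genome()

  v <- parseVariantLabel("3700", g)
  expect_equal(variantPosition(v), 3700L)
  expect_equal(refBase(v), "G")
  expect_equal(altBase(v), "A")
  expect_equal(variantKind(v), "transition")

  v <- parseVariantLabel("14482A", g)
  expect_equal(refBase(v), "C")
  expect_equal(altBase(v), "A")
  expect_equal(variantKind(v), "transversion")
  expect_equal(variantLabel(v, "hgvs"), "m.14482C>A")

  v <- parseVariantLabel("@263", g)
  expect_true(isReversion(v))
  expect_equal(variantPosition(v), 263L)

  v <- parseVariantLabel("m.3733G>C", g)
  expect_equal(variantKind(v), "transversion")
  expect_equal(altBase(v), "C")

  # suffix annotations
  v <- parseVariantLabel("3915s", g)
  expect_equal(v@effectHint, "synonymous")
  v <- parseVariantLabel("5821h~t", g)
  expect_true(isHeteroplasmic(v))
  expect_equal(v@locusHint, "tRNA")
  v <- parseVariantLabel("960d", g)
  expect_equal(variantKind(v), "deletion")
  v <- parseVariantLabel("573+C", g)
  expect_equal(variantKind(v), "insertion")
  expect_equal(altBase(v), "C")
})

test_that("parsing without a genome leaves shorthand transitions unresolved", {
  v <- parseVariantLabel("3700")
  expect_false(isResolved(v))
  expect_equal(variantKind(v), "transition")
  expect_true(is.na(refBase(v)))
})

test_that("parse errors name the offending token and check bounds", {
  g <- ref_genome()
  expect_error(parseVariantLabel("3700zz", g), "unknown token")
  expect_error(parseVariantLabel("99999", g), "outside")
  expect_error(parseVariantLabel("m.3700C>A", g), "mismatch")
  expect_error(parseVariantLabel("m.3700G>G", g), "identical")
  expect_error(classifySubstitution("A", "A"), "identical")
})

test_that("transition/transversion classification follows base classes", {
  expect_equal(classifySubstitution("G", "A"), "transition")
  expect_equal(classifySubstitution("T", "C"), "transition")
  expect_equal(classifySubstitution("C", "A"), "transversion")
  expect_equal(classifySubstitution("G", "T"), "transversion")
})

test_that("labels round-trip through parse and canonical serialisation", {
  g <- ref_genome()
  cases <- c("3700", "14482A", "@263", "3915s", "12705ns", "5821h",
             "573+C", "960d", "1234~r")
  for (lab in cases) {
    v1 <- parseVariantLabel(lab, g)
    v2 <- parseVariantLabel(variantLabel(v1, "short"), g)
    expect_equal(variantKey(v1), variantKey(v2), info = lab)
    expect_equal(isHeteroplasmic(v1), isHeteroplasmic(v2), info = lab)
    expect_equal(v1@effectHint, v2@effectHint, info = lab)
  }
  # property over randomly generated labels
  set.seed(42)
  for (i in 1:200) {
    pos <- sample(16569L, 1)
    suffix <- sample(c("", "A", "C", "G", "T", "s", "ns", "h", "d"), 1)
    ref <- as.character(Biostrings::subseq(genomeSeq(g), pos, pos))
    if (suffix == ref) next  # explicit base equal to reference is an error
    lab <- paste0(pos, suffix)
    v1 <- parseVariantLabel(lab, g)
    v2 <- parseVariantLabel(variantLabel(v1, "short"), g)
    expect_equal(variantKey(v1), variantKey(v2))
  }
})

test_that("the nine documented nucleotide->protein pairs annotate exactly", {
  g <- ref_genome()
  expected <- list(
    c("m.3700G>A", "MT-ND1", "p.A132T"),
    c("m.3733G>A", "MT-ND1", "p.E143K"),
    c("m.3733G>C", "MT-ND1", "p.E143Q"),
    c("m.4171C>A", "MT-ND1", "p.L289M"),
    c("m.10663T>C", "MT-ND4L", "p.V65A"),
    c("m.14459G>A", "MT-ND6", "p.A72V"),
    c("m.14482C>A", "MT-ND6", "p.M64I"),
    c("m.14495A>G", "MT-ND6", "p.L60S"),
    c("m.14568C>T", "MT-ND6", "p.G36S"))
  for (e in expected) {
    pc <- annotateProteinChange(parseVariantLabel(e[1], g), g)
    expect_equal(pc@gene, e[2], info = e[1])
    expect_equal(proteinLabel(pc), e[3], info = e[1])
  }
  # codon positions consistent with the gene frame
  pc <- annotateProteinChange(parseVariantLabel("m.3700G>A", g), g)
  expect_equal(pc@codonPosition, 1L)
  pc <- annotateProteinChange(parseVariantLabel("m.10663T>C", g), g)
  expect_equal(pc@codonPosition, 2L)
})

test_that("annotation is self-consistent with direct translation of the mutated gene", {
  g <- ref_genome()
  gm <- geneMap(g)
  set.seed(7)
  genes <- which(S4Vectors::mcols(gm)$product == "protein")
  for (i in sample(genes, 5)) {
    st <- GenomicRanges::start(gm)[i]; en <- GenomicRanges::end(gm)[i]
    minus <- as.character(GenomicRanges::strand(gm))[i] == "-"
    for (rep in 1:8) {
      pos <- sample(st:en, 1)
      ref <- as.character(Biostrings::subseq(genomeSeq(g), pos, pos))
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      v <- parseVariantLabel(sprintf("m.%d%s>%s", pos, ref, alt), g)
      pc <- annotateProteinChange(v, g)
      mut <- applyVariant(g, v)
      cds <- Biostrings::subseq(mut, st, en)
      if (minus) cds <- Biostrings::reverseComplement(cds)
      aa <- as.character(Biostrings::translate(
        cds, genetic.code = Biostrings::getGeneticCode("SGC1")))
      expect_equal(substr(aa, pc@residueIndex, pc@residueIndex), pc@altAA)
    }
  }
})

test_that("noncoding and degenerate-codon cases annotate as markers", {
  g <- ref_genome()
  # control region
  pc <- annotateProteinChange(parseVariantLabel("m.263A>G", g), g)
  expect_equal(pc@consequence, "noncoding")
  expect_equal(pc@locusType, "control-region")
  # rRNA
  v <- parseVariantLabel("1000", g)
  pc <- annotateProteinChange(v, g)
  expect_equal(pc@consequence, "noncoding")
  expect_equal(pc@locusType, "rRNA")
  # third-position transition in a four-fold degenerate codon is synonymous:
  # GGC -> GGT (both Gly)
  tg <- toy_genome("AAAATGGGCTT",
                   data.frame(gene = "toy", start = 4, end = 9,
                              strand = "+", product = "protein"))
  pc <- annotateProteinChange(parseVariantLabel("m.9C>T", tg), tg)
  expect_equal(pc@consequence, "synonymous")
  # indels parse but are not annotated
  pc <- annotateProteinChange(parseVariantLabel("573+C", g), g)
  expect_equal(pc@consequence, "indel")
})

test_that("annotation errors: unannotatable positions and corrupt gene maps", {
  g <- ref_genome()
  # 8525 sits between two coding genes, outside the control region
  expect_error(annotateProteinChange(parseVariantLabel("8525", g), g),
               "unannotatable")
  tg <- toy_genome("AAATGGGCTTT",
                   data.frame(gene = "bad", start = 4, end = 10,
                              strand = "+", product = "protein"))
  expect_error(annotateProteinChange(parseVariantLabel("m.5G>A", tg), tg),
               "integrity|divisible")
})

test_that("codons extract correctly at the far end of the genome", {
  seq <- paste(rep("ACGT", 6), collapse = "")  # 24 bp
  tg <- toy_genome(seq, data.frame(gene = "toy", start = 13, end = 24,
                                   strand = "+", product = "protein"))
  v <- parseVariantLabel("m.24T>A", tg)
  pc <- annotateProteinChange(v, tg)
  expect_equal(pc@residueIndex, 4L)
  expect_equal(pc@codonPosition, 3L)
})

test_that("reference-private positions are excluded when reading cohorts", {
  g <- ref_genome()
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tvariants", "s1\t8860,15326,3700"), f)
  cohort <- readCohort(f, g)
  keys <- vapply(haplotypeVariants(cohort[[1]]), variantKey, character(1))
  expect_equal(keys, "3700:A")
})
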