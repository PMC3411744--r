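random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("amplicons span primer start through reverse-primer end", {
  # unique 10-bp primers at offsets 5 and 80 of a 100-bp genome
  set.seed(101)
  g <- random_dna(100, 101)
  fwd <- substr(g, 6, 15)
  revBind <- substr(g, 81, 90)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(revBind)))
  amp <- simulateAmplicon(g, fwd, rev)
  expect_equal(amp$length, 85L)  # 6..90 inclusive
  expect_equal(amp$start, 6L)
  expect_equal(as.character(amp$amplicon), substr(g, 6, 90))
})

test_that("primer failures are reported: absent, multiple, degenerate", {
  g <- random_dna(100, 102)
  fwd <- substr(g, 6, 15)
  expect_error(simulateAmplicon(g, fwd, "AAAAAAAAAA"), "not found")
  g2 <- paste0(g, substr(g, 1, 30))  # duplicate the forward site
  expect_error(
    simulateAmplicon(paste0(substr(g2, 1, 115), "G"), fwd,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAString(substr(g, 81, 90))))),
    "ambiguous")
  # forward primer equal to the reverse complement of the reverse primer
  expect_error(simulateAmplicon(g, fwd, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd)))),
    "ambiguous")
})

test_that("amplicons wrap across the circular origin", {
  g <- random_dna(200, 103)
  # forward primer near the end, reverse-binding site near the start
  fwd <- substr(g, 181, 190)
  revBind <- substr(g, 21, 30)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(revBind)))
  amp <- simulateAmplicon(g, fwd, rev)
  expect_equal(amp$length, 50L)  # 181..200 plus 1..30
  expect_equal(as.character(amp$amplicon),
               paste0(substr(g, 181, 200), substr(g, 1, 30)))
})

test_that("digests cut at the offset and fragment lengths sum to the amplicon", {
  ecoRI <- restrictionEnzyme("EcoRI", "GAATTC", 1L)
  # no site
  d <- digestAmplicon("ACGTACGTACGT", ecoRI)
  expect_equal(fragments(d), 12L)
  # one planted site, cut after position 20 + 1 - 1 = 20... site at 21
  amp <- paste0(strrep("AC", 10), "GAATTC", strrep("GT", 10))
  d <- digestAmplicon(amp, ecoRI)
  expect_equal(fragments(d), c(21L, 25L))
  expect_equal(sum(fragments(d)), nchar(amp))
  # palindromic site counted once, not twice
  expect_equal(length(fragments(d)), 2L)

  # non-palindromic recognition is also found on the bottom strand
  enz <- restrictionEnzyme("toy", "GGATC", 1L)
  amp2 <- paste0("AAAAA", "GGATC", "AAAAA", "GATCC", "AAAAA")
  d2 <- digestAmplicon(amp2, enz)
  expect_equal(length(fragments(d2)), 3L)
  expect_equal(sum(fragments(d2)), nchar(amp2))

  # degenerate IUPAC recognition
  hinfI <- restrictionEnzyme("HinfI", "GANTC", 1L)
  d3 <- digestAmplicon("AAAGACTCAAA", hinfI)
  expect_equal(sum(fragments(d3)), 11L)
  expect_equal(length(fragments(d3)), 2L)

  # conservation property over random amplicons and enzymes
  for (i in 1:20) {
    amp <- random_dna(sample(50:300, 1), 300 + i)
    d <- digestAmplicon(amp, ecoRI)
    expect_equal(sum(fragments(d)), nchar(amp))
  }
})

test_that("differential digestion finds allele-diagnostic fragments", {
  # build a genome where the alt base completes a GAATTC site inside the
  # amplicon: wild GAcTTC (uncut), mutant GAATTC (cut)
  set.seed(104)
  left <- random_dna(40, 105)
  right <- random_dna(40, 106)
  seq <- paste0(left, "GACTTC", right)
  tg <- toy_genome(seq, data.frame(gene = "toy", start = 1, end = 3,
                                   strand = "+", product = "tRNA"))
  v <- parseVariantLabel(sprintf("m.%dC>A", 43), tg)
  fwd <- substr(seq, 3, 14)
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seq, 70, 82))))
  ecoRI <- restrictionEnzyme("EcoRI", "GAATTC", 1L)
  dd <- differentialDigest(tg, v, fwd, rev, ecoRI)
  expect_equal(length(fragments(dd$wild)), 1L)
  expect_equal(length(fragments(dd$mutant)), 2L)
  expect_setequal(dd$diagnostic$wild, fragments(dd$wild))
  expect_setequal(dd$diagnostic$mutant, fragments(dd$mutant))

  # a variant that touches no site is an uninformative assay; position 20
  # lies inside the amplicon but outside both primers and the planted site
  ref20 <- substr(seq, 20, 20)
  alt20 <- setdiff(c("C", "T", "A", "G"), c(ref20, "G", "A"))[1]
  v2 <- parseVariantLabel(sprintf("m.20%s>%s", ref20, alt20), tg)
  expect_error(differentialDigest(tg, v2, fwd, rev, ecoRI),
               "uninformative")

  # a variant outside the amplicon is a design error
  ref2 <- substr(seq, 86, 86)
  v3 <- parseVariantLabel(sprintf("m.86%s>%s", ref2,
                                  setdiff(c("A", "C", "G", "T"), ref2)[1]),
                          tg)
  expect_error(differentialDigest(tg, v3, fwd, rev, ecoRI), "outside")

  # destroying one of two sites removes one fragment
  seq2 <- paste0(left, "GAATTC", substr(right, 1, 20), "GAATTC",
                 random_dna(20, 107))
  tg2 <- toy_genome(seq2, data.frame(gene = "toy", start = 1, end = 3,
                                     strand = "+", product = "tRNA"))
  v4 <- parseVariantLabel("m.43A>C", tg2)
  fwd2 <- substr(seq2, 3, 14)
  rev2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seq2, 80, 92))))
  dd2 <- differentialDigest(tg2, v4, fwd2, rev2, ecoRI)
  expect_equal(length(fragments(dd2$mutant)),
               length(fragments(dd2$wild)) - 1L)
})

test_that("heteroplasmy estimation is molarity-weighted and exact at the boundaries", {
  # zero mutant signal
  bands <- data.frame(allele = c("wild", "mutant"), length = c(300, 200),
                      intensity = c(5, 0))
  expect_equal(estimateHeteroplasmy(bands), 0)
  # pure mutant
  bands$intensity <- c(0, 7)
  expect_equal(estimateHeteroplasmy(bands), 100)
  # equal-length, equal-intensity bands: 50%
  bands <- data.frame(allele = c("wild", "mutant"), length = c(200, 200),
                      intensity = c(3, 3))
  expect_equal(estimateHeteroplasmy(bands), 50)
  # length normalisation: doubling lengths at fixed molarity doubles
  # intensity and leaves the estimate unchanged
  b1 <- data.frame(allele = c("wild", "mutant"), length = c(100, 300),
                   intensity = c(0.6 * 100, 0.4 * 300))
  b2 <- transform(b1, length = length * 2, intensity = intensity * 2)
  expect_equal(estimateHeteroplasmy(b1), estimateHeteroplasmy(b2))
  expect_equal(estimateHeteroplasmy(b1), 40)
  # error cases
  expect_error(estimateHeteroplasmy(
    data.frame(allele = c("wild", "mutant"), length = c(1, 1),
               intensity = c(0, 0))), "signal")
  expect_error(estimateHeteroplasmy(
    data.frame(allele = c("wild", "mutant"), length = c(1, 1),
               intensity = c(-1, 1))), "negative")
  expect_error(estimateHeteroplasmy(
    data.frame(allele = "wild", length = 1, intensity = 1)), "diagnostic")
})

test_that("the estimator recovers a 41% mutant load under multiplicative noise", {
  hits <- 0L
  n <- 200L
  for (i in seq_len(n)) {
    gel <- simulateGel(0.41, wildLengths = c(210, 90),
                       mutantLengths = c(200, 100), sigma = 0.05,
                       seed = 9000 + i)
    est <- estimateHeteroplasmy(gel)
    if (abs(est - 41) <= 5) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("gel simulation is deterministic and honours its config checks", {
  g1 <- simulateGel(0.5, 200, 200, sigma = 0, seed = 1)
  expect_equal(g1$intensity[1], g1$intensity[2])  # sigma 0, equal lengths
  g2 <- simulateGel(0.41, c(210, 90), 300, seed = 77)
  g3 <- simulateGel(0.41, c(210, 90), 300, seed = 77)
  expect_identical(g2, g3)
  expect_error(simulateGel(0.5, 100, 100, sigma = -1), "sigma")
  expect_error(simulateGel(1.5, 100, 100), "fraction")
  expect_error(simulateGel(0.5, -10, 100), "positive")
})

test_that("assay definition tables read into enzyme objects", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("mutation\tforward\treverse\tenzyme\trecognition\tcut_offset",
               "m.1G>A\tACGT\tTGCA\tEcoRI\tGAATTC\t1"), f)
  assays <- readAssayTable(f)
  expect_equal(assays[[1]]$enzyme@name, "EcoRI")
  expect_error(restrictionEnzyme("x", "GAT", 1), "at least 4")
})
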