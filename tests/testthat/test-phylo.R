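test_that("the cohort tree fixture parses with all leaves and haplogroups", {
  tree <- cohort_tree()
  expect_equal(length(leafLabels(tree)), 17L)  # 16 probands + control I
  expected_hg <- c("H", "H26a", "H66", "H1c1", "H10", "U6a1a1", "K1a",
                   "J1c3", "J1c3e1", "J1c", "J1c2e", "J1c2", "J2b1", "X2b",
                   "I5a", "L2a1")
  expect_true(all(expected_hg %in% haplogroupLabels(tree)))
})

test_that("trees round-trip through both serialisation dialects", {
  tree <- cohort_tree()
  g <- ref_genome()
  for (fmt in c("indented", "newick")) {
    txt <- serializePhylogeny(tree, fmt)
    tree2 <- parsePhylogeny(txt, g)
    expect_equal(tree2@label, tree@label)
    expect_equal(tree2@parent, tree@parent)
    expect_equal(tree2@haplogroup, tree@haplogroup)
    expect_equal(tree2@mutationKeys, tree@mutationKeys)
    # fixpoint
    expect_identical(serializePhylogeny(tree2, fmt), txt)
  }
  # trivial newick
  t0 <- parsePhylogeny("(A,B)R;")
  expect_equal(sort(leafLabels(t0)), c("A", "B"))
  expect_equal(sum(lengths(t0@mutations)), 0L)
})

test_that("malformed tree documents are rejected with diagnostics", {
  expect_error(parsePhylogeny("((A,B)R;"), "unbalanced|parenthes")
  expect_error(parsePhylogeny(c("root", "    deep ; muts=1")), "level")
  expect_error(parsePhylogeny(character(0)), "empty")
})

test_that("haplogroup assignment maximises matched minus missing motif", {
  g <- ref_genome()
  tree <- cohort_tree()
  # exactly the root-to-J1c motif
  asg <- assignHaplogroup(c("4216", "10398", "13708", "14766", "14798",
                            "15452A"), tree, g)
  expect_equal(asg$haplogroup, "J1c")
  # empty haplotype sits at the reference root
  asg <- assignHaplogroup(character(0), tree, g)
  expect_equal(asg$haplogroup, "H")
  # every cohort sample is assigned its recorded haplogroup or an ancestor
  # sharing its full non-synonymous motif (H subclades have no such marker)
  cohort <- cohort_profiles()
  hg <- attr(cohort, "haplogroups")
  collapsed <- c(H = "H", H26a = "H", H66 = "H", H1c1 = "H", H10 = "H",
                 U6a1a1 = "U6a1a1", K1a = "K1a", J1c3 = "J1c3",
                 J1c3e1 = "J1c3e1", J1c = "J1c", J1c2e = "J1c",
                 J1c2 = "J1c", J2b1 = "J2b", X2b = "X2b", I5a = "I5a",
                 L2a1 = "L2a1")
  for (h in cohort) {
    asg <- assignHaplogroup(h, tree, g)
    expect_equal(asg$haplogroup, unname(collapsed[hg[sampleId(h)]]),
                 info = sampleId(h))
  }
})

test_that("simulated haplotypes recover their planted haplogroup", {
  hits <- 0L
  n <- 200L
  for (i in seq_len(n)) {
    sim <- simulateCohort(nLeaves = 8L, meanMutations = 2,
                          seed = 1000L + i)
    h <- sim$cohort[[1L]]
    asg <- assignHaplogroup(h, sim$phylogeny)
    truth <- sim$truth$plantedHaplogroup[[sampleId(h)]]
    if (identical(asg$haplogroup, truth)) hits <- hits + 1L
  }
  expect_gte(hits / n, 0.95)
})

test_that("independent-origin counts on the cohort fixture match the recorded events", {
  tree <- cohort_tree()
  oc <- countIndependentOrigins(tree, carrier_states("3700"),
                                variant = "m.3700G>A")
  expect_equal(nOrigins(oc), 2L)
  expect_setequal(originBranches(oc), c("F1", "F2"))

  oc <- countIndependentOrigins(tree, carrier_states("14568"),
                                variant = "m.14568C>T")
  expect_equal(nOrigins(oc), 5L)
  expect_setequal(originBranches(oc), c("F4", "F6", "F7", "F11", "F12"))

  # reversible parsimony cannot merge the F11/F12 pair because the
  # non-carrier control I sits between them
  oc <- countIndependentOrigins(tree, carrier_states("14568"),
                                mode = "reversible")
  expect_equal(nOrigins(oc), 5L)

  oc <- countIndependentOrigins(tree, carrier_states("14482A"))
  expect_equal(nOrigins(oc), 2L)
})

test_that("single carriers, missing states and carrier-free inputs behave", {
  tree <- cohort_tree()
  st <- carrier_states("10663")
  oc <- countIndependentOrigins(tree, st)
  expect_equal(nOrigins(oc), 1L)
  expect_equal(originBranches(oc), "F16")
  expect_error(countIndependentOrigins(tree, st[-1]), "missing")
  oc <- countIndependentOrigins(tree, st & FALSE)
  expect_equal(nOrigins(oc), 0L)
})

test_that("parsimony counts equal the exhaustive-labeling oracle on random trees", {
  set.seed(11)
  for (i in 1:150) {
    n <- sample(3:8, 1)
    tree <- randomTopology(n, seed = i)
    states <- stats::setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                              leafLabels(tree))
    for (mode in c("irreversible", "reversible")) {
      got <- nOrigins(countIndependentOrigins(tree, states, mode = mode))
      expect_equal(got, oracle_origins(tree, states, mode),
                   info = sprintf("tree %d mode %s", i, mode))
    }
  }
})

test_that("parsimony bounds and clade behaviour hold on random trees", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    tree <- randomTopology(n, seed = 500 + i)
    states <- stats::setNames(sample(c(TRUE, FALSE), n, replace = TRUE),
                              leafLabels(tree))
    irr <- nOrigins(countIndependentOrigins(tree, states))
    rev <- nOrigins(countIndependentOrigins(tree, states,
                                            mode = "reversible"))
    expect_lte(irr, sum(states))      # never more origins than carriers
    expect_gte(irr, rev * 0 + (sum(states) > 0))  # >=1 when carriers exist
    expect_gte(irr, rev)              # gains-only is the more conservative
  }
  # a clean carrier clade needs exactly one gain in either mode
  tree <- parsePhylogeny("((a,b)ab,(c,d)cd)root;")
  st <- c(a = TRUE, b = TRUE, c = FALSE, d = FALSE)
  expect_equal(nOrigins(countIndependentOrigins(tree, st)), 1L)
  expect_equal(nOrigins(countIndependentOrigins(tree, st,
                                                mode = "reversible")), 1L)
})

test_that("recurrent branch mutations are flagged by exact multiset accounting", {
  tree <- cohort_tree()
  rec <- flagRecurrentMutations(tree)
  r14568 <- rec[rec$key == "14568:T", ]
  expect_equal(r14568$count, 5L)
  expect_false("10663:C" %in% rec$key)  # single branch, not flagged
  # heteroplasmy flags collapse onto one key
  t2 <- parsePhylogeny(c("root", "  a ; muts=5000h", "  b ; muts=5000"))
  expect_equal(flagRecurrentMutations(t2)$count, 2L)
  # simulator-planted duplicates are flagged iff planted twice or more
  sim <- simulateCohort(nLeaves = 6, focalVariant = "9999",
                        originBranches = c("t1", "t2"), seed = 3)
  expect_true("9999:ts" %in% flagRecurrentMutations(sim$phylogeny)$key)
})

test_that("variants classify as ancient on haplogroup paths and recent otherwise", {
  g <- ref_genome()
  tree <- cohort_tree()
  cohort <- cohort_profiles()
  f10 <- cohort[[match("F10", vapply(cohort, sampleId, character(1)))]]
  expect_equal(classifyVariantAge("13708", f10, tree, g), "ancient")
  expect_equal(classifyVariantAge("14482A", f10, tree, g), "recent")
  # simulator-planted private variant is recent on every replicate
  for (i in 1:20) {
    sim <- simulateCohort(nLeaves = 6, seed = 40 + i)
    h <- sim$cohort[[1]]
    # take a variant on the leaf's own pendant branch
    lf <- match(sampleId(h), sim$phylogeny@label)
    pv <- sim$phylogeny@mutations[[lf]][1]
    expect_equal(classifyVariantAge(pv, h, sim$phylogeny), "recent")
  }
})

test_that("haplogroup enrichment reproduces the cohort fraction and fold change", {
  cohort <- cohort_profiles()
  hg <- attr(cohort, "haplogroups")
  enr <- haplogroupEnrichment(unname(hg), c("J1c", "J2b"), 0.062,
                              cohort_tree())
  expect_equal(enr$nCarriers, 6L)   # rows 8-13 of the cohort table
  expect_equal(enr$cohortFraction, 0.375)
  # the reported 5.6-fold enrichment, from a 35% cohort fraction vs 6.2%
  enr2 <- haplogroupEnrichment(c(rep("J1c", 35), rep("H", 65)),
                               c("J1c", "J2b"), 0.062)
  expect_equal(round(enr2$foldEnrichment, 1), 5.6)
  # trivial identity and scale invariance
  enr3 <- haplogroupEnrichment(c("J1c", rep("X", 9)), "J1c", 0.1)
  expect_equal(enr3$foldEnrichment, 1.0)
  enr4 <- haplogroupEnrichment(rep(c("J1c", rep("X", 9)), 7), "J1c", 0.1)
  expect_equal(enr4$foldEnrichment, enr3$foldEnrichment)
  expect_error(haplogroupEnrichment(character(0), "J", 0.1), "empty")
  expect_error(haplogroupEnrichment("J", "J", 0), "frequency")
})
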