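test_that("simulated duplication trees carry the named ancestral nodes", {
  sc <- simulationScenario(nTaxa = 4, branchScale = 0.2, seed = 5)
  tr <- simulateTree(sc)
  expect_equal(ape::Ntip(tr), 8L)
  expect_true(all(c("preLUCA", "LUCA_Ffh", "LUCA_FtsY") %in% tr$node.label))
  expect_equal(tr$node.label[1L], "preLUCA")  # root label
  expect_true(all(tr$edge.length > 0))
  expect_true(all(grepl("^(Ffh|FtsY)_(Bacteria|Archaea)_", tr$tip.label)))
  # leaf names parse under the header convention
  expect_silent(parseLabel(tr$tip.label))

  # determinism: identical scenario, identical Newick
  expect_identical(ape::write.tree(simulateTree(sc)),
                   ape::write.tree(simulateTree(sc)))

  # birth-death shape also yields the duplication scaffold
  scbd <- simulationScenario(nTaxa = 4, treeShape = "birth_death",
                             branchScale = 0.2, seed = 6)
  trbd <- simulateTree(scbd)
  expect_equal(ape::Ntip(trbd), 8L)
  expect_true("preLUCA" %in% trbd$node.label)
})

test_that("alignment simulation respects the tree and the seed", {
  m <- WAGM
  # zero branch lengths: every leaf equals the root sequence
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  sim0 <- simulateAlignment(tr0, m, 30, seed = 2)
  for (s in alignmentStrings(sim0$alignment))
    expect_equal(unname(s), sim0$rootSequence)

  # determinism
  tr <- ape::read.tree(text = "((a:0.2,b:0.1):0.1,c:0.3);")
  s1 <- simulateAlignment(tr, m, 50, seed = 9)
  s2 <- simulateAlignment(tr, m, 50, seed = 9)
  expect_identical(alignmentStrings(s1$alignment),
                   alignmentStrings(s2$alignment))
  expect_identical(s1$rootSequence, s2$rootSequence)
})

test_that("long-branch leaf composition converges to the equilibrium", {
  m <- WAGM
  tr <- ape::read.tree(text = "(a:50);")
  sim <- simulateAlignment(tr, m, 10000, seed = 13)
  chars <- strsplit(alignmentStrings(sim$alignment)[[1]], "")[[1]]
  counts <- table(factor(chars, levels = modelAlphabet(m)))
  for (aa in modelAlphabet(m)) {
    p <- eqFreqs(m)[[aa]]
    sd3 <- 3 * sqrt(10000 * p * (1 - p))
    expect_lt(abs(counts[[aa]] - 10000 * p), sd3 + 1e-9)
  }
})

test_that("gap overlay copies exactly the template's gap coordinates", {
  simA <- proteinAlignment(c(a = "ACDE", b = "FGHI"))
  tmplFree <- proteinAlignment(c(a = "WWWW", b = "WWWW"))
  expect_identical(alignmentMatrix(overlayGaps(simA, tmplFree)),
                   alignmentMatrix(simA))

  tmplAll <- proteinAlignment(c(a = "----", b = "----"))
  expect_true(all(alignmentMatrix(overlayGaps(simA, tmplAll)) == "-"))

  tmpl <- proteinAlignment(c(b = "-W-W", a = "W--W"))  # row order differs
  out <- overlayGaps(simA, tmpl)
  expect_identical(alignmentMatrix(out) == "-",
                   alignmentMatrix(tmpl)[c("a", "b"), ] == "-")
  # non-gap cells keep the simulated residues
  expect_equal(alignmentMatrix(out)["a", c(1, 4)], c("A", "E"),
               ignore_attr = TRUE)

  expect_error(overlayGaps(simA, proteinAlignment(c(a = "--", b = "--"))),
               class = "alignmentError")
})

test_that("the simulation null is seeded, reproducible and sanity-bounded", {
  m <- WAGM
  sc <- simulationScenario(nTaxa = 4, branchScale = 0.1, length = 120, seed = 3)
  tree <- simulateTree(sc)
  expect_error(nullReconstructionDistribution(tree, model = m, nSims = 0,
                                              length = 120),
               class = "validationError")
  nd1 <- nullReconstructionDistribution(tree, model = m, nSims = 25,
                                        aminoAcids = c("W", "C"),
                                        gapThreshold = 10, seed = 17,
                                        length = 120)
  nd2 <- nullReconstructionDistribution(tree, model = m, nSims = 25,
                                        aminoAcids = c("W", "C"),
                                        gapThreshold = 10, seed = 17,
                                        length = 120)
  expect_identical(nullCounts(nd1), nullCounts(nd2))
  expect_equal(nd1@nSims, 25L)
  expect_true(all(nullCounts(nd1) >= 0))
  # counts stay in the plausible neighbourhood of the equilibrium expectation
  expect_lt(abs(mean(nullCounts(nd1, "W")) - 120 * eqFreqs(m)[["W"]]), 3)
})

test_that("a gap template flows through the null pipeline", {
  m <- WAGM
  sc <- simulationScenario(nTaxa = 4, branchScale = 0.1, length = 60, seed = 4)
  tree <- simulateTree(sc)
  tmplMat <- matrix(sample(c("A", "-"), 8 * 60, replace = TRUE, prob = c(0.7, 0.3)),
                    nrow = 8, dimnames = list(tree$tip.label, NULL))
  tmplMat[, 1] <- "A"   # keep at least some fully present columns
  tmpl <- new("ProteinAlignment", seqs = tmplMat)
  nd <- nullReconstructionDistribution(tree, templateAlignment = tmpl,
                                       model = m, nSims = 20,
                                       aminoAcids = "W", gapThreshold = 10,
                                       seed = 23)
  expect_equal(nrow(nullCounts(nd)), 20L)
  # gapped templates shorten reconstructions, so counts cannot exceed 60
  expect_true(all(nullCounts(nd, "W") <= 60))
})

test_that("a depleted root composition is recovered as a depletion signal", {
  m <- WAGM
  late <- c("C", "H", "F", "M", "Y", "W")
  pi <- eqFreqs(m)
  depleted <- pi
  depleted[late] <- depleted[late] / 10
  depleted <- depleted / sum(depleted)
  sc <- simulationScenario(nTaxa = 8, branchScale = 0.3, length = 200, seed = 41)
  tree <- simulateTree(sc)
  obsSim <- simulateAlignment(tree, m, 200, rootFreqs = depleted, seed = 42)
  prof <- reconstructionProfile(tree, obsSim$alignment, m)
  obs <- sum(vapply(late, function(a)
    countResidues(ancSequence(callSequence(prof, 10)), a), integer(1)))
  nd <- nullReconstructionDistribution(tree, model = m, nSims = 20,
                                       aminoAcids = late, gapThreshold = 10,
                                       seed = 43, length = 200)
  dt <- depletionTest(obs, rowSums(nullCounts(nd)))
  expect_lte(dt$p, 0.05)
  expect_lt(obs, dt$nullMean)
})
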