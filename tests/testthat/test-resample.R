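test_that("cluster files parse in the documented dialect", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Cluster 1:",
               "Ffh_Bacteria_Aquificae_A1",
               ">Ffh_Archaea_TACK_B2",
               "",
               "Cluster 2:",
               "FtsY_Bacteria_Proteobacteria_C3"), f)
  cs <- parseClusterFile(f)
  expect_s4_class(cs, "ClusterSet")
  expect_equal(nClusters(cs), 2L)
  expect_equal(clusterMembers(cs)[[1L]],
               c("Ffh_Bacteria_Aquificae_A1", "Ffh_Archaea_TACK_B2"))
  expect_equal(cs@provenance, "file")

  fEmpty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), fEmpty)
  expect_error(parseClusterFile(fEmpty), class = "formatError")

  fStray <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("junk", "Cluster 1:", "m1"), fStray)
  expect_equal(nClusters(parseClusterFile(fStray)), 1L)     # tolerant
  expect_error(parseClusterFile(fStray, strict = TRUE),
               class = "formatError")
})

test_that("cluster members must exist in the paired alignment", {
  cs <- new("ClusterSet", clusters = list(c("a", "b"), "zz"),
            provenance = "file")
  aln <- proteinAlignment(c(a = "AC", b = "AG"))
  err <- tryCatch(checkClusterPairing(cs, aln), error = function(e) e)
  expect_s3_class(err, "pairingError")
  expect_match(conditionMessage(err), "zz")
})

test_that("greedy identity clustering honors the soft bound and identity floor", {
  # 10 identical sequences with soft bound 5 split into two clusters of 5
  aln <- proteinAlignment(setNames(rep("ACDEFGHIKL", 10), paste0("s", 1:10)))
  cs <- clusterSequences(aln, softMax = 5, seed = 1)
  expect_equal(sort(lengths(clusterMembers(cs))), c(5L, 5L))
  expect_equal(cs@provenance, "computed")

  # mutually dissimilar sequences never join: all singletons
  seqs <- vapply(1:10, function(i)
    paste(rep(modelAlphabet(WAGM)[i], 20), collapse = ""), character(1))
  names(seqs) <- paste0("d", 1:10)
  cs2 <- clusterSequences(proteinAlignment(seqs), softMax = 5, seed = 1)
  expect_equal(nClusters(cs2), 10L)

  # determinism under a fixed seed
  cs3 <- clusterSequences(aln, softMax = 5, seed = 7)
  cs4 <- clusterSequences(aln, softMax = 5, seed = 7)
  expect_identical(clusterMembers(cs3), clusterMembers(cs4))
})

test_that("replicate subsets take exactly one member per cluster", {
  cs <- new("ClusterSet",
            clusters = list(c("a", "b"), c("c", "d", "e"), "f"),
            provenance = "file")
  reps <- makeReplicates(cs, n = 20, seed = 3)
  expect_length(reps, 20L)
  for (r in reps) {
    expect_length(r, 3L)
    expect_true(r[1] %in% c("a", "b"))
    expect_true(r[2] %in% c("c", "d", "e"))
    expect_equal(r[3], "f")
  }
  expect_identical(makeReplicates(cs, 5, seed = 3), reps[1:5])  # substreams

  # singleton clusters leave no choice
  singles <- new("ClusterSet", clusters = list("a", "b"), provenance = "file")
  repsS <- makeReplicates(singles, 4, seed = 1)
  expect_true(all(vapply(repsS, identical, logical(1), y = c("a", "b"))))
})

test_that("tree pruning compresses paths and keeps the leaf set", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  pr <- pruneTree(tr, c("a", "c"))
  expect_equal(sort(pr$tip.label), c("a", "c"))
  expect_equal(ape::write.tree(pr), "(a:2,c:2);")  # 1+1 summed on the path

  # identity when keeping everything
  expect_identical(pruneTree(tr, c("a", "b", "c")), tr)

  # leaf set of the pruned tree equals keep, on a larger random pruning
  sc <- simulationScenario(nTaxa = 8, branchScale = 0.1, seed = 2)
  big <- simulateTree(sc)
  keep <- sort(big$tip.label[c(1, 3, 6, 9, 12, 16)])
  expect_setequal(pruneTree(big, keep, nodesOfInterest = character(0))$tip.label,
                  keep)

  expect_error(pruneTree(tr, "a"), class = "validationError")
  expect_error(pruneTree(tr, c("a", "zz")), class = "pairingError")
})

test_that("pruning errors when a named node loses one whole side", {
  tr <- ape::read.tree(text = "((a:1,b:1)AB:1,((c:1,d:1):1,e:1)CDE:1)root;")
  err <- tryCatch(pruneTree(tr, c("a", "b", "c", "d")), error = function(e) e)
  # CDE keeps c and d but loses its e side
  expect_s3_class(err, "pruneError")
  expect_match(conditionMessage(err), "CDE")
  # fine when both sides of every named node survive (d drops under an
  # unnamed node only)
  expect_silent(pruneTree(tr, c("a", "b", "c", "e")))
})

test_that("simple-majority consensus applies the documented tie-breaks", {
  expect_equal(ancSequence(consensusSequence(c("A", "A", "G"))), "A")
  expect_equal(ancSequence(consensusSequence(c("A", "A", "G", "G"))), "A")  # tie: alphabetical
  expect_equal(ancSequence(consensusSequence(c("A", "-", "-"))), "-")
  expect_equal(ancSequence(consensusSequence(c("A-", "-A"))), "AA")  # '-' loses ties

  cons <- consensusSequence(c("AC-", "AC-", "GC-"))
  expect_equal(ancSequence(cons), "AC-")
  expect_equal(cons@winningFrequency, c(2 / 3, 1, 1))

  # consensus of identical sequences is that sequence
  s <- "ACD-WGH"
  expect_equal(ancSequence(consensusSequence(rep(s, 7))), s)

  expect_error(consensusSequence(c("AC", "A")), class = "alignmentError")
})

test_that("consensus agrees with seqinr's majority rule on tie-free columns", {
  skip_if_not_installed("seqinr")
  set.seed(12)
  # 5 sequences, 30 columns, constructed tie-free: one symbol always wins
  mat <- replicate(30, {
    win <- sample(c(modelAlphabet(WAGM), "-"), 1)
    col <- c(rep(win, 3), sample(setdiff(modelAlphabet(WAGM), win), 2))
    sample(col)
  })
  seqs <- apply(mat, 1, paste0, collapse = "")
  mine <- ancSequence(consensusSequence(seqs))
  theirs <- toupper(paste0(seqinr::consensus(mat, method = "majority"),
                           collapse = ""))
  expect_equal(mine, theirs)
})

test_that("replicated reconstruction reduces to a direct call when trivial", {
  m <- WAGM
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,(c:0.1,d:0.3):0.2);")
  aln <- proteinAlignment(c(a = "AWKD-", b = "AWRD-", c = "VWKEC", d = "AFKDC"))
  res <- replicatedASR(aln, tr, m, clusters = NULL, thresholds = c(50),
                       n = 1, seed = 1, indelRate = 1)
  direct <- callSequence(reconstructionProfile(tr, aln, m, indelRate = 1), 50)
  expect_equal(setSequences(res$sets[["50"]]), ancSequence(direct))
  expect_equal(ancSequence(res$consensus[["50"]]), ancSequence(direct))
})

test_that("replicate ensembles keep master columns and lengthen with the threshold", {
  m <- WAGM
  sc <- simulationScenario(nTaxa = 8, branchScale = 0.15, length = 80, seed = 31)
  tree <- simulateTree(sc)
  sim <- simulateAlignment(tree, m, 80, seed = 32)
  # synthetic shared gap block on a subset of taxa makes gap calls non-trivial
  mat <- alignmentMatrix(sim$alignment)
  mat[1:6, 1:20] <- "-"
  aln <- new("ProteinAlignment", seqs = mat)
  cl <- clusterSequences(aln, softMax = 4, seed = 31)
  res <- replicatedASR(aln, tree, m, cl, thresholds = c(10, 50, 90),
                       n = 6, seed = 31)
  for (tn in c("10", "50", "90"))
    expect_true(all(nchar(setSequences(res$sets[[tn]])) == 80L))
  len10 <- mean(ungappedLength(setSequences(res$sets[["10"]])))
  len90 <- mean(ungappedLength(setSequences(res$sets[["90"]])))
  expect_gte(len90, len10)

  # full-pipeline determinism: identical seeds give identical ensembles
  res2 <- replicatedASR(aln, tree, m, cl, thresholds = c(10, 50, 90),
                        n = 6, seed = 31)
  expect_identical(lapply(res$sets, setSequences),
                   lapply(res2$sets, setSequences))
})
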