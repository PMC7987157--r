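# The pruning engine is checked against full state enumeration (the
# brute-force oracle in helper-oracles.R), closed forms, and phangorn's
# independent likelihood implementation.

test_that("site likelihoods match closed forms on degenerate inputs", {
  m <- WAGM
  # single leaf: log L = log pi[state] for any branch length (stationarity)
  tr1 <- ape::read.tree(text = "(a:0.7);")
  aln1 <- proteinAlignment(c(a = "A"))
  expect_equal(siteLogLikelihood(tr1, aln1, m), log(eqFreqs(m)[["A"]]),
               tolerance = 1e-12)
  # all-gap column contributes likelihood 1
  tr2 <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,c:0.3);")
  aln2 <- proteinAlignment(c(a = "-A", b = "-A", c = "-V"))
  expect_equal(siteLogLikelihood(tr2, aln2, m)[1L], 0, tolerance = 1e-12)
})

test_that("site likelihoods match brute-force enumeration with gaps and X", {
  m <- WAGM
  tr <- ape::read.tree(text = "((a:0.2,b:0.1):0.15,(c:0.3,d:0.05):0.2);")
  aln <- proteinAlignment(c(a = "AC-WXG", b = "AVD-PG",
                            c = "TC-W-G", d = "AADWPP"))
  got <- siteLogLikelihood(tr, aln, m)
  want <- bruteForceLogLik(tr, aln, m)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("site likelihoods agree with phangorn on simulated data", {
  skip_if_not_installed("phangorn")
  m <- WAGM
  tr <- ape::read.tree(text = "((a:0.2,b:0.1):0.15,(c:0.3,d:0.05):0.2);")
  sim <- simulateAlignment(tr, m, 60, seed = 5)
  mine <- sum(siteLogLikelihood(tr, sim$alignment, m))
  chars <- t(sapply(alignmentStrings(sim$alignment),
                    function(s) strsplit(s, "")[[1]]))
  fit <- phangorn::pml(tr, phangorn::phyDat(chars, type = "AA"), model = "WAG")
  expect_equal(mine, fit$logLik, tolerance = 1e-3)
})

test_that("marginal posteriors match enumeration and the zero-branch limit", {
  m <- WAGM
  # zero-branch limit: two identical leaves pin the root state
  tr0 <- ape::read.tree(text = "(a:1e-8,b:1e-8);")
  post0 <- marginalPosteriors(tr0, proteinAlignment(c(a = "A", b = "A")), m)
  expect_gt(post0["A", 1], 0.999)

  # 3-leaf star: posterior proportional to pi_x P(x->A)^2 P(x->V)
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  aln <- proteinAlignment(c(a = "A", b = "A", c = "V"))
  suppressWarnings(post <- marginalPosteriors(tr, aln, m))
  P <- transitionMatrix(m, 0.1)
  want <- eqFreqs(m) * P[, "A"]^2 * P[, "V"]
  expect_equal(unname(post[, 1]), unname(want / sum(want)), tolerance = 1e-10)

  # 4-taxon brute force, including missing data
  tr4 <- ape::read.tree(text = "((a:0.2,b:0.1):0.15,(c:0.3,d:0.05):0.2);")
  aln4 <- proteinAlignment(c(a = "AW-", b = "VW-", c = "A-C", d = "AWC"))
  got <- marginalPosteriors(tr4, aln4, m)
  want4 <- bruteForceRootPosterior(tr4, aln4, m)
  expect_equal(unname(got), unname(want4), tolerance = 1e-10)

  expect_error(marginalPosteriors(tr4, aln4, m, nodeId = "a"),
               class = "domainError")
  expect_error(marginalPosteriors(tr4, aln4, m, nodeId = 2),
               class = "domainError")
})

test_that("posteriors at a node are invariant to re-rooting along a branch", {
  # pulley principle for reversible models: sliding the root along the
  # central branch leaves the marginal posterior at the (a,b) ancestor
  # unchanged
  m <- WAGM
  aln <- proteinAlignment(c(a = "AWKD", b = "AWRD", c = "VWKE", d = "AFKD"))
  t1 <- ape::read.tree(text = "((a:0.2,b:0.1)AB:0.05,(c:0.3,d:0.1)CD:0.25);")
  t2 <- ape::read.tree(text = "((a:0.2,b:0.1)AB:0.25,(c:0.3,d:0.1)CD:0.05);")
  p1 <- marginalPosteriors(t1, aln, m, nodeId = "AB")
  p2 <- marginalPosteriors(t2, aln, m, nodeId = "AB")
  expect_equal(p1, p2, tolerance = 1e-10)
  expect_equal(sum(siteLogLikelihood(t1, aln, m)),
               sum(siteLogLikelihood(t2, aln, m)), tolerance = 1e-10)
})

test_that("leaf/alignment mismatches are pairing errors listing offenders", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  err <- tryCatch(siteLogLikelihood(tr, proteinAlignment(c(a = "A", b = "A", z = "A")),
                                    WAGM),
                  error = function(e) e)
  expect_s3_class(err, "pairingError")
  expect_match(conditionMessage(err), "c")
  expect_match(conditionMessage(err), "z")
})

test_that("gap posteriors match 2-state enumeration and unanimity limits", {
  tr <- ape::read.tree(text = "(a:0.2,b:0.2,c:0.2);")
  # mixed column matches brute force at a fixed rate
  alnMix <- proteinAlignment(c(a = "AA-", b = "A-A", c = "--A"))
  suppressWarnings(gp <- gapPosteriors(tr, alnMix, indelRate = 0.8))
  want <- bruteForceRootPosterior(tr, alnMix, BINM, rate = 0.8)
  expect_equal(gp, unname(want[2L, ]), tolerance = 1e-10)

  # unanimity on short branches
  trS <- ape::read.tree(text = "(a:0.01,b:0.01,c:0.01);")
  suppressWarnings(gpAbsent <- gapPosteriors(
    trS, proteinAlignment(c(a = "-A", b = "-A", c = "-A")), indelRate = 1))
  expect_gt(gpAbsent[1L], 0.99)
  expect_lt(gpAbsent[2L], 0.01)
})

test_that("the indel-rate estimate maximizes the binary likelihood", {
  tr <- ape::read.tree(text = "((a:0.3,b:0.2):0.2,(c:0.4,d:0.1):0.3);")
  aln <- randomAlignment(c("a", "b", "c", "d"), 60, gapProb = 0.3, seed = 8)
  est <- estimateIndelRate(tr, aln)
  expect_true(est$rate >= exp(-5) && est$rate <= exp(2))
  # no grid point beats the optimum beyond the search tolerance
  enc <- ifelse(alignmentMatrix(aln) == "-", 2L, 1L)
  dim(enc) <- dim(alignmentMatrix(aln))
  rownames(enc) <- rownames(alignmentMatrix(aln))
  grid <- exp(seq(-5, 2, length.out = 40))
  gridLL <- vapply(grid, function(r) {
    s <- srpAncestry:::.pruningPass(tr, enc, BINM, rate = r)$colLogLik
    sum(s)
  }, numeric(1))
  expect_gte(est$logLik + 1e-6, max(gridLL))
})

test_that("sequence calling follows the gap-threshold rule with alphabetical ties", {
  rp <- matrix(0, 20, 3, dimnames = list(modelAlphabet(WAGM), NULL))
  rp["A", 1] <- rp["G", 1] <- 0.5           # tie: alphabetical winner A
  rp["W", 2] <- 1
  rp["V", 3] <- 1
  prof <- new("ReconstructionProfile", nodeId = "root",
              residuePosterior = rp, gapPosterior = c(0.5, 0.95, 0.90))
  expect_equal(ancSequence(callSequence(prof, 90)), "A--")
  expect_equal(ancSequence(callSequence(prof, 91)), "A-V")  # 0.95 still >= 0.91
  expect_equal(ancSequence(callSequence(prof, 96)), "AWV")
  expect_error(callSequence(prof, 0), class = "validationError")

  # monotone: raising the threshold never decreases the ungapped length
  set.seed(9)
  gp <- runif(30)
  rpr <- matrix(stats::rexp(20 * 30), 20, 30,
                dimnames = list(modelAlphabet(WAGM), NULL))
  rpr <- sweep(rpr, 2, colSums(rpr), "/")
  prof2 <- new("ReconstructionProfile", nodeId = "root",
               residuePosterior = rpr, gapPosterior = gp)
  lens <- vapply(c(10, 30, 50, 70, 90),
                 function(th) ungappedLength(ancSequence(callSequence(prof2, th))),
                 integer(1))
  expect_true(all(diff(lens) >= 0))
})

test_that("threshold sweep counts the thresholds that call a residue", {
  rp <- matrix(1 / 20, 20, 3, dimnames = list(modelAlphabet(WAGM), NULL))
  prof <- new("ReconstructionProfile", nodeId = "root",
              residuePosterior = rp, gapPosterior = c(0, 1, 0.5))
  occ <- thresholdSweep(prof)
  expect_equal(occ[1L], 1)
  expect_equal(occ[2L], 0)
  expect_equal(occ[3L], sum((1:99) > 50) / 99)  # direct enumeration
})

test_that("called root sequences recover simulated roots at least as well as leaf majority", {
  m <- WAGM
  sc <- simulationScenario(nTaxa = 16, branchScale = 0.05, length = 500, seed = 21)
  tree <- simulateTree(sc)  # 32 leaves
  accASR <- accBase <- numeric(0)
  for (rep in 1:5) {
    sim <- simulateAlignment(tree, m, 500, seed = 100 + rep)
    prof <- reconstructionProfile(tree, sim$alignment, m, indelRate = 1)
    called <- strsplit(ancSequence(callSequence(prof, 50)), "")[[1]]
    truth <- strsplit(sim$rootSequence, "")[[1]]
    accASR <- c(accASR, mean(called == truth))
    mat <- alignmentMatrix(sim$alignment)
    maj <- apply(mat, 2, function(col) names(sort(table(col), decreasing = TRUE))[1])
    accBase <- c(accBase, mean(maj == truth))
  }
  expect_gte(mean(accASR), mean(accBase))
  expect_gt(mean(accASR), 0.5)
})
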