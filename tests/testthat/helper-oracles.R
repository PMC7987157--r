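# Independent brute-force oracles for small trees: likelihoods and marginal
# posteriors by full enumeration over all internal-node state assignments.
# These never share code with the pruning engine they check.

WAGM <- wagModel()
BINM <- indelModel()

# Full-enumeration column likelihood and root posterior.
# tipStates: named integer vector (state index, NA = missing data).
# rate multiplies all branch lengths.
bruteForceColumn <- function(tree, tipStates, model, rate = 1) {
  k <- length(modelAlphabet(model))
  pi <- eqFreqs(model)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edges <- tree$edge
  elen <- tree$edge.length
  Plist <- lapply(seq_len(nrow(edges)),
                  function(e) transitionMatrix(model, elen[e], rate))
  intNodes <- ntip + seq_len(nint)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nint)))
  lik <- 0
  rootLik <- numeric(k)
  for (ci in seq_len(nrow(combos))) {
    assign_int <- combos[ci, ]
    stateOf <- function(node) {
      if (node <= ntip) tipStates[tree$tip.label[node]]
      else assign_int[node - ntip]
    }
    pr <- pi[assign_int[1L]]   # root = ntip + 1 is the first internal node
    for (e in seq_len(nrow(edges))) {
      sp <- stateOf(edges[e, 1L])
      sc <- stateOf(edges[e, 2L])
      if (is.na(sc)) next      # missing tip: sums to 1
      pr <- pr * Plist[[e]][sp, sc]
    }
    lik <- lik + pr
    rootLik[assign_int[1L]] <- rootLik[assign_int[1L]] + pr
  }
  list(logLik = log(lik), rootPosterior = rootLik / lik)
}

# Encode a character column into state indices for a model alphabet
# (residue model: '-'/'X' -> NA; binary model: gap -> state 2).
encodeColumn <- function(chars, model) {
  alpha <- modelAlphabet(model)
  if (length(alpha) == 2L) {
    ifelse(chars == "-", 2L, 1L)
  } else {
    match(chars, alpha)
  }
}

# Brute-force check of all three engine outputs on one small alignment.
bruteForceLogLik <- function(tree, alignment, model) {
  m <- alignmentMatrix(alignment)
  vapply(seq_len(ncol(m)), function(j) {
    st <- encodeColumn(m[, j], model)
    names(st) <- rownames(m)
    bruteForceColumn(tree, st, model)$logLik
  }, numeric(1))
}

bruteForceRootPosterior <- function(tree, alignment, model, rate = 1) {
  m <- alignmentMatrix(alignment)
  sapply(seq_len(ncol(m)), function(j) {
    st <- encodeColumn(m[, j], model)
    names(st) <- rownames(m)
    bruteForceColumn(tree, st, model, rate)$rootPosterior
  })
}

# Random gapped test alignments over a fixed tip set.
randomAlignment <- function(tips, nCols, gapProb = 0.2, xProb = 0.05, seed = 1) {
  set.seed(seed)
  syms <- c(modelAlphabet(WAGM), "-", "X")
  probs <- c(rep((1 - gapProb - xProb) / 20, 20), gapProb, xProb)
  m <- matrix(sample(syms, length(tips) * nCols, replace = TRUE, prob = probs),
              nrow = length(tips), dimnames = list(tips, NULL))
  new("ProteinAlignment", seqs = m)
}
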