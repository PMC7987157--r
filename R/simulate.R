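# Synthetic-data generation: duplication trees mirroring the Ffh/FtsY
# study design, sequences evolved under a reversible substitution model
# from a configurable root composition, gap overlay from an empirical
# template, and the simulation null distribution of ancestral residue
# counts.
#
# Indels are never simulated stochastically: gaps enter only through
# templates, matching the empirical-gap-placement design.

#' Simulation scenario
#'
#' Bundles the knobs of the synthetic-data generator. The default scenario
#' mirrors the study system at desk scale: a rooted tree with a basal
#' duplication joining two paralog subtrees (leaf prefixes \code{Ffh_} /
#' \code{FtsY_}), each containing a bacterial and an archaeal clade, with
#' named internal nodes \code{preLUCA} (root), \code{LUCA_Ffh} and
#' \code{LUCA_FtsY}.
#'
#' @param nTaxa number of leaves per paralog clade (>= 2; split evenly
#'   between the two domain clades).
#' @param treeShape \code{"balanced"} (default), \code{"birth_death"}, or
#'   \code{"supplied"} (then give \code{suppliedTree}).
#' @param branchScale branch length scale in substitutions/site; for a
#'   balanced tree every branch has this length, for birth-death trees edge
#'   lengths are rescaled to this mean.
#' @param duplicationAtRoot logical; FALSE gives a single clade without the
#'   paralog duplication.
#' @param length number of alignment columns to simulate.
#' @param rootFreqs 20 root-state probabilities in WAG residue order
#'   (default: the model's equilibrium frequencies).
#' @param gapTemplate optional [ProteinAlignment-class] whose gaps are
#'   overlaid on the simulated sequences.
#' @param suppliedTree an [ape::phylo] when \code{treeShape = "supplied"}.
#' @param seed integer seed.
#' @return a list of class \code{"SimulationScenario"}.
#' @export
simulationScenario <- function(nTaxa = 16L, treeShape = c("balanced", "birth_death", "supplied"),
                               branchScale = 0.1, duplicationAtRoot = TRUE,
                               length = 400L, rootFreqs = NULL,
                               gapTemplate = NULL, suppliedTree = NULL,
                               seed = 1L) {
  treeShape <- match.arg(treeShape)
  if (nTaxa < 2L) .err("validationError", "nTaxa must be >= 2 per clade")
  if (length < 1L) .err("validationError", "length must be >= 1")
  if (!is.null(rootFreqs)) {
    if (length(rootFreqs) != 20L || abs(sum(rootFreqs) - 1) > 1e-12)
      .err("validationError", "rootFreqs must be 20 probabilities summing to 1")
  }
  structure(list(nTaxa = as.integer(nTaxa), treeShape = treeShape,
                 branchScale = branchScale,
                 duplicationAtRoot = isTRUE(duplicationAtRoot),
                 length = as.integer(length), rootFreqs = rootFreqs,
                 gapTemplate = gapTemplate, suppliedTree = suppliedTree,
                 seed = as.integer(seed)),
            class = "SimulationScenario")
}

# Balanced binary subtree over given leaf names, all branches = scale.
.balancedNewick <- function(leaves, scale) {
  if (length(leaves) == 1L) return(sprintf("%s:%g", leaves, scale))
  half <- ceiling(length(leaves) / 2)
  sprintf("(%s,%s):%g",
          .balancedNewick(leaves[seq_len(half)], scale),
          .balancedNewick(leaves[-seq_len(half)], scale), scale)
}

#' Simulate a rooted study tree
#'
#' @param scenario a [simulationScenario()].
#' @return an [ape::phylo]; with \code{duplicationAtRoot} the root is named
#'   \code{preLUCA} and the two paralog ancestors \code{LUCA_Ffh} /
#'   \code{LUCA_FtsY}; every branch length is positive.
#' @export
simulateTree <- function(scenario) {
  stopifnot(inherits(scenario, "SimulationScenario"))
  set.seed(scenario$seed)
  scale <- scenario$branchScale
  if (scenario$treeShape == "supplied") {
    if (is.null(scenario$suppliedTree))
      .err("validationError", "treeShape 'supplied' requires suppliedTree")
    return(validateTree(scenario$suppliedTree))
  }
  if (scenario$treeShape == "birth_death") {
    mkClade <- function(gene) {
      n <- scenario$nTaxa
      nB <- ceiling(n / 2)
      tr <- ape::rphylo(n, birth = 1, death = 0)
      tr$edge.length <- tr$edge.length * scale / mean(tr$edge.length)
      tr$tip.label <- sprintf("%s_%s_SimPhylum_s%03d", gene,
                              rep(c("Bacteria", "Archaea"), c(nB, n - nB)),
                              seq_len(n))
      tr
    }
    sub1 <- mkClade("Ffh")
    nwk1 <- sub("\\);$", sprintf(")LUCA_Ffh:%g", scale), ape::write.tree(sub1))
    if (!scenario$duplicationAtRoot) {
      txt <- sub(sprintf("LUCA_Ffh:%g$", scale), "preLUCA;", nwk1)
      return(validateTree(ape::read.tree(text = txt)))
    }
    sub2 <- mkClade("FtsY")
    nwk2 <- sub("\\);$", sprintf(")LUCA_FtsY:%g", scale), ape::write.tree(sub2))
    txt <- sprintf("(%s,%s)preLUCA;", nwk1, nwk2)
    return(validateTree(ape::read.tree(text = txt)))
  }
  # balanced
  mkClade <- function(gene) {
    n <- scenario$nTaxa
    nB <- ceiling(n / 2)
    leavesB <- sprintf("%s_Bacteria_SimPhylum_s%03d", gene, seq_len(nB))
    leavesA <- if (n - nB > 0L)
      sprintf("%s_Archaea_SimPhylum_s%03d", gene, nB + seq_len(n - nB))
    else character(0)
    if (length(leavesA) == 0L) .balancedNewick(leavesB, scale)
    else sprintf("(%s,%s)", .balancedNewick(leavesB, scale),
                 .balancedNewick(leavesA, scale))
  }
  if (scenario$duplicationAtRoot) {
    txt <- sprintf("(%sLUCA_Ffh:%g,%sLUCA_FtsY:%g)preLUCA;",
                   mkClade("Ffh"), scale, mkClade("FtsY"), scale)
  } else {
    txt <- sprintf("%spreLUCA;", mkClade("Ffh"))
  }
  validateTree(ape::read.tree(text = txt))
}

#' Simulate a gap-free alignment along a tree
#'
#' The root sequence is drawn i.i.d. from \code{rootFreqs}; each branch
#' evolves the parent sequence through the model's transition matrix for
#' its length. Returns the tip alignment together with the true root
#' sequence for recovery tests.
#'
#' @param tree rooted [ape::phylo].
#' @param model a [RateModel-class].
#' @param length number of columns.
#' @param rootFreqs root-state probabilities (default: model equilibrium).
#' @param seed integer seed; the same seed reproduces the alignment
#'   bit-identically.
#' @return list with \code{alignment} ([ProteinAlignment-class]) and
#'   \code{rootSequence} (character string).
#' @export
simulateAlignment <- function(tree, model, length, rootFreqs = NULL, seed = 1L) {
  validateTree(tree)
  if (length < 1L) .err("validationError", "length must be >= 1")
  k <- base::length(model@alphabet)
  if (is.null(rootFreqs)) rootFreqs <- model@eqFreqs
  if (base::length(rootFreqs) != k || abs(sum(rootFreqs) - 1) > 1e-9)
    .err("validationError", sprintf("rootFreqs must be %d probabilities summing to 1", k))
  set.seed(seed)
  ntip <- base::length(tree$tip.label)
  N <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix(NA_integer_, N, length)
  states[root, ] <- sample.int(k, length, replace = TRUE, prob = rootFreqs)
  tre <- stats::reorder(tree, "postorder")
  edges <- tre$edge[rev(seq_len(nrow(tre$edge))), , drop = FALSE]  # preorder
  elen <- rev(tre$edge.length)
  for (e in seq_len(nrow(edges))) {
    pa <- edges[e, 1L]
    ch <- edges[e, 2L]
    P <- transitionMatrix(model, elen[e])
    parent <- states[pa, ]
    child <- integer(length)
    for (s in unique(parent)) {
      idx <- which(parent == s)
      child[idx] <- sample.int(k, base::length(idx), replace = TRUE, prob = P[s, ])
    }
    states[ch, ] <- child
  }
  tipSeqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                   function(s) paste0(model@alphabet[s], collapse = ""))
  names(tipSeqs) <- tree$tip.label
  list(alignment = proteinAlignment(tipSeqs),
       rootSequence = paste0(model@alphabet[states[root, ]], collapse = ""))
}

#' Overlay template gaps onto a simulated alignment
#'
#' \code{output[i, j]} is \code{"-"} wherever the template has a gap and
#' the simulated character otherwise; the empirical data thus determine
#' the indel structure while the simulation determines the residues.
#'
#' @param simulated,template [ProteinAlignment-class] objects over the same
#'   taxon set and column count (rows matched by name).
#' @return a [ProteinAlignment-class].
#' @export
overlayGaps <- function(simulated, template) {
  sm <- alignmentMatrix(simulated)
  tm <- alignmentMatrix(template)
  if (!setequal(rownames(sm), rownames(tm)) || ncol(sm) != ncol(tm))
    .err("alignmentError", "simulated and template must share taxa and columns")
  tm <- tm[rownames(sm), , drop = FALSE]
  sm[tm == GAP_CHAR] <- GAP_CHAR
  new("ProteinAlignment", seqs = sm)
}

#' Null distribution of ancestral residue counts under model simulation
#'
#' For each simulation: evolve a fresh alignment from the model equilibrium
#' along the tree, overlay the template's gaps, draw one reduced dataset
#' (one random member per cluster -- one reduced alignment per simulated
#' dataset), prune the tree, reconstruct the ancestral sequence at the node
#' at the given gap threshold, and count the requested residues. The
#' collected counts form the simulation null against which observed
#' ancestral counts are tested.
#'
#' Per-simulation randomness uses the seed substream \code{seed + i}, so
#' results are independent of execution order.
#'
#' @inheritParams replicatedASR
#' @param templateAlignment [ProteinAlignment-class] providing the gap
#'   structure (NULL for gap-free simulation); its column count sets the
#'   simulated length.
#' @param aminoAcids residues to count (default: the late-code set
#'   C, H, F, M, Y, W).
#' @param nSims number of simulations (>= 1).
#' @param gapThreshold percent threshold for calling gaps (default 10, the
#'   threshold used for the simulation arm).
#' @param length simulated length when no template is given.
#' @return a [NullDistribution-class].
#' @export
nullReconstructionDistribution <- function(tree, templateAlignment = NULL,
                                           model, clusters = NULL,
                                           nodeId = "root",
                                           aminoAcids = LATE_RESIDUES,
                                           nSims = 100L, gapThreshold = 10,
                                           seed = 1L, indelRate = NULL,
                                           length = NULL) {
  validateTree(tree)
  if (nSims < 1L)
    .err("validationError", "nSims must be >= 1 (empty null distribution)")
  if (!is.null(templateAlignment)) {
    checkPairing(tree, templateAlignment)
    length <- nColumns(templateAlignment)
  } else if (is.null(length)) {
    .err("validationError", "either templateAlignment or length must be given")
  }
  if (is.null(clusters))
    clusters <- new("ClusterSet", clusters = as.list(tree$tip.label),
                    provenance = "computed")
  anchors <- if (identical(nodeId, "root")) character(0) else as.character(nodeId)
  counts <- matrix(0L, nSims, base::length(aminoAcids),
                   dimnames = list(NULL, aminoAcids))
  for (i in seq_len(nSims)) {
    sim <- simulateAlignment(tree, model, length, seed = seed + i)
    aln <- if (is.null(templateAlignment)) sim$alignment
           else overlayGaps(sim$alignment, templateAlignment)
    set.seed(seed + i)
    keep <- vapply(clusterMembers(clusters),
                   function(x) x[sample.int(base::length(x), 1L)], character(1))
    if (base::length(keep) < 2L)
      .err("validationError", "clusters must yield at least 2 members")
    ptree <- pruneTree(tree, keep, nodesOfInterest = anchors)
    prof <- reconstructionProfile(ptree, aln[keep], model, nodeId = nodeId,
                                  indelRate = indelRate)
    anc <- ancSequence(callSequence(prof, gapThreshold))
    counts[i, ] <- vapply(aminoAcids, function(a) countResidues(anc, a),
                          integer(1))
  }
  new("NullDistribution", nodeId = as.character(nodeId), counts = counts,
      nSims = as.integer(nSims))
}
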