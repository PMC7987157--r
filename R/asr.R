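# Marginal ancestral sequence reconstruction: Felsenstein pruning over all
# alignment columns at once, an up-down (outside) pass for marginal
# posteriors at internal nodes, and the binary presence/absence model for
# maximum-likelihood gap inference.
#
# Gap semantics: in the residue likelihood, '-' and 'X' are missing data
# (partial likelihood 1 for every state); the gap/residue decision at an
# ancestral node is made solely by the separate binary-character
# reconstruction, mirroring the two-part inference design.

# ---- encoding -------------------------------------------------------------

.encodeResidues <- function(alnMatrix) {
  idx <- match(alnMatrix, AA_ORDER)        # NA for '-' and 'X': missing data
  dim(idx) <- dim(alnMatrix)
  rownames(idx) <- rownames(alnMatrix)
  idx
}

.encodePresence <- function(alnMatrix) {
  idx <- ifelse(alnMatrix == GAP_CHAR, 2L, 1L)  # state 1 = present, 2 = absent
  dim(idx) <- dim(alnMatrix)
  rownames(idx) <- rownames(alnMatrix)
  idx
}

# ---- pruning engine -------------------------------------------------------

# One post-order (and optionally pre-order) pass over all columns.
# enc: n_tips x C integer state matrix (NA = missing), rownames = tip labels.
# Returns per-node scaled partial likelihoods with per-column log scale
# factors; column scaling uses column sums (any positive scale is valid).
.pruningPass <- function(tree, enc, model, rate = 1, down = FALSE) {
  k <- length(model@alphabet)
  C <- ncol(enc)
  ntip <- length(tree$tip.label)
  N <- ntip + tree$Nnode
  tipIdx <- match(tree$tip.label, rownames(enc))
  if (anyNA(tipIdx))
    .err("pairingError",
         paste0("tips missing from alignment: ",
                paste(tree$tip.label[is.na(tipIdx)], collapse = ", ")))

  up <- vector("list", N)
  upLog <- vector("list", N)
  for (i in seq_len(ntip)) {
    states <- enc[tipIdx[i], ]
    M <- matrix(0, k, C)
    obs <- which(!is.na(states))
    M[cbind(states[obs], obs)] <- 1
    M[, is.na(states)] <- 1                 # missing data: all states equal
    up[[i]] <- M
    upLog[[i]] <- numeric(C)
  }

  tre <- stats::reorder(tree, "postorder")
  edges <- tre$edge
  elen <- tre$edge.length
  Pmats <- vector("list", N)
  contrib <- vector("list", N)
  contribLog <- vector("list", N)

  for (e in seq_len(nrow(edges))) {
    ch <- edges[e, 2L]
    pa <- edges[e, 1L]
    P <- transitionMatrix(model, elen[e], rate)
    Pmats[[ch]] <- P
    cb <- P %*% up[[ch]]
    contrib[[ch]] <- cb
    contribLog[[ch]] <- upLog[[ch]]
    if (is.null(up[[pa]])) {
      up[[pa]] <- cb
      upLog[[pa]] <- contribLog[[ch]]
    } else {
      up[[pa]] <- up[[pa]] * cb
      upLog[[pa]] <- upLog[[pa]] + contribLog[[ch]]
      cs <- .colSums(up[[pa]], k, C)
      if (any(cs == 0))
        .err("domainError", "zero likelihood column encountered")
      up[[pa]] <- up[[pa]] / rep(cs, each = k)
      upLog[[pa]] <- upLog[[pa]] + log(cs)
    }
  }

  root <- ntip + 1L
  rootLik <- .colSums(model@eqFreqs * up[[root]], k, C)
  colLogLik <- log(rootLik) + upLog[[root]]

  res <- list(up = up, upLog = upLog, colLogLik = colLogLik, root = root,
              ntip = ntip, k = k, C = C)
  if (!down) return(res)

  dn <- vector("list", N)
  dnLog <- vector("list", N)
  dn[[root]] <- matrix(model@eqFreqs, k, C)
  dnLog[[root]] <- numeric(C)
  children <- split(edges[, 2L], edges[, 1L])
  for (e in rev(seq_len(nrow(edges)))) {   # preorder: parents before children
    ch <- edges[e, 2L]
    pa <- edges[e, 1L]
    part <- dn[[pa]]
    plog <- dnLog[[pa]]
    for (s in children[[as.character(pa)]]) {
      if (s == ch) next
      part <- part * contrib[[s]]
      plog <- plog + contribLog[[s]]
    }
    D <- crossprod(Pmats[[ch]], part)     # t(P) %*% part
    cs <- .colSums(D, k, C)
    cs[cs == 0] <- 1
    dn[[ch]] <- D / rep(cs, each = k)
    dnLog[[ch]] <- plog + log(cs)
  }
  res$down <- dn
  res$downLog <- dnLog
  res
}

# Mixture over discrete-gamma categories: per-column log-likelihood and,
# when node is given, the category-weighted marginal posterior there.
.likelihoodAndPosterior <- function(tree, enc, model, node = NULL) {
  rates <- model@categoryRates
  m <- length(rates)
  perCat <- vector("list", m)
  for (ci in seq_len(m))
    perCat[[ci]] <- .pruningPass(tree, enc, model, rate = rates[ci],
                                 down = !is.null(node))
  llMat <- do.call(rbind, lapply(perCat, `[[`, "colLogLik"))  # m x C
  mx <- apply(llMat, 2L, max)
  colLogLik <- mx + log(.colMeans(exp(llMat - rep(mx, each = m)), m, ncol(llMat)))
  post <- NULL
  if (!is.null(node)) {
    k <- perCat[[1L]]$k
    C <- perCat[[1L]]$C
    w <- exp(llMat - rep(mx, each = m))   # proportional category weights
    w <- w / rep(colSums(w), each = m)
    post <- matrix(0, k, C)
    for (ci in seq_len(m)) {
      p <- perCat[[ci]]$up[[node]] * perCat[[ci]]$down[[node]]
      p <- p / rep(.colSums(p, k, C), each = k)
      post <- post + rep(w[ci, ], each = k) * p
    }
    rownames(post) <- model@alphabet
  }
  list(colLogLik = colLogLik, posterior = post)
}

# ---- node resolution ------------------------------------------------------

#' Resolve a node identifier to an internal node number
#'
#' @param tree an [ape::phylo].
#' @param nodeId \code{"root"}, an internal node label, or a node number.
#' @return integer node number (> number of tips).
#' @export
resolveNode <- function(tree, nodeId) {
  ntip <- length(tree$tip.label)
  if (is.numeric(nodeId)) {
    n <- as.integer(nodeId)
    if (n < 1L || n > ntip + tree$Nnode)
      .err("validationError", sprintf("node number %d out of range", n))
    if (n <= ntip)
      .err("domainError",
           sprintf("node %d is a leaf ('%s'); marginal reconstruction targets internal nodes",
                   n, tree$tip.label[n]))
    return(n)
  }
  if (identical(nodeId, "root")) return(ntip + 1L)
  if (nodeId %in% tree$tip.label)
    .err("domainError", sprintf("'%s' is a leaf; marginal reconstruction targets internal nodes",
                                nodeId))
  w <- which(tree$node.label == nodeId)
  if (length(w) != 1L)
    .err("validationError", sprintf("internal node '%s' not found (or not unique)", nodeId))
  ntip + w
}

# ---- exported operations --------------------------------------------------

#' Per-column log-likelihood under the substitution model
#'
#' Felsenstein pruning with the root weighted by the equilibrium
#' frequencies; gaps and \code{"X"} are missing data (partial likelihood 1
#' for every state), so an all-gap column has log-likelihood 0.
#'
#' @param tree rooted [ape::phylo] whose tips match the alignment headers.
#' @param alignment a [ProteinAlignment-class].
#' @param model a [RateModel-class] (typically [wagModel()]).
#' @return numeric vector of per-column log-likelihoods.
#' @export
siteLogLikelihood <- function(tree, alignment, model) {
  validateTree(tree)
  checkPairing(tree, alignment)
  enc <- .encodeResidues(alignmentMatrix(alignment))
  .likelihoodAndPosterior(tree, enc, model)$colLogLik
}

#' Marginal ancestral posteriors at an internal node
#'
#' Per-column posterior distribution over the 20 residues at \code{nodeId}
#' given all leaf data, computed by the up-down (outside) algorithm.
#'
#' @inheritParams siteLogLikelihood
#' @param nodeId \code{"root"}, an internal node label, or a node number;
#'   a leaf is a domain-error.
#' @return 20 x n_columns matrix of posteriors (columns sum to 1), rows in
#'   WAG residue order.
#' @export
marginalPosteriors <- function(tree, alignment, model, nodeId = "root") {
  validateTree(tree)
  checkPairing(tree, alignment)
  node <- resolveNode(tree, nodeId)
  enc <- .encodeResidues(alignmentMatrix(alignment))
  .likelihoodAndPosterior(tree, enc, model, node = node)$posterior
}

#' Estimate the indel rate by maximum likelihood
#'
#' Each column is recoded as binary presence/absence and the single rate of
#' the 2-state reversible equal-frequency model is maximized by
#' golden-section search on the natural-log rate in [-5, 2] (tolerance
#' 1e-4).
#'
#' @inheritParams siteLogLikelihood
#' @return list with \code{rate} and \code{logLik}.
#' @export
estimateIndelRate <- function(tree, alignment) {
  validateTree(tree)
  checkPairing(tree, alignment)
  enc <- .encodePresence(alignmentMatrix(alignment))
  bin <- indelModel()
  f <- function(logr)
    sum(.pruningPass(tree, enc, bin, rate = exp(logr))$colLogLik)
  opt <- stats::optimize(f, interval = c(-5, 2), maximum = TRUE, tol = 1e-4)
  list(rate = exp(opt$maximum), logLik = opt$objective)
}

#' Marginal gap (absence) posteriors at an internal node
#'
#' Columns are recoded as binary presence(1)/absence(0) and the marginal
#' posterior of the absent state at \code{nodeId} is computed under the
#' 2-state reversible model with equal stationary frequencies. Contiguous
#' indel events are scored per column independently (no block model).
#'
#' @inheritParams marginalPosteriors
#' @param indelRate positive rate of the binary process relative to branch
#'   lengths; when NULL it is estimated by [estimateIndelRate()].
#' @return numeric vector of per-column gap posteriors in [0, 1].
#' @export
gapPosteriors <- function(tree, alignment, indelRate = NULL, nodeId = "root") {
  validateTree(tree)
  checkPairing(tree, alignment)
  node <- resolveNode(tree, nodeId)
  if (is.null(indelRate)) indelRate <- estimateIndelRate(tree, alignment)$rate
  .assertScalarNumber(indelRate, "indelRate")
  if (indelRate <= 0) .err("domainError", "indelRate must be positive")
  enc <- .encodePresence(alignmentMatrix(alignment))
  bin <- indelModel()
  pass <- .pruningPass(tree, enc, bin, rate = indelRate, down = TRUE)
  p <- pass$up[[node]] * pass$down[[node]]
  p <- p / rep(.colSums(p, 2L, ncol(enc)), each = 2L)
  unname(p[2L, ])
}

#' Full reconstruction profile (residue + gap posteriors) at one node
#'
#' @inheritParams marginalPosteriors
#' @param indelRate as in [gapPosteriors()].
#' @return A [ReconstructionProfile-class].
#' @export
reconstructionProfile <- function(tree, alignment, model, nodeId = "root",
                                  indelRate = NULL) {
  rp <- marginalPosteriors(tree, alignment, model, nodeId)
  gp <- gapPosteriors(tree, alignment, indelRate, nodeId)
  new("ReconstructionProfile", nodeId = as.character(nodeId),
      residuePosterior = rp, gapPosterior = gp)
}

#' Call an ancestral sequence at a gap-inference threshold
#'
#' A column is called \code{"-"} iff its gap posterior is >= threshold/100
#' ("X% threshold for inferring gaps"); otherwise the maximum-posterior
#' residue, ties broken alphabetically by one-letter code. Raising the
#' threshold therefore never decreases the ungapped length.
#'
#' @param profile a [ReconstructionProfile-class].
#' @param gapThreshold percent in [1, 99].
#' @return An [AncestralSequence-class].
#' @export
callSequence <- function(profile, gapThreshold) {
  .assertScalarNumber(gapThreshold, "gapThreshold")
  if (gapThreshold < 1 || gapThreshold > 99)
    .err("validationError", "gapThreshold must lie in [1, 99]")
  rp <- profile@residuePosterior[AA_ALPHA, , drop = FALSE]
  win <- AA_ALPHA[max.col(t(rp), ties.method = "first")]
  gap <- profile@gapPosterior >= gapThreshold / 100
  win[gap] <- GAP_CHAR
  new("AncestralSequence", nodeId = profile@nodeId,
      gapThreshold = gapThreshold, sequence = paste0(win, collapse = ""))
}

#' Per-column occupancy across the 1-99% gap-threshold sweep
#'
#' For each column, the fraction of thresholds at which the called
#' character is a residue rather than a gap (the quantity plotted as an
#' occupancy histogram under threshold-annotated reconstructions).
#'
#' @param profile a [ReconstructionProfile-class].
#' @param thresholds integer percents, default 1:99.
#' @return numeric vector of per-column occupancy frequencies in [0, 1].
#' @export
thresholdSweep <- function(profile, thresholds = 1:99) {
  gp <- profile@gapPosterior
  sapply(gp, function(g) mean(g < thresholds / 100))
}
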