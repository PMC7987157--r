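# Cluster-based dataset reduction, replicate assembly, guide-tree pruning
# and simple-majority consensus across replicate reconstructions.
#
# Replicate alignments are row subsets of the master alignment (columns are
# never realigned), so replicate reconstructions stay column-comparable and
# a per-column consensus is well defined.

#' Parse a cluster-membership file
#'
#' Dialect: lines matching \code{"Cluster N:"} open a new cluster; every
#' following non-blank line is a member header (leading \code{">"} and
#' whitespace stripped). In strict mode any line before the first cluster
#' header, or an empty cluster, is an error; the default parser is tolerant
#' and skips stray preamble lines.
#'
#' @param path path to the cluster file.
#' @param strict logical; error on any unrecognized content.
#' @return A [ClusterSet-class] with provenance \code{"file"}.
#' @export
parseClusterFile <- function(path, strict = FALSE) {
  if (!file.exists(path))
    .err("formatError", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  clusters <- list()
  current <- NULL
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^Cluster\\s+\\S+:?\\s*$", ln, ignore.case = TRUE)) {
      if (!is.null(current)) clusters[[length(clusters) + 1L]] <- current
      current <- character(0)
    } else if (!is.null(current)) {
      current <- c(current, sub("^>\\s*", "", ln))
    } else if (strict) {
      .err("formatError", sprintf("unexpected line before first cluster: '%s'", ln))
    }
  }
  if (!is.null(current)) clusters[[length(clusters) + 1L]] <- current
  if (length(clusters) == 0L)
    .err("formatError", sprintf("no clusters found in %s", path))
  if (any(lengths(clusters) == 0L)) {
    if (strict) .err("formatError", "empty cluster in file")
    clusters <- clusters[lengths(clusters) > 0L]
    if (length(clusters) == 0L)
      .err("formatError", sprintf("no non-empty clusters in %s", path))
  }
  new("ClusterSet", clusters = clusters, provenance = "file")
}

#' Check cluster members against an alignment
#'
#' @param clusters a [ClusterSet-class].
#' @param alignment a [ProteinAlignment-class].
#' @return invisibly TRUE; a pairing-error lists members missing from the
#'   alignment.
#' @export
checkClusterPairing <- function(clusters, alignment) {
  members <- unlist(clusterMembers(clusters), use.names = FALSE)
  missing_m <- setdiff(members, sequenceNames(alignment))
  if (length(missing_m))
    .err("pairingError",
         paste0("cluster members not in alignment: ",
                paste(utils::head(missing_m, 10L), collapse = ", "),
                if (length(missing_m) > 10L) " ..."))
  invisible(TRUE)
}

# Percent-identity matrix over all unordered pairs. Denominator per pair:
# columns where at least one member is a residue (gap-gap columns excluded);
# numerator: equal non-gap characters.
.identityMatrix <- function(alnMatrix) {
  n <- nrow(alnMatrix)
  gap <- alnMatrix == GAP_CHAR
  idm <- matrix(100, n, n, dimnames = list(rownames(alnMatrix), rownames(alnMatrix)))
  if (n == 1L) return(idm)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      den <- sum(!(gap[i, ] & gap[j, ]))
      num <- sum(alnMatrix[i, ] == alnMatrix[j, ] & !gap[i, ])
      idm[i, j] <- idm[j, i] <- if (den == 0L) 0 else 100 * num / den
    }
  }
  idm
}

#' Greedy single-linkage identity clustering with soft size bounds
#'
#' Sequences are visited in a seed-randomized order. Each sequence joins
#' the cluster with the highest single-linkage percent identity (the best
#' identity to any current member), provided that identity reaches
#' \code{minIdentity}. If the nearest cluster is already at \code{softMax}
#' members, the sequence instead joins the best unfilled cluster whose
#' linkage identity is within 5 percentage points of the nearest one;
#' otherwise it starts a new cluster. The bound is soft: it only diverts
#' members when a near-equivalent cluster exists.
#'
#' @param alignment a [ProteinAlignment-class].
#' @param softMax soft upper bound on members per cluster (>= 1).
#' @param seed integer seed controlling the visiting order.
#' @param minIdentity minimum percent identity to join any cluster
#'   (default 30; below this a sequence founds a new cluster).
#' @return A [ClusterSet-class] with provenance \code{"computed"}.
#' @export
clusterSequences <- function(alignment, softMax, seed = 1L, minIdentity = 30) {
  if (softMax < 1L) .err("validationError", "softMax must be >= 1")
  m <- alignmentMatrix(alignment)
  n <- nrow(m)
  idm <- .identityMatrix(m)
  set.seed(seed)
  ord <- sample.int(n)
  clusters <- list()
  for (i in ord) {
    if (length(clusters) == 0L) {
      clusters <- list(i)
      next
    }
    link <- vapply(clusters, function(cl) max(idm[i, cl]), numeric(1))
    best <- which.max(link)
    if (link[best] < minIdentity) {
      clusters[[length(clusters) + 1L]] <- i
      next
    }
    if (length(clusters[[best]]) >= softMax) {
      open <- which(lengths(clusters) < softMax & link >= link[best] - 5 &
                      link >= minIdentity)
      if (length(open)) {
        best2 <- open[which.max(link[open])]
        clusters[[best2]] <- c(clusters[[best2]], i)
      } else {
        clusters[[length(clusters) + 1L]] <- i
      }
    } else {
      clusters[[best]] <- c(clusters[[best]], i)
    }
  }
  headers <- rownames(m)
  new("ClusterSet",
      clusters = lapply(clusters, function(cl) headers[sort(cl)]),
      provenance = "computed")
}

#' Assemble replicate subsets, one member per cluster
#'
#' Replicate r draws with the seed substream \code{seed + r}, so replicates
#' are independent of execution order and reproducible individually.
#'
#' @param clusters a [ClusterSet-class].
#' @param n number of replicates (the full design uses 100).
#' @param seed master integer seed.
#' @return list of \code{n} character vectors of headers, each containing
#'   exactly one member per cluster.
#' @export
makeReplicates <- function(clusters, n, seed = 1L) {
  if (n < 1L) .err("validationError", "n must be >= 1")
  cl <- clusterMembers(clusters)
  lapply(seq_len(n), function(r) {
    set.seed(seed + r)
    vapply(cl, function(x) x[sample.int(length(x), 1L)], character(1))
  })
}

#' Prune a guide tree to a replicate subset
#'
#' Leaves outside \code{keep} are removed and unary internal nodes are
#' suppressed with branch lengths summed (via [ape::keep.tip()]). Named
#' nodes of interest (non-numeric internal labels, e.g. \code{preLUCA})
#' must retain at least one descendant leaf on each side; otherwise a
#' prune-error identifies the node, since its reconstruction would no
#' longer be anchored.
#'
#' @param tree an [ape::phylo].
#' @param keep character vector of leaf names to retain (>= 2).
#' @param nodesOfInterest internal node labels whose anchoring must be
#'   checked; NULL (default) checks every non-numeric label,
#'   \code{character(0)} skips the check.
#' @return the pruned [ape::phylo].
#' @export
pruneTree <- function(tree, keep, nodesOfInterest = NULL) {
  miss <- setdiff(keep, tree$tip.label)
  if (length(miss))
    .err("pairingError", paste0("not tree leaves: ", paste(miss, collapse = ", ")))
  if (length(keep) < 2L)
    .err("validationError", "keep must contain at least 2 leaves")
  if (length(keep) == length(tree$tip.label)) return(tree)
  lab <- tree$node.label %||% character(0)
  named <- which(!is.na(lab) & nzchar(lab) &
                   is.na(suppressWarnings(as.numeric(lab))))
  if (!is.null(nodesOfInterest))
    named <- named[lab[named] %in% nodesOfInterest]
  if (length(named)) {
    ntip <- length(tree$tip.label)
    keepSet <- match(keep, tree$tip.label)
    children <- split(tree$edge[, 2L], tree$edge[, 1L])
    for (w in named) {
      node <- ntip + w
      kids <- children[[as.character(node)]]
      if (is.null(kids)) next
      # surviving leaves per child subtree; the node stays anchored only if
      # every side keeps at least one
      surv <- vapply(kids, function(kid) {
        if (kid <= ntip) return(as.integer(kid %in% keepSet))
        desc <- ape::extract.clade(tree, kid)$tip.label
        length(intersect(match(desc, tree$tip.label), keepSet))
      }, integer(1))
      if (any(surv == 0L))
        .err("pruneError",
             sprintf("named node '%s' loses all descendants on one side under this pruning",
                     tree$node.label[w]))
    }
  }
  ape::keep.tip(tree, keep)
}

#' Simple-majority consensus of gapped sequences on shared columns
#'
#' Per column, the most frequent symbol over the 20 residues and the gap;
#' ties are broken with \code{"-"} last, then alphabetically among
#' residues.
#'
#' @param sequences character vector of equal-length gapped sequences, a
#'   [ReconstructionSet-class], or a [ProteinAlignment-class].
#' @param nodeId,gapThreshold metadata attached to the result (taken from a
#'   ReconstructionSet automatically).
#' @return A [ConsensusSequence-class] with the per-column winning-symbol
#'   frequency.
#' @export
consensusSequence <- function(sequences, nodeId = "consensus",
                              gapThreshold = NA_real_) {
  if (is(sequences, "ReconstructionSet")) {
    nodeId <- sequences@nodeId
    gapThreshold <- sequences@gapThreshold
    sequences <- sequences@sequences
  } else if (is(sequences, "ProteinAlignment")) {
    sequences <- alignmentStrings(sequences)
  }
  if (length(sequences) < 1L) .err("validationError", "no sequences")
  if (length(unique(nchar(sequences))) != 1L)
    .err("alignmentError", "sequences must share the master column count")
  m <- .seqsToMatrix(sequences)
  symbols <- c(AA_ALPHA, GAP_CHAR)   # '-' last: loses ties to any residue
  counts <- apply(m, 2L, function(col) {
    tabulate(match(col, symbols), nbins = length(symbols))
  })
  win <- apply(counts, 2L, which.max)   # first max: alphabetical, '-' last
  winFreq <- counts[cbind(win, seq_len(ncol(counts)))] / nrow(m)
  new("ConsensusSequence", nodeId = nodeId, gapThreshold = gapThreshold,
      sequence = paste0(symbols[win], collapse = ""),
      winningFrequency = winFreq)
}

#' Replicated ancestral reconstruction with consensus
#'
#' The full resampling design: for each of \code{n} replicates, draw one
#' member per cluster (seed substream \code{seed + r}), subset the master
#' alignment rows (columns preserved), prune the guide tree, compute the
#' reconstruction profile at the node of interest, and call sequences at
#' every requested gap threshold; then build the simple-majority consensus
#' per threshold.
#'
#' @inheritParams siteLogLikelihood
#' @param clusters a [ClusterSet-class]; NULL means singleton clusters
#'   (every record its own cluster; no reduction).
#' @param nodeId node of interest: \code{"root"} or a named internal node
#'   that survives every pruning.
#' @param thresholds integer percents in [1, 99].
#' @param n number of replicates.
#' @param seed master integer seed.
#' @param indelRate fixed indel rate, or NULL to re-estimate per replicate.
#' @return list with elements \code{sets} (named list of
#'   [ReconstructionSet-class] per threshold) and \code{consensus} (named
#'   list of [ConsensusSequence-class] per threshold).
#' @export
replicatedASR <- function(alignment, tree, model, clusters = NULL,
                          nodeId = "root", thresholds = c(10, 50, 90),
                          n = 100L, seed = 1L, indelRate = NULL) {
  validateTree(tree)
  checkPairing(tree, alignment)
  if (any(thresholds < 1 | thresholds > 99))
    .err("validationError", "thresholds must lie in [1, 99]")
  if (is.null(clusters))
    clusters <- new("ClusterSet",
                    clusters = as.list(sequenceNames(alignment)),
                    provenance = "computed")
  checkClusterPairing(clusters, alignment)
  subsets <- makeReplicates(clusters, n, seed)
  thrNames <- as.character(thresholds)
  seqs <- matrix(NA_character_, nrow = n, ncol = length(thresholds),
                 dimnames = list(NULL, thrNames))
  anchors <- if (identical(nodeId, "root")) character(0) else as.character(nodeId)
  for (r in seq_len(n)) {
    keep <- subsets[[r]]
    sub <- alignment[keep]
    ptree <- pruneTree(tree, keep, nodesOfInterest = anchors)
    pnode <- if (identical(nodeId, "root")) "root" else nodeId
    prof <- reconstructionProfile(ptree, sub, model, nodeId = pnode,
                                  indelRate = indelRate)
    for (ti in seq_along(thresholds))
      seqs[r, ti] <- ancSequence(callSequence(prof, thresholds[ti]))
  }
  sets <- list()
  cons <- list()
  for (ti in seq_along(thresholds)) {
    sets[[thrNames[ti]]] <- new("ReconstructionSet",
                                nodeId = as.character(nodeId),
                                gapThreshold = thresholds[ti],
                                sequences = unname(seqs[, ti]))
    cons[[thrNames[ti]]] <- consensusSequence(sets[[thrNames[ti]]])
  }
  list(sets = sets, consensus = cons)
}
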