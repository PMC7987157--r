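#' @import methods
NULL

#' Gapped protein multiple sequence alignment
#'
#' Column-indexed container for a set of aligned amino-acid sequences over
#' the alphabet of the 20 standard residues plus \code{"-"} (gap) and
#' \code{"X"} (unknown residue, treated as missing data by all likelihood
#' machinery).  The alignment columns are the master coordinate system for
#' every downstream computation: ancestral profiles, consensus sequences,
#' domain intervals and trimming maps all refer to these columns.
#'
#' @slot seqs character matrix, rows = sequences (rownames are the FASTA
#'   headers), columns = alignment columns; every cell one character.
#'
#' @seealso [readFastaAlignment()], [proteinAlignment()]
#' @export
setClass("ProteinAlignment", representation(seqs = "matrix"))

setValidity("ProteinAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m) || nrow(m) < 1L)
    return("alignment must contain at least one record")
  if (ncol(m) < 1L)
    return("alignment must contain at least one column")
  bad <- !(m %in% c(AA_ORDER, GAP_CHAR, UNKNOWN_CHAR))
  dim(bad) <- dim(m)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    return(sprintf("illegal symbol '%s' in record '%s' at column %d",
                   m[idx[1L], idx[2L]], rownames(m)[idx[1L]] %||% idx[1L],
                   idx[2L]))
  }
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("records must carry unique names")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a ProteinAlignment
#'
#' @param sequences named character vector of equal-length gapped sequences,
#'   or a character matrix of single characters with rownames.
#' @return A [ProteinAlignment-class] object.  Characters are uppercased and
#'   the alternative gap character \code{"."} is normalized to \code{"-"}.
#' @examples
#' aln <- proteinAlignment(c(a = "AC-", b = "AG-"))
#' nColumns(aln)
#' @export
proteinAlignment <- function(sequences) {
  if (is.matrix(sequences)) m <- sequences
  else {
    if (is.null(names(sequences)))
      names(sequences) <- paste0("seq", seq_along(sequences))
    if (any(nchar(sequences) == 0L))
      .err("formatError", sprintf("record '%s' has length 0",
                                  names(sequences)[nchar(sequences) == 0L][1L]))
    m <- .seqsToMatrix(sequences)
  }
  m[] <- toupper(m)
  m[m == "."] <- GAP_CHAR
  bad <- !(m %in% c(AA_ORDER, GAP_CHAR, UNKNOWN_CHAR))
  dim(bad) <- dim(m)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    .err("formatError",
         sprintf("illegal residue symbol '%s' in record '%s' at column %d",
                 m[idx[1L], idx[2L]], rownames(m)[idx[1L]], idx[2L]))
  }
  new("ProteinAlignment", seqs = m)
}

#' Amino-acid substitution rate model
#'
#' A reversible continuous-time Markov model over a residue alphabet:
#' symmetric exchangeabilities, equilibrium frequencies and the normalized
#' rate matrix (expected substitutions per site per unit branch length = 1).
#' The eigendecomposition of the frequency-symmetrized rate matrix is cached
#' so transition matrices for many branch lengths are cheap.
#'
#' The same class drives both the 20-state residue model (WAG) and the
#' 2-state presence/absence model used for gap inference.
#'
#' @slot alphabet character vector of state symbols.
#' @slot exch symmetric matrix of exchangeabilities (diagonal zero).
#' @slot eqFreqs equilibrium frequencies, summing to 1.
#' @slot rateMatrix normalized rate matrix Q (rows sum to 0).
#' @slot nRateCategories number of discrete-gamma rate categories (1 = none).
#' @slot gammaShape gamma shape parameter (NA when nRateCategories == 1).
#' @slot categoryRates per-category relative rates (mean 1).
#' @slot eigenValues,eigenVectors,invVectors cached decomposition of Q.
#'
#' @seealso [wagModel()], [transitionMatrix()]
#' @export
setClass("RateModel", representation(
  alphabet = "character",
  exch = "matrix",
  eqFreqs = "numeric",
  rateMatrix = "matrix",
  nRateCategories = "integer",
  gammaShape = "numeric",
  categoryRates = "numeric",
  eigenValues = "numeric",
  eigenVectors = "matrix",
  invVectors = "matrix"
))

setValidity("RateModel", function(object) {
  k <- length(object@alphabet)
  p <- object@eqFreqs
  Q <- object@rateMatrix
  if (abs(sum(p) - 1) > 1e-12) return("eqFreqs must sum to 1")
  if (max(abs(rowSums(Q))) > 1e-10) return("rate matrix rows must sum to 0")
  db <- p * Q - t(p * Q)
  if (max(abs(db)) > 1e-8) return("detailed balance violated")
  if (abs(-sum(p * diag(Q)) - 1) > 1e-10)
    return("rate matrix must be normalized to 1 expected substitution")
  if (object@nRateCategories > 1L &&
      abs(mean(object@categoryRates) - 1) > 1e-10)
    return("category rates must have mean 1")
  if (k != nrow(Q)) return("alphabet/matrix dimension mismatch")
  TRUE
})

#' Per-column ancestral reconstruction profile at one internal node
#'
#' @slot nodeId node identifier (label or number, as character).
#' @slot residuePosterior 20 x n_columns matrix of marginal posteriors over
#'   residues (each column sums to 1), rownames in WAG residue order.
#' @slot gapPosterior per-column posterior probability that the node state
#'   is "absent" under the binary presence/absence indel model.
#' @export
setClass("ReconstructionProfile", representation(
  nodeId = "character",
  residuePosterior = "matrix",
  gapPosterior = "numeric"
))

setValidity("ReconstructionProfile", function(object) {
  rp <- object@residuePosterior
  if (nrow(rp) != 20L) return("residuePosterior must have 20 rows")
  if (max(abs(colSums(rp) - 1)) > 1e-8)
    return("residue posteriors must sum to 1 per column")
  gp <- object@gapPosterior
  if (length(gp) != ncol(rp))
    return("gapPosterior length must equal the column count")
  if (any(gp < -1e-12 | gp > 1 + 1e-12))
    return("gap posteriors must lie in [0,1]")
  TRUE
})

#' Called ancestral sequence at one node and gap threshold
#'
#' @slot nodeId node identifier.
#' @slot gapThreshold gap-inference threshold in percent (1-99).
#' @slot sequence gapped sequence string on the master columns.
#' @export
setClass("AncestralSequence", representation(
  nodeId = "character",
  gapThreshold = "numeric",
  sequence = "character"
))

#' Set of replicate ancestral reconstructions at one threshold
#'
#' @slot nodeId node identifier.
#' @slot gapThreshold gap-inference threshold in percent.
#' @slot sequences character vector of gapped sequences, one per replicate,
#'   all on the master columns.
#' @export
setClass("ReconstructionSet", representation(
  nodeId = "character",
  gapThreshold = "numeric",
  sequences = "character"
))

setValidity("ReconstructionSet", function(object) {
  if (length(object@sequences) < 1L) return("no member sequences")
  if (length(unique(nchar(object@sequences))) != 1L)
    return("member sequences must share the master column count")
  TRUE
})

#' Simple-majority consensus across replicate reconstructions
#'
#' @slot nodeId node identifier.
#' @slot gapThreshold gap-inference threshold in percent (NA when unknown).
#' @slot sequence consensus sequence on the master columns.
#' @slot winningFrequency per-column relative frequency of the winning
#'   symbol, in (0, 1].
#' @export
setClass("ConsensusSequence", representation(
  nodeId = "character",
  gapThreshold = "numeric",
  sequence = "character",
  winningFrequency = "numeric"
))

#' Disjoint clustering of alignment members
#'
#' @slot clusters list of non-empty character vectors of member headers.
#' @slot provenance "file" (parsed from a cluster file) or "computed"
#'   (greedy identity clustering).
#' @export
setClass("ClusterSet", representation(
  clusters = "list",
  provenance = "character"
))

setValidity("ClusterSet", function(object) {
  if (length(object@clusters) < 1L) return("no clusters")
  if (any(lengths(object@clusters) == 0L)) return("empty cluster")
  all_members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(all_members)) return("clusters must be disjoint")
  TRUE
})

#' Null distribution of ancestral residue counts under WAG simulation
#'
#' @slot nodeId node identifier the reconstructions were made at.
#' @slot counts integer matrix, rows = simulations, columns = amino acids.
#' @slot nSims number of simulations.
#' @export
setClass("NullDistribution", representation(
  nodeId = "character",
  counts = "matrix",
  nSims = "integer"
))

setValidity("NullDistribution", function(object) {
  if (nrow(object@counts) != object@nSims)
    return("counts rows must equal nSims")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Conserved-block trimming result
#'
#' @slot alignment trimmed [ProteinAlignment-class].
#' @slot keptColumns strictly increasing 1-based master-column indices.
#' @export
setClass("TrimResult", representation(
  alignment = "ProteinAlignment",
  keptColumns = "integer"
))

## ---- show methods ---------------------------------------------------------

setMethod("show", "ProteinAlignment", function(object) {
  cat(sprintf("ProteinAlignment: %d sequences x %d columns (%.1f%% gaps)\n",
              nrow(object@seqs), ncol(object@seqs), gapFraction(object)))
})

setMethod("show", "RateModel", function(object) {
  cat(sprintf("RateModel: %d states (%s...), %d rate categor%s\n",
              length(object@alphabet),
              paste(utils::head(object@alphabet, 5), collapse = ""),
              object@nRateCategories,
              if (object@nRateCategories == 1L) "y" else "ies"))
})

setMethod("show", "ReconstructionProfile", function(object) {
  cat(sprintf("ReconstructionProfile at node '%s': %d columns\n",
              object@nodeId, ncol(object@residuePosterior)))
})

setMethod("show", "AncestralSequence", function(object) {
  cat(sprintf("AncestralSequence at node '%s' (gap threshold %g%%): %d/%d residues\n",
              object@nodeId, object@gapThreshold,
              ungappedLength(object@sequence), nchar(object@sequence)))
})

setMethod("show", "ClusterSet", function(object) {
  cat(sprintf("ClusterSet: %d clusters over %d members (%s)\n",
              length(object@clusters),
              length(unlist(object@clusters, use.names = FALSE)),
              object@provenance))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution at node '%s': %d simulations x %d residues\n",
              object@nodeId, object@nSims, ncol(object@counts)))
})

## ---- accessors ------------------------------------------------------------

#' Alignment accessors
#'
#' @param x a [ProteinAlignment-class].
#' @return \code{nColumns}: number of alignment columns. \code{nSequences}:
#'   number of records. \code{sequenceNames}: record headers.
#'   \code{alignmentMatrix}: the underlying character matrix.
#'   \code{alignmentStrings}: named character vector of sequence strings.
#' @export
nColumns <- function(x) ncol(x@seqs)

#' @rdname nColumns
#' @export
nSequences <- function(x) nrow(x@seqs)

#' @rdname nColumns
#' @export
sequenceNames <- function(x) rownames(x@seqs)

#' @rdname nColumns
#' @export
alignmentMatrix <- function(x) x@seqs

#' @rdname nColumns
#' @export
alignmentStrings <- function(x) .matrixToSeqs(x@seqs)

#' Subset alignment records (columns always preserved)
#'
#' @param x a [ProteinAlignment-class].
#' @param i record indices or header names.
#' @param j,...,drop ignored; columns are the master coordinate system and
#'   are never dropped by subsetting.
#' @export
setMethod("[", "ProteinAlignment", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    missing_i <- setdiff(i, rownames(x@seqs))
    if (length(missing_i))
      .err("pairingError", paste0("records not in alignment: ",
                                  paste(missing_i, collapse = ", ")))
  }
  new("ProteinAlignment", seqs = x@seqs[i, , drop = FALSE])
})

#' Cluster accessors
#'
#' @param x a [ClusterSet-class].
#' @return \code{clusterMembers}: list of member-header vectors.
#'   \code{nClusters}: number of clusters.
#' @export
clusterMembers <- function(x) x@clusters

#' @rdname clusterMembers
#' @export
nClusters <- function(x) length(x@clusters)

#' Profile and sequence accessors
#'
#' @param x a [ReconstructionProfile-class], [AncestralSequence-class],
#'   [ConsensusSequence-class] or [ReconstructionSet-class].
#' @return \code{residuePosterior}: 20 x n_columns posterior matrix.
#'   \code{gapPosterior}: per-column gap posterior. \code{ancSequence}: the
#'   sequence string. \code{setSequences}: replicate sequences.
#' @export
residuePosterior <- function(x) x@residuePosterior

#' @rdname residuePosterior
#' @export
gapPosterior <- function(x) x@gapPosterior

#' @rdname residuePosterior
#' @export
ancSequence <- function(x) x@sequence

#' @rdname residuePosterior
#' @export
setSequences <- function(x) x@sequences

#' Rate-model accessors
#'
#' @param x a [RateModel-class].
#' @return \code{eqFreqs}: equilibrium frequencies. \code{rateMatrix}: the
#'   normalized rate matrix. \code{modelAlphabet}: state symbols.
#' @export
eqFreqs <- function(x) x@eqFreqs

#' @rdname eqFreqs
#' @export
rateMatrix <- function(x) x@rateMatrix

#' @rdname eqFreqs
#' @export
modelAlphabet <- function(x) x@alphabet

#' Null-distribution counts
#'
#' @param x a [NullDistribution-class].
#' @param residue optional one-letter code; when given, the count vector for
#'   that residue, otherwise the full matrix.
#' @export
nullCounts <- function(x, residue = NULL) {
  if (is.null(residue)) return(x@counts)
  if (!residue %in% colnames(x@counts))
    .err("validationError", sprintf("residue '%s' not in null distribution", residue))
  x@counts[, residue]
}
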