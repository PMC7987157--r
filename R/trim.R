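# Conserved-block selection in the style of Gblocks (Castresana rules):
# per-column conservation status from occupancy thresholds, removal of long
# nonconserved stretches, flank trimming to highly conserved columns, and
# minimum block length. Reimplements the published rule set; it does not
# promise byte-equivalence with the original binary, whose flank-scanning
# details are under-documented.

#' Trimming parameters
#'
#' @param nSeqs number of sequences in the alignment the parameters apply
#'   to (used for defaults and bounds).
#' @param minConserved minimum sequences carrying the most frequent residue
#'   for a conserved column; default \code{floor(n/2) + 1}, the minimum the
#'   rule set allows.
#' @param minFlank minimum for a highly conserved (flanking) column;
#'   default \code{ceiling(0.85 n)}; must be >= \code{minConserved}.
#' @param maxNonconservedStretch longest run of nonconserved columns kept
#'   inside a block (default 8).
#' @param minBlockLength shortest block kept (default 10).
#' @param gapAllowance \code{"none"} (any gap disqualifies a column),
#'   \code{"half"} (columns with gaps in >= 50\% of sequences are
#'   disqualified) or \code{"all"} (gaps never disqualify).
#' @return list of class \code{"TrimParams"}.
#' @export
trimParams <- function(nSeqs, minConserved = NULL, minFlank = NULL,
                       maxNonconservedStretch = 8L, minBlockLength = 10L,
                       gapAllowance = c("none", "half", "all")) {
  gapAllowance <- match.arg(gapAllowance)
  floorCons <- floor(nSeqs / 2) + 1L
  if (is.null(minConserved)) minConserved <- floorCons
  if (is.null(minFlank)) minFlank <- ceiling(0.85 * nSeqs)
  if (minConserved < floorCons)
    .err("validationError",
         sprintf("minConserved must be >= floor(n/2)+1 = %d", floorCons))
  if (minFlank < minConserved)
    .err("validationError", "minFlank must be >= minConserved")
  if (minBlockLength < 1L)
    .err("validationError", "minBlockLength must be >= 1")
  structure(list(nSeqs = as.integer(nSeqs),
                 minConserved = as.integer(minConserved),
                 minFlank = as.integer(minFlank),
                 maxNonconservedStretch = as.integer(maxNonconservedStretch),
                 minBlockLength = as.integer(minBlockLength),
                 gapAllowance = gapAllowance),
            class = "TrimParams")
}

#' The relaxed trimming preset
#'
#' The permissive parameterization for divergent protein alignments:
#' conservation thresholds at their minimum (just over half the
#' sequences), up to 100 contiguous nonconserved positions, minimum block
#' length two, and no gap disqualification.
#'
#' @param nSeqs number of sequences.
#' @return a [trimParams()] object.
#' @export
relaxedTrimParams <- function(nSeqs) {
  trimParams(nSeqs, maxNonconservedStretch = 100L, minBlockLength = 2L,
             gapAllowance = "all")
}

#' Classify alignment columns by conservation
#'
#' A column is conserved when its most frequent residue (gaps and X never
#' count as the residue) occurs in at least \code{minConserved} sequences,
#' highly conserved at \code{minFlank}; gap handling follows
#' \code{gapAllowance}.
#'
#' @param alignment a [ProteinAlignment-class].
#' @param params a [trimParams()].
#' @return character vector over columns with values \code{"nonconserved"},
#'   \code{"conserved"}, \code{"highly_conserved"}.
#' @export
classifyColumns <- function(alignment, params) {
  m <- alignmentMatrix(alignment)
  n <- nrow(m)
  if (params$nSeqs != n)
    .err("validationError", "params built for a different sequence count")
  status <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    resCounts <- tabulate(match(col, AA_ORDER), nbins = 20L)
    top <- max(resCounts)
    nGaps <- sum(col == GAP_CHAR)
    gapBad <- switch(params$gapAllowance,
                     none = nGaps > 0L,
                     half = 2L * nGaps >= n,
                     all = FALSE)
    status[j] <- if (gapBad || top < params$minConserved) "nonconserved"
                 else if (top >= params$minFlank) "highly_conserved"
                 else "conserved"
  }
  status
}

#' Select conserved blocks from column statuses
#'
#' The block rules: (1) every maximal run of nonconserved columns longer
#' than \code{maxNonconservedStretch} is removed; (2) each remaining
#' segment is trimmed from both ends up to its first and last highly
#' conserved column (blocks must be flanked by highly conserved
#' positions); (3) blocks shorter than \code{minBlockLength} are removed.
#'
#' @param statuses column statuses from [classifyColumns()].
#' @param params a [trimParams()].
#' @return integer vector of kept 1-based column indices (possibly empty,
#'   with a warning).
#' @export
selectBlocks <- function(statuses, params) {
  C <- length(statuses)
  keepMask <- rep(TRUE, C)
  # (1) long nonconserved stretches
  r <- rle(statuses == "nonconserved")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (r$values[i] && r$lengths[i] > params$maxNonconservedStretch)
      keepMask[starts[i]:ends[i]] <- FALSE
  }
  # (2) flank trimming within each surviving segment
  kept <- integer(0)
  r2 <- rle(keepMask)
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  for (i in seq_along(r2$lengths)) {
    if (!r2$values[i]) next
    seg <- starts2[i]:ends2[i]
    hc <- seg[statuses[seg] == "highly_conserved"]
    if (length(hc) == 0L) next
    block <- seg[seg >= min(hc) & seg <= max(hc)]
    # (3) minimum block length
    if (length(block) >= params$minBlockLength)
      kept <- c(kept, block)
  }
  if (length(kept) == 0L)
    warning("no columns survive block selection", call. = FALSE)
  kept
}

#' Trim an alignment to its conserved blocks
#'
#' @param alignment a [ProteinAlignment-class].
#' @param params a [trimParams()] (default: the relaxed preset for this
#'   alignment's size).
#' @return a [TrimResult-class] with the trimmed alignment and the kept
#'   master-column indices.
#' @export
trimAlignment <- function(alignment, params = relaxedTrimParams(nSequences(alignment))) {
  statuses <- classifyColumns(alignment, params)
  kept <- selectBlocks(statuses, params)
  m <- alignmentMatrix(alignment)[, kept, drop = FALSE]
  if (length(kept) == 0L)
    .err("validationError", "no columns kept; nothing to trim to")
  new("TrimResult", alignment = new("ProteinAlignment", seqs = m),
      keptColumns = as.integer(kept))
}

#' Percentage of gap cells in an alignment
#'
#' @param alignment a [ProteinAlignment-class].
#' @return percent of cells equal to \code{"-"}.
#' @export
gapFraction <- function(alignment) {
  m <- alignmentMatrix(alignment)
  100 * sum(m == GAP_CHAR) / length(m)
}
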