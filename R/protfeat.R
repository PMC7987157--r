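# Sequence-level physicochemical calculators: net charge and isoelectric
# point (Henderson-Hasselbalch with the Bjellqvist pK constants, bisection
# root finding), mean Kyte-Doolittle hydropathy, a localization heuristic
# and membrane-targeting-sequence (MTS) extraction by pairwise alignment.

#' Bjellqvist pK constants
#'
#' The side-chain and terminal pK values used by the common isoelectric
#' point webserver implementation. Alternative sets can be supplied with
#' the same structure.
#'
#' @return list with \code{nTerm}, \code{cTerm} and \code{sideChain}
#'   (named numeric for D, E, C, Y, H, K, R).
#' @export
bjellqvistPK <- function() {
  list(nTerm = 7.5, cTerm = 3.55,
       sideChain = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
                     H = 5.98, K = 10.0, R = 12.0))
}

.checkPKSet <- function(pks) {
  vals <- c(pks$nTerm, pks$cTerm, pks$sideChain)
  if (any(vals <= 0 | vals >= 14))
    .err("validationError", "all pK values must lie in (0, 14)")
  invisible(pks)
}

#' Net charge of an ungapped sequence at a given pH
#'
#' Henderson-Hasselbalch sum over the two termini and the ionizable side
#' chains: positive groups (N-terminus, His, Lys, Arg) contribute
#' \code{+n / (1 + 10^(pH - pK))}, negative groups (C-terminus, Asp, Glu,
#' Cys, Tyr) contribute \code{-n / (1 + 10^(pK - pH))}. Strictly
#' decreasing in pH.
#'
#' @param seq ungapped sequence string (a gap is a domain-error; degap
#'   first).
#' @param pH real pH value.
#' @param pks a pK set, see [bjellqvistPK()].
#' @return net charge (real).
#' @export
netCharge <- function(seq, pH, pks = bjellqvistPK()) {
  .checkPKSet(pks)
  if (nchar(seq) == 0L) .err("validationError", "sequence must be non-empty")
  if (grepl("-", seq, fixed = TRUE))
    .err("domainError", "gapped input; degap the sequence before charge calculations")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = AA_ORDER))
  posK <- c(pks$nTerm, pks$sideChain[c("H", "K", "R")])
  posN <- c(1, counts[c("H", "K", "R")])
  negK <- c(pks$cTerm, pks$sideChain[c("D", "E", "C", "Y")])
  negN <- c(1, counts[c("D", "E", "C", "Y")])
  sum(posN / (1 + 10^(pH - posK))) - sum(negN / (1 + 10^(negK - pH)))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in [0, 14] where the net charge crosses zero. The charge is
#' strictly decreasing in pH and is positive at pH 0 (protonated
#' N-terminus) and negative at pH 14 (deprotonated C-terminus), so
#' bisection always converges; if no sign change exists under an unusual
#' pK set, the nearer boundary is returned with \code{flagged = TRUE}.
#'
#' @param seq ungapped sequence string.
#' @param pks a pK set, see [bjellqvistPK()].
#' @param tol absolute charge tolerance per residue for the convergence
#'   guard (|charge(pI)| < tol * length).
#' @return list with \code{pI}, \code{charge} at pI, \code{flagged}.
#' @export
isoelectricPoint <- function(seq, pks = bjellqvistPK(), tol = 1e-3) {
  lo <- 0
  hi <- 14
  clo <- netCharge(seq, lo, pks)
  chi <- netCharge(seq, hi, pks)
  if (clo < 0 || chi > 0) {
    pI <- if (abs(clo) < abs(chi)) lo else hi
    return(list(pI = pI, charge = netCharge(seq, pI, pks), flagged = TRUE))
  }
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    cm <- netCharge(seq, mid, pks)
    if (cm > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-6) break
  }
  pI <- (lo + hi) / 2
  charge <- netCharge(seq, pI, pks)
  list(pI = pI, charge = charge,
       flagged = abs(charge) >= tol * nchar(seq))
}

#' The Kyte-Doolittle hydropathy scale
#'
#' @return named numeric over the 20 residues (positive = hydrophobic).
#' @export
kyteDoolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
}

#' Mean hydropathy of a sequence
#'
#' Arithmetic mean of the scale values over the residues after degapping;
#' unknown residues (\code{X}) are excluded from both numerator and
#' denominator. Permutation-invariant by construction.
#'
#' @param seq sequence string (gaps are removed).
#' @param scale residue-to-value table, see [kyteDoolittle()].
#' @return mean hydropathy (real).
#' @export
meanHydropathy <- function(seq, scale = kyteDoolittle()) {
  chars <- strsplit(gsub("-", "", seq, fixed = TRUE), "", fixed = TRUE)[[1L]]
  chars <- chars[chars != UNKNOWN_CHAR]
  if (length(chars) == 0L)
    .err("domainError", "no scorable residues (empty or all-X sequence)")
  if (!all(chars %in% names(scale)))
    .err("validationError", "hydropathy scale must cover all residues")
  mean(scale[chars])
}

#' Classify localization from mean hydropathy
#'
#' A deliberately simple heuristic: sequences at or above the threshold are
#' called transmembrane-like, below it cytoplasmic. This approximates the
#' qualitative behaviour of hydrophobicity-index classifiers (sign and
#' ordering), and is not equivalent to any proprietary predictor.
#'
#' @param h mean hydropathy value.
#' @param threshold decision boundary (default 0.6; the boundary itself is
#'   classified transmembrane-like).
#' @return \code{"transmembrane_like"} or \code{"cytoplasmic"}.
#' @export
classifyLocalization <- function(h, threshold = 0.6) {
  if (h >= threshold) "transmembrane_like" else "cytoplasmic"
}

#' Extract a membrane-targeting-sequence (MTS) region by alignment
#'
#' Globally aligns a user-supplied reference MTS (the motif is not part of
#' any domain database, so the reference must be provided) against the
#' degapped target with affine gap penalties, and reports the matched
#' interval, its subsequence and its isoelectric point. An alignment score
#' below \code{scoreFloor} yields a not-found result.
#'
#' @param seq target sequence (gaps removed before alignment).
#' @param referenceMts ungapped reference MTS sequence.
#' @param scoring substitution matrix name understood by
#'   [Biostrings::pairwiseAlignment()] (default "BLOSUM62").
#' @param gapOpening,gapExtension affine gap penalties.
#' @param scoreFloor minimum acceptable alignment score.
#' @param pks pK set for the isoelectric point of the extracted region.
#' @return list with \code{found}; when found also \code{interval}
#'   (0-based half-open on the degapped target), \code{subsequence},
#'   \code{pI} and \code{score}.
#' @export
extractMTS <- function(seq, referenceMts, scoring = "BLOSUM62",
                       gapOpening = 10, gapExtension = 0.5,
                       scoreFloor = 0, pks = bjellqvistPK()) {
  target <- gsub("-", "", seq, fixed = TRUE)
  if (nchar(target) == 0L || nchar(referenceMts) == 0L)
    .err("validationError", "sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(referenceMts),
    subject = Biostrings::AAString(target),
    type = "global-local", substitutionMatrix = scoring,
    gapOpening = gapOpening, gapExtension = gapExtension)
  sc <- Biostrings::score(aln)
  if (sc < scoreFloor) return(list(found = FALSE, score = sc))
  s <- Biostrings::start(Biostrings::subject(aln))
  e <- Biostrings::end(Biostrings::subject(aln))
  subseq <- substr(target, s, e)
  list(found = TRUE, interval = c(s - 1L, e), subsequence = subseq,
       pI = isoelectricPoint(subseq, pks)$pI, score = sc)
}
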