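# Substitution-model machinery: building reversible rate models, the WAG
# parameters, and transition probabilities via eigendecomposition of the
# frequency-symmetrized rate matrix (exactly reversible, cheap to reuse
# across many branch lengths).

# Build a normalized reversible rate matrix and cache its decomposition.
# exch: symmetric non-negative matrix (diagonal ignored); freqs sum to 1.
.makeRateModel <- function(alphabet, exch, freqs, nRateCategories = 1L,
                           gammaShape = NA_real_) {
  k <- length(alphabet)
  stopifnot(nrow(exch) == k, length(freqs) == k)
  freqs <- freqs / sum(freqs)
  Q <- exch * rep(freqs, each = k)   # q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  # symmetrize: S = D^{1/2} Q D^{-1/2} with D = diag(pi); S symmetric for
  # reversible Q, so eigen() is stable and P(t) is exactly reversible.
  sq <- sqrt(freqs)
  S <- Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  V <- es$vectors * (1 / sq)        # rows scaled: V = D^{-1/2} U
  Vinv <- t(es$vectors * sq)        # Vinv = U' D^{1/2}
  if (nRateCategories > 1L) {
    if (!is.finite(gammaShape) || gammaShape <= 0)
      .err("validationError",
           "gammaShape must be a positive real when nRateCategories > 1")
    rates <- .discreteGammaRates(gammaShape, nRateCategories)
  } else {
    rates <- 1
  }
  dimnames(Q) <- list(alphabet, alphabet)
  dimnames(exch) <- list(alphabet, alphabet)
  names(freqs) <- alphabet
  new("RateModel", alphabet = alphabet, exch = exch, eqFreqs = freqs,
      rateMatrix = Q, nRateCategories = as.integer(nRateCategories),
      gammaShape = as.numeric(gammaShape), categoryRates = rates,
      eigenValues = es$values, eigenVectors = V, invVectors = Vinv)
}

# Mean-1 discrete gamma category rates (equal-probability categories,
# category mean method).
.discreteGammaRates <- function(shape, k) {
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  # mean of the gamma density within each quantile slice
  p <- stats::pgamma(q * shape / shape, shape = shape + 1, rate = shape)
  r <- k * diff(p)
  r / mean(r)
}

#' The WAG amino-acid substitution model
#'
#' Returns the published WAG exchangeabilities and equilibrium frequencies
#' as a normalized reversible [RateModel-class] (expected substitutions per
#' site per unit branch length = 1), residues in the canonical WAG order
#' ARNDCQEGHILKMFPSTWYV. Discrete-gamma rate heterogeneity is available but
#' off by default: ancestral reconstruction here uses plain WAG.
#'
#' @param nRateCategories number of discrete-gamma categories (1 = none).
#' @param gammaShape gamma shape; required when \code{nRateCategories > 1}.
#' @return A [RateModel-class].
#' @examples
#' m <- wagModel()
#' sum(eqFreqs(m))  # 1
#' @export
wagModel <- function(nRateCategories = 1L, gammaShape = NA_real_) {
  readRateModelFile(system.file("extdata", "wag.dat", package = "srpAncestry"),
                    nRateCategories = nRateCategories, gammaShape = gammaShape)
}

#' Read a substitution model from a PAML/PhyML "dat" file
#'
#' The layout is the standard one: 19 lines giving the lower triangle of the
#' symmetric exchangeability matrix (row i holds entries for states
#' 2..20 against 1..i-1), a blank line, then the 20 equilibrium frequencies.
#'
#' @param path path to the .dat file.
#' @param alphabet state symbols (default: WAG residue order).
#' @param nRateCategories,gammaShape as in [wagModel()].
#' @return A [RateModel-class].
#' @export
readRateModelFile <- function(path, alphabet = AA_ORDER,
                              nRateCategories = 1L, gammaShape = NA_real_) {
  if (!file.exists(path))
    .err("formatError", sprintf("model file not found: %s", path))
  txt <- readLines(path)
  nums <- as.numeric(unlist(strsplit(trimws(txt[nzchar(trimws(txt))]), "\\s+")))
  k <- length(alphabet)
  need <- k * (k - 1L) / 2L + k
  if (length(nums) < need || any(!is.finite(nums[seq_len(need)])))
    .err("formatError", sprintf("model file %s: expected %d numbers", path, need))
  exch <- matrix(0, k, k)
  pos <- 1L
  for (i in 2:k) {
    exch[i, 1:(i - 1L)] <- nums[pos:(pos + i - 2L)]
    pos <- pos + i - 1L
  }
  exch <- exch + t(exch)
  freqs <- nums[pos:(pos + k - 1L)]
  .makeRateModel(alphabet, exch, freqs, nRateCategories, gammaShape)
}

#' The 2-state presence/absence model for indel inference
#'
#' A reversible binary model over states \code{"1"} (residue present) and
#' \code{"0"} (absent) with equal stationary frequencies, normalized to 1
#' expected change per site per unit branch length. The indel rate relative
#' to the residue substitution process is applied through the
#' \code{categoryRate} argument of [transitionMatrix()] (i.e. effective
#' change rate = \code{rate * t} on a branch of length \code{t}).
#'
#' @return A [RateModel-class] with alphabet \code{c("1", "0")}.
#' @export
indelModel <- function() {
  exch <- matrix(c(0, 2, 2, 0), 2, 2)
  .makeRateModel(c("1", "0"), exch, c(0.5, 0.5))
}

#' Transition probability matrix P(t)
#'
#' \code{P(t) = exp(Q t r)} computed from the cached symmetric
#' eigendecomposition of the rate matrix; exactly row-stochastic and
#' reversible up to round-off.
#'
#' @param model a [RateModel-class].
#' @param t branch length in expected substitutions per site (>= 0).
#' @param categoryRate relative rate multiplier (e.g. a discrete-gamma
#'   category rate), default 1.
#' @return k x k row-stochastic matrix (rows: ancestral state).
#' @examples
#' P <- transitionMatrix(wagModel(), 0.1)
#' range(rowSums(P))  # 1
#' @export
transitionMatrix <- function(model, t, categoryRate = 1) {
  .assertScalarNumber(t, "t")
  if (t < 0) .err("domainError", "branch length t must be >= 0")
  P <- model@eigenVectors %*%
    (exp(model@eigenValues * t * categoryRate) * model@invVectors)
  # clamp tiny negative round-off and renormalize rows
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(model@alphabet, model@alphabet)
  P
}
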