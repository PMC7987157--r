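# Amino-acid chronology statistics: counting late-code residues per
# sequence/node/domain, observed-vs-null depletion tests, alignment summary
# statistics and posterior-support comparisons.

#' Genetic-code chronology of amino acids
#'
#' The consensus recruitment order of amino acids into the canonical
#' genetic code, earliest to latest, with the late set comprising the six
#' residues believed to have been added last (Cys, His, Phe, Met, Tyr,
#' Trp). Tryptophan is widely considered the final addition.
#'
#' @return list with \code{groups} (ordered list of residue groups,
#'   earliest first) and \code{lateSet}.
#' @export
defaultChronology <- function() {
  groups <- list(c("G", "A"), c("V", "D"), "P", "S", c("E", "L"), "T",
                 "R", "N", "K", "Q", "I", "C", "H", "F", "M", "Y", "W")
  chronology(groups, lateSet = LATE_RESIDUES)
}

#' Construct a chronology
#'
#' @param groups ordered list of character vectors; every residue must
#'   appear exactly once across groups.
#' @param lateSet subset of residues regarded as late additions.
#' @return list of class \code{"Chronology"}.
#' @export
chronology <- function(groups, lateSet) {
  res <- unlist(groups, use.names = FALSE)
  if (!setequal(res, AA_ORDER) || anyDuplicated(res))
    .err("validationError",
         "chronology groups must contain every residue exactly once")
  if (!all(lateSet %in% res))
    .err("validationError", "lateSet must be a subset of the residues")
  structure(list(groups = groups, lateSet = lateSet), class = "Chronology")
}

#' Count selected residues in a gapped sequence
#'
#' Gaps are never counted; the count can be restricted to a half-open
#' 0-based column interval on the master coordinates.
#'
#' @param seq gapped sequence string.
#' @param residues character vector of one-letter codes.
#' @param interval optional \code{c(start, end)}, 0-based half-open.
#' @return integer count.
#' @examples
#' countResidues("WATW", "W")            # 2
#' countResidues("W-W", "W", c(0, 2))    # 1
#' @export
countResidues <- function(seq, residues, interval = NULL) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (!is.null(interval)) {
    if (length(interval) != 2L || interval[1L] < 0 ||
        interval[2L] > length(chars) || interval[1L] >= interval[2L])
      .err("validationError", "interval must be 0-based half-open within bounds")
    chars <- chars[(interval[1L] + 1L):interval[2L]]
  }
  sum(chars %in% setdiff(residues, GAP_CHAR))
}

#' Domain annotation on master columns
#'
#' @param names domain names (unique).
#' @param start,end 0-based half-open column intervals.
#' @param nColumns optional total column count for bounds checking.
#' @return data.frame with columns name, start, end.
#' @export
domainAnnotation <- function(names, start, end, nColumns = NULL) {
  if (anyDuplicated(names)) .err("validationError", "domain names must be unique")
  if (any(start >= end) || any(start < 0))
    .err("validationError", "domain intervals must satisfy 0 <= start < end")
  if (!is.null(nColumns) && any(end > nColumns))
    .err("validationError", "domain interval exceeds the column count")
  data.frame(name = names, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Per-sequence residue counts by group and domain
#'
#' Builds the long-format composition table: one row per (sequence,
#' residue, domain) with the count and the ungapped length. Groups come
#' from the parsed header convention when \code{groupby} is \code{"gene"}
#' or \code{"taxon_group"}; records with non-conforming headers are grouped
#' as \code{NA} and flagged, not dropped.
#'
#' @param seqs named character vector of gapped sequences or a
#'   [ProteinAlignment-class].
#' @param chron a [chronology()]; only its late set is tabulated unless
#'   \code{residues} overrides.
#' @param groupby \code{"sequence"}, \code{"gene"} or \code{"taxon_group"}.
#' @param domains optional [domainAnnotation()]; the whole sequence is
#'   always included as domain \code{"whole"}.
#' @param residues residues to count (default: the chronology's late set).
#' @return data.frame with columns id, group, residue, domain, count,
#'   ungappedLength.
#' @export
compositionSummary <- function(seqs, chron = defaultChronology(),
                               groupby = c("sequence", "gene", "taxon_group"),
                               domains = NULL, residues = NULL) {
  groupby <- match.arg(groupby)
  if (is(seqs, "ProteinAlignment")) seqs <- alignmentStrings(seqs)
  if (is.null(residues)) residues <- chron$lateSet
  ids <- names(seqs)
  groups <- switch(groupby,
    sequence = ids,
    gene = ,
    taxon_group = {
      lab <- lapply(ids, function(h)
        tryCatch(parseLabel(h), error = function(e) NULL))
      vapply(lab, function(l) if (is.null(l)) NA_character_ else l[[groupby]],
             character(1))
    })
  doms <- rbind(data.frame(name = "whole", start = 0L,
                           end = nchar(seqs[[1L]]), stringsAsFactors = FALSE),
                domains)
  rows <- list()
  for (i in seq_along(seqs)) {
    ug <- ungappedLength(seqs[[i]])
    for (d in seq_len(nrow(doms))) {
      iv <- c(doms$start[d], doms$end[d])
      for (r in residues) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = ids[i], group = groups[i], residue = r, domain = doms$name[d],
          count = countResidues(seqs[[i]], r, interval = iv),
          ungappedLength = ug, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summary statistics of a composition table
#'
#' @param tbl a table from [compositionSummary()].
#' @return data.frame per (group, residue, domain) with n, mean, median,
#'   q25, q75, min, max of the counts.
#' @export
compositionStats <- function(tbl) {
  key <- interaction(tbl$group, tbl$residue, tbl$domain, drop = TRUE)
  out <- lapply(split(tbl, key), function(d) {
    q <- stats::quantile(d$count, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = d$group[1L], residue = d$residue[1L],
               domain = d$domain[1L], n = nrow(d), mean = mean(d$count),
               median = q[2L], q25 = q[1L], q75 = q[3L],
               min = min(d$count), max = max(d$count),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Empirical depletion test of an observed count against a simulation null
#'
#' One-sided: is the observed ancestral count lower than expected under the
#' model null? \code{p = (1 + #\{null <= observed\}) / (nSims + 1)};
#' \code{z = (observed - mean) / SD} (flagged absent for a zero-variance
#' null). p is in (0, 1] and monotone non-increasing as the observed count
#' decreases.
#'
#' @param observed observed integer count.
#' @param null numeric vector of null counts, or a
#'   [NullDistribution-class] (then give \code{residue}).
#' @param residue residue column when \code{null} is a NullDistribution.
#' @return list with \code{p}, \code{z} (NA when the null has zero
#'   variance), \code{nSims}, \code{nullMean}, \code{nullSD}.
#' @export
depletionTest <- function(observed, null, residue = NULL) {
  if (is(null, "NullDistribution")) {
    null <- if (is.null(residue)) rowSums(nullCounts(null))
            else nullCounts(null, residue)
  }
  n <- length(null)
  if (n < 20L)
    .err("validationError", "null distribution must have at least 20 simulations")
  p <- (1 + sum(null <= observed)) / (n + 1)
  s <- stats::sd(null)
  z <- if (s > 0) (observed - mean(null)) / s else NA_real_
  list(p = p, z = z, nSims = n, nullMean = mean(null), nullSD = s)
}

#' Average pairwise identity and positivity of an alignment
#'
#' For every unordered pair: the denominator is the number of columns where
#' at least one member has a residue (gap-gap columns excluded, residue-gap
#' columns count as mismatches); identity counts equal residues, positivity
#' counts residue pairs with a strictly positive substitution score
#' (standard BLAST "positives" semantics).
#'
#' @param alignment a [ProteinAlignment-class] with >= 2 records.
#' @param scoring substitution matrix with residue dimnames (default
#'   BLOSUM62 from Biostrings).
#' @return list with \code{identity} and \code{positive}, both averaged
#'   percentages.
#' @export
pairwiseIdentityStats <- function(alignment, scoring = NULL) {
  if (nSequences(alignment) < 2L)
    .err("validationError", "need at least 2 records")
  if (is.null(scoring)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    scoring <- e$BLOSUM62
  }
  m <- alignmentMatrix(alignment)
  n <- nrow(m)
  gap <- m == GAP_CHAR
  res <- m %in% AA_ORDER
  dim(res) <- dim(m)
  idSum <- 0
  posSum <- 0
  npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      den <- sum(!(gap[i, ] & gap[j, ]))
      if (den == 0L) next
      both <- res[i, ] & res[j, ]
      idNum <- sum(both & m[i, ] == m[j, ])
      sc <- scoring[cbind(m[i, both], m[j, both])]
      posNum <- sum(sc > 0)
      idSum <- idSum + 100 * idNum / den
      posSum <- posSum + 100 * posNum / den
      npair <- npair + 1L
    }
  }
  list(identity = idSum / npair, positive = posSum / npair)
}

#' Compare two sets of posterior support values
#'
#' An F-test of the variance ratio, a pooled-variance one-tailed t-test
#' (alternative: mean of \code{a} greater than mean of \code{b}), and the
#' cumulative fraction of nodes with support >= x for x on a 0.01 grid.
#' Zero variance in both samples is flagged degenerate and compared by
#' means only.
#'
#' @param a,b numeric vectors of support values (length >= 3).
#' @return list with \code{F}, \code{Fp}, \code{t}, \code{p},
#'   \code{degenerate}, \code{meanA}, \code{meanB} and \code{cumulative}
#'   (data.frame x, fracA, fracB).
#' @export
supportComparison <- function(a, b) {
  if (length(a) < 3L || length(b) < 3L)
    .err("validationError", "each support list must have length >= 3")
  x <- seq(0, 1, by = 0.01)
  cum <- data.frame(x = x,
                    fracA = vapply(x, function(v) mean(a >= v), numeric(1)),
                    fracB = vapply(x, function(v) mean(b >= v), numeric(1)))
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    return(list(F = NA_real_, Fp = NA_real_, t = NA_real_, p = NA_real_,
                degenerate = TRUE, meanA = mean(a), meanB = mean(b),
                cumulative = cum))
  }
  ft <- stats::var.test(a, b)
  tt <- stats::t.test(a, b, var.equal = TRUE, alternative = "greater")
  list(F = unname(ft$statistic), Fp = ft$p.value,
       t = unname(tt$statistic), p = tt$p.value,
       degenerate = FALSE, meanA = mean(a), meanB = mean(b),
       cumulative = cum)
}
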