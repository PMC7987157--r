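# Reading/writing alignments, trees, taxon labels and the plain-text
# cluster / replicate-reconstruction file dialects.

#' Read a FASTA protein alignment
#'
#' Reads an aligned FASTA file into a [ProteinAlignment-class]. Characters
#' are uppercased and the alternative gap character \code{"."} is normalized
#' to \code{"-"}. All records must have identical length; \code{"X"} is
#' accepted and treated as missing data downstream.
#'
#' @param path path to a FASTA file.
#' @return A [ProteinAlignment-class].
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC-", ">b", "AG-"), f)
#' readFastaAlignment(f)
#' @export
readFastaAlignment <- function(path) {
  if (!file.exists(path))
    .err("formatError", sprintf("file not found: %s", path))
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) .err("formatError", conditionMessage(e)))
  if (length(ss) == 0L)
    .err("formatError", sprintf("no FASTA records in %s", path))
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))  # header up to first whitespace
  if (any(nchar(seqs) == 0L))
    .err("formatError",
         sprintf("record '%s' has length 0", names(seqs)[nchar(seqs) == 0L][1L]))
  if (length(unique(nchar(seqs))) != 1L)
    .err("alignmentError",
         sprintf("ragged alignment in %s: lengths %s", path,
                 paste(sort(unique(nchar(seqs))), collapse = ", ")))
  proteinAlignment(seqs)
}

#' Write an alignment (or any named set of sequences) as FASTA
#'
#' @param x a [ProteinAlignment-class] or named character vector.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeFastaAlignment <- function(x, path) {
  seqs <- if (is(x, "ProteinAlignment")) alignmentStrings(x) else x
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Parse a taxon header of the form gene_domain_phylum_Accession
#'
#' The first token is the gene (one of FtsY, Ffh, FlhA, SS, SecY), the
#' second the taxonomic domain, the last the accession; any middle tokens
#' beyond the domain are joined into the taxon group (superphylum names can
#' themselves contain underscores).
#'
#' @param header header string, or vector of headers.
#' @return A data.frame with columns \code{header}, \code{gene},
#'   \code{domain}, \code{taxon_group}, \code{accession}.
#' @examples
#' parseLabel("FtsY_Bacteria_Proteobacteria_P10121")
#' @export
parseLabel <- function(header) {
  out <- lapply(header, function(h) {
    tok <- strsplit(h, "_", fixed = TRUE)[[1L]]
    if (length(tok) < 4L)
      .err("labelError", sprintf("header '%s' has fewer than 4 tokens", h))
    if (!tok[1L] %in% GENE_TOKENS)
      .err("labelError", sprintf("unknown gene token '%s' in header '%s'",
                                 tok[1L], h))
    data.frame(header = h, gene = tok[1L], domain = tok[2L],
               taxon_group = paste(tok[3:(length(tok) - 1L)], collapse = "_"),
               accession = tok[length(tok)], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Format a parsed taxon label back into a header string
#'
#' Inverse of [parseLabel()]: round-trips every valid label.
#'
#' @param label a one-row data.frame as returned by [parseLabel()] (or a
#'   multi-row one; a vector of headers is returned).
#' @export
formatLabel <- function(label) {
  paste(label$gene, label$domain, label$taxon_group, label$accession, sep = "_")
}

#' Parse all alignment headers, flagging non-conforming records
#'
#' Unlike [parseLabel()], records whose headers do not follow the naming
#' convention are flagged (column \code{valid} set to FALSE), not dropped
#' and not an error.
#'
#' @param alignment a [ProteinAlignment-class].
#' @return data.frame with one row per record, columns as [parseLabel()]
#'   plus \code{valid}.
#' @export
alignmentLabels <- function(alignment) {
  headers <- sequenceNames(alignment)
  rows <- lapply(headers, function(h) {
    r <- tryCatch(parseLabel(h), error = function(e) NULL)
    if (is.null(r))
      r <- data.frame(header = h, gene = NA_character_, domain = NA_character_,
                      taxon_group = NA_character_, accession = NA_character_,
                      stringsAsFactors = FALSE)
    r
  })
  out <- do.call(rbind, rows)
  out$valid <- !is.na(out$gene)
  out
}

#' Read a Newick tree with branch lengths and support labels
#'
#' Internal node labels are retained verbatim; numeric labels are
#' interpreted as posterior support values (see [nodeSupports()]),
#' non-numeric ones as named nodes of interest (e.g. \code{preLUCA}).
#' A basal trifurcation (unrooted-style root) is accepted with a warning.
#'
#' @param path path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path))
    .err("treeError", sprintf("file not found: %s", path))
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) .err("treeError", conditionMessage(e)))
  if (is.null(tr)) .err("treeError", sprintf("no tree parsed from %s", path))
  validateTree(tr)
}

#' Validate a phylogenetic tree for use as an ASR guide
#'
#' @param tree an [ape::phylo].
#' @return the tree, invisibly checked: unique leaf names, finite
#'   non-negative branch lengths; a trifurcating root is flagged with a
#'   warning but accepted.
#' @export
validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) .err("treeError", "not a phylo object")
  if (anyDuplicated(tree$tip.label))
    .err("treeError",
         paste0("duplicated leaf names: ",
                paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                      collapse = ", ")))
  if (is.null(tree$edge.length))
    .err("treeError", "tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    .err("treeError", "branch lengths must be finite and non-negative")
  root <- ape::Ntip(tree) + 1L
  if (sum(tree$edge[, 1L] == root) > 2L)
    warning("tree has a trifurcating (unrooted-style) root; treating it as rooted",
            call. = FALSE)
  tree
}

#' Numeric support values from internal node labels
#'
#' @param tree an [ape::phylo].
#' @return numeric vector of length \code{tree$Nnode}; NA where the label is
#'   absent or non-numeric (named nodes of interest).
#' @export
nodeSupports <- function(tree) {
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(lab))
}

#' Check that tree leaves and alignment records pair up
#'
#' @param tree an [ape::phylo].
#' @param alignment a [ProteinAlignment-class].
#' @return invisibly TRUE; otherwise a pairing-error listing offenders.
#' @export
checkPairing <- function(tree, alignment) {
  tips <- tree$tip.label
  heads <- sequenceNames(alignment)
  only_tree <- setdiff(tips, heads)
  only_aln <- setdiff(heads, tips)
  if (length(only_tree) || length(only_aln))
    .err("pairingError",
         paste0("leaf/record mismatch;",
                if (length(only_tree))
                  paste0(" tree-only: ", paste(only_tree, collapse = ", ")),
                if (length(only_aln))
                  paste0(" alignment-only: ", paste(only_aln, collapse = ", "))))
  invisible(TRUE)
}

#' Number of non-gap characters in a gapped sequence
#'
#' @param seq gapped sequence string (vectorized).
#' @return integer count(s) of characters other than \code{"-"}.
#' @examples
#' ungappedLength("A-C-")  # 2
#' @export
ungappedLength <- function(seq) {
  nchar(seq) - nchar(gsub("[^-]", "", seq))
}

#' Read a replicate-reconstruction FASTA
#'
#' A reconstruction set is a FASTA of equally long gapped sequences, all
#' reconstructed at the same node/threshold from reduced replicate datasets.
#'
#' @param path FASTA file path.
#' @param nodeId,gapThreshold metadata to attach.
#' @return A [ReconstructionSet-class].
#' @export
readReconstructionSet <- function(path, nodeId = "root", gapThreshold = NA_real_) {
  aln <- readFastaAlignment(path)
  new("ReconstructionSet", nodeId = nodeId, gapThreshold = gapThreshold,
      sequences = alignmentStrings(aln))
}
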