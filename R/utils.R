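# Shared constants and classed error conditions.

# Residue ordering of the published WAG table (PAML convention). All rate
# matrices, frequency vectors and posterior matrices in this package index
# residues in this order; never reorder silently.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Alphabetical one-letter order, used only for deterministic tie-breaking.
AA_ALPHA <- sort(AA_ORDER)

GAP_CHAR <- "-"
UNKNOWN_CHAR <- "X"

# Recognized gene tokens of the header convention gene_domain_phylum_Accession.
GENE_TOKENS <- c("FtsY", "Ffh", "FlhA", "SS", "SecY")
DOMAIN_TOKENS <- c("Bacteria", "Archaea")

# Residues inferred to have entered the canonical genetic code last.
LATE_RESIDUES <- c("C", "H", "F", "M", "Y", "W")

.err <- function(class, msg, ..., call. = sys.call(-1)) {
  cond <- structure(
    class = c(class, "srpAncestryError", "error", "condition"),
    list(message = msg, call = call., ...)
  )
  stop(cond)
}

.assertScalarNumber <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .err("validationError", sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

# Split a vector of equal-length sequence strings into a character matrix
# (rows = sequences, columns = alignment columns).
.seqsToMatrix <- function(seqs) {
  n <- nchar(seqs)
  if (length(unique(n)) != 1L)
    .err("alignmentError", "sequences have unequal lengths")
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

.matrixToSeqs <- function(m) {
  s <- apply(m, 1L, paste0, collapse = "")
  names(s) <- rownames(m)
  s
}
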