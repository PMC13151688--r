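# Shared internal helpers.

DNA_BASES <- c("A", "C", "G", "T")

# x * log2(x) with the 0 log 0 = 0 convention used throughout the map
# equation; accepts vectors.
plogp <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# IUPAC nucleotide code -> base set, taken from the Biostrings code map so
# the degenerate alphabet stays in sync with the field's convention.
iupac_sets <- function() {
  strsplit(Biostrings::IUPAC_CODE_MAP, "", fixed = TRUE)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing number", name), call. = FALSE)
  }
}

# Coerce promoter input (data.frame from extract_promoters, or a named
# character vector of sequences) to a named uppercase character vector.
as_promoter_seqs <- function(promoters) {
  if (is.data.frame(promoters)) {
    if (!all(c("gene_id", "sequence") %in% names(promoters))) {
      stop("promoter data.frame needs 'gene_id' and 'sequence' columns", call. = FALSE)
    }
    seqs <- toupper(promoters$sequence)
    names(seqs) <- promoters$gene_id
    return(seqs)
  }
  if (is.character(promoters)) {
    if (is.null(names(promoters))) {
      stop("promoter sequences must be named by gene id", call. = FALSE)
    }
    return(toupper(promoters))
  }
  stop("unsupported promoter input", call. = FALSE)
}
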