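# Residue conservation in multiple alignments: per-column information
# content (sequence-logo style) and mapping of DNA-contact positions from an
# ungapped reference frame onto alignment columns.

check_alignment <- function(msa) {
  stopifnot(is.character(msa), !is.null(names(msa)))
  if (length(msa) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(widths), collapse = ", "),
         call. = FALSE)
  }
  toupper(msa)
}

#' Per-column information content of an alignment
#'
#' Frequencies are computed over non-gap symbols; information content is
#' log2(alphabet_size) - H(freqs) in bits, optionally with the small-sample
#' correction e(n) = (alphabet_size - 1) / (2 ln2 n) subtracted (floored at
#' 0), and optionally scaled by the non-gap fraction. Gap-only columns carry
#' 0 bits.
#'
#' @param msa Named character vector of equal-length aligned sequences
#'   (gap character '-').
#' @param alphabet_size 20 for protein, 4 for nucleotide logos.
#' @param small_sample_correction Apply the e(n) correction (default FALSE).
#' @param gap_weighting Scale ic by (1 - gap_fraction) (default FALSE).
#' @return list with \code{profile} (data.frame \code{col},
#'   \code{gap_fraction}, \code{ic_bits}) and \code{freqs} (columns x
#'   residues frequency matrix over the residues observed).
#' @export
column_information_content <- function(msa, alphabet_size = 20L,
                                       small_sample_correction = FALSE,
                                       gap_weighting = FALSE) {
  msa <- check_alignment(msa)
  chars <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  n_cols <- ncol(chars)
  residues <- sort(setdiff(unique(as.vector(chars)), "-"))
  freqs <- matrix(0, nrow = n_cols, ncol = length(residues),
                  dimnames = list(NULL, residues))
  gap_fraction <- numeric(n_cols)
  ic <- numeric(n_cols)
  for (k in seq_len(n_cols)) {
    col <- chars[, k]
    nongap <- col[col != "-"]
    gap_fraction[k] <- 1 - length(nongap) / length(col)
    if (length(nongap) == 0L) next
    tab <- table(nongap) / length(nongap)
    freqs[k, names(tab)] <- as.numeric(tab)
    h <- -sum(plogp(as.numeric(tab)))
    val <- log2(alphabet_size) - h
    if (small_sample_correction) {
      val <- val - (alphabet_size - 1) / (2 * log(2) * length(nongap))
    }
    if (gap_weighting) val <- val * (1 - gap_fraction[k])
    ic[k] <- max(0, val)
  }
  list(profile = data.frame(col = seq_len(n_cols), gap_fraction = gap_fraction,
                            ic_bits = ic),
       freqs = freqs)
}

#' Map ungapped reference positions to alignment columns
#'
#' Reference position k is the k-th non-gap character of the reference row;
#' the mapping returns that character's alignment column. Annotated residue
#' letters are checked against the reference sequence.
#'
#' @param msa Named character vector of aligned sequences.
#' @param reference_id Row id of the reference sequence.
#' @param positions 1-based positions in the ungapped reference.
#' @param residues Optional expected letters at those positions.
#' @return data.frame with \code{position}, \code{column},
#'   \code{reference_residue}.
#' @export
map_reference_positions <- function(msa, reference_id, positions,
                                    residues = NULL) {
  msa <- check_alignment(msa)
  if (!reference_id %in% names(msa)) {
    stop("reference '", reference_id, "' not in alignment", call. = FALSE)
  }
  refchars <- strsplit(msa[[reference_id]], "", fixed = TRUE)[[1]]
  nongap_cols <- which(refchars != "-")
  if (any(positions < 1L | positions > length(nongap_cols))) {
    stop("position(s) outside the ungapped reference (length ",
         length(nongap_cols), ")", call. = FALSE)
  }
  cols <- nongap_cols[positions]
  ref_res <- refchars[cols]
  if (!is.null(residues)) {
    residues <- toupper(residues)
    bad <- which(ref_res != residues)
    if (length(bad)) {
      stop(sprintf("annotated residue '%s' at position %d does not match reference '%s'",
                   residues[bad[1]], positions[bad[1]], ref_res[bad[1]]),
           call. = FALSE)
    }
  }
  data.frame(position = positions, column = cols, reference_residue = ref_res,
             stringsAsFactors = FALSE)
}

#' Conservation report for annotated contact positions
#'
#' For each mapped column: the modal non-gap residue, the fraction of
#' non-gap rows matching the reference residue, and the column's
#' information content.
#'
#' @inheritParams map_reference_positions
#' @param alphabet_size Alphabet size for the information content.
#' @return data.frame with \code{position}, \code{column},
#'   \code{reference_residue}, \code{modal_residue},
#'   \code{fraction_matching_reference}, \code{ic_bits}.
#' @export
contact_conservation_report <- function(msa, reference_id, positions,
                                        residues = NULL, alphabet_size = 20L) {
  msa <- check_alignment(msa)
  mapping <- map_reference_positions(msa, reference_id, positions, residues)
  icc <- column_information_content(msa, alphabet_size = alphabet_size)
  chars <- do.call(rbind, strsplit(msa, "", fixed = TRUE))
  modal <- character(nrow(mapping))
  frac <- numeric(nrow(mapping))
  for (r in seq_len(nrow(mapping))) {
    col <- chars[, mapping$column[r]]
    nongap <- col[col != "-"]
    tab <- sort(table(nongap), decreasing = TRUE)
    modal[r] <- names(tab)[1]
    frac[r] <- mean(nongap == mapping$reference_residue[r])
  }
  cbind(mapping,
        data.frame(modal_residue = modal, fraction_matching_reference = frac,
                   ic_bits = icc$profile$ic_bits[mapping$column],
                   stringsAsFactors = FALSE))
}

#' Read an aligned FASTA as a named character vector
#'
#' @param path Aligned FASTA (protein or nucleotide; gaps '-').
#' @return Named character vector of aligned rows.
#' @export
read_alignment_fasta <- function(path) {
  aln <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(aln))
  names(out) <- sub("\\s.*$", "", names(aln))
  out
}
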