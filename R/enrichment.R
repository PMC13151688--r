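# Family-level motif enrichment: gene x TF-family promoter-hit indicators
# and one-sided Fisher tests of overrepresentation within communities.

#' Gene x TF-family promoter hit indicator matrix
#'
#' The indicator is 1 iff at least one hit from any motif of the family lies
#' in the gene's promoter. The universe (all scanned genes) is fixed across
#' families.
#'
#' @param hits Hit data.frame (from [scan_iupac()] or [scan_pwm()]) whose
#'   motif column is named \code{pattern} or \code{motif_id}.
#' @param motif_to_family Named character vector motif id -> family id.
#' @param universe Character vector of all scanned gene ids.
#' @return Binary integer matrix, genes (rows) x families (columns).
#' @export
gene_family_hit_matrix <- function(hits, motif_to_family, universe) {
  motif_col <- if ("motif_id" %in% names(hits)) "motif_id" else "pattern"
  families <- sort(unique(unname(motif_to_family)))
  mat <- matrix(0L, nrow = length(universe), ncol = length(families),
                dimnames = list(universe, families))
  if (nrow(hits) > 0L) {
    unmapped <- setdiff(unique(hits[[motif_col]]), names(motif_to_family))
    if (length(unmapped)) {
      stop("motif(s) without a family mapping: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    fam <- motif_to_family[hits[[motif_col]]]
    in_universe <- hits$seq_id %in% universe
    mat[cbind(hits$seq_id[in_universe], fam[in_universe])] <- 1L
  }
  mat
}

#' One-sided Fisher's exact test (enrichment)
#'
#' Upper-tail hypergeometric probability P(X >= a) for the 2x2 table
#' [[a, b], [c, d]]: population N = a+b+c+d, K = a+c successes, n = a+b
#' draws.
#'
#' @param a Community genes with a hit.
#' @param b Community genes without a hit.
#' @param c Outside genes with a hit.
#' @param d Outside genes without a hit.
#' @return The one-sided p-value.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("table cells must be nonnegative", call. = FALSE)
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Family enrichment per community
#'
#' One one-sided Fisher test per (community, family), with
#' Benjamini-Hochberg correction pooled across all tests. Families with no
#' hit anywhere in the universe are untestable and reported with NA
#' p/q-values. log2 proportion enrichment is
#' log2((a/(a+b)) / ((a+c)/N)), NA when a = 0.
#'
#' @param partition Named module labels (gene -> community), genes a subset
#'   of the hit-matrix universe.
#' @param hit_matrix Matrix from [gene_family_hit_matrix()].
#' @param q_max BH threshold reported in \code{significant_q} (default 0.01).
#' @param p_max Raw threshold reported in \code{significant_p} (default 0.05).
#' @return data.frame with community, family, the 2x2 cells, pvalue, qvalue,
#'   log2_enrichment and both significance flags, sorted by (qvalue, pvalue).
#' @export
community_family_enrichment <- function(partition, hit_matrix,
                                        q_max = 0.01, p_max = 0.05) {
  universe <- rownames(hit_matrix)
  unknown <- setdiff(names(partition), universe)
  if (length(unknown)) {
    stop("partition gene(s) outside the scanned universe: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  N <- length(universe)
  fam_total <- colSums(hit_matrix)
  communities <- sort(unique(unname(partition)))
  rows <- list()
  for (comm in communities) {
    members <- names(partition)[partition == comm]
    inside <- hit_matrix[members, , drop = FALSE]
    a <- colSums(inside)
    b <- length(members) - a
    c_ <- fam_total - a
    d <- N - length(members) - c_
    p <- ifelse(fam_total == 0, NA_real_,
                fisher_one_sided(a, b, c_, d))
    rows[[comm]] <- data.frame(
      community = comm, family = colnames(hit_matrix),
      a = a, b = b, c = c_, d = d, pvalue = p,
      log2_enrichment = ifelse(a == 0, NA_real_,
                               log2((a / (a + b)) / (fam_total / N))),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  testable <- !is.na(out$pvalue)
  out$qvalue <- NA_real_
  out$qvalue[testable] <- bh_qvalues(pmax(out$pvalue[testable], .Machine$double.xmin))
  out$significant_q <- !is.na(out$qvalue) & out$qvalue <= q_max
  out$significant_p <- !is.na(out$pvalue) & out$pvalue < p_max
  out <- out[order(out$qvalue, out$pvalue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
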