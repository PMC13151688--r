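# Expression quantification: median-of-ratios normalization, the
# fold-change/p-value differential expression filter, and 2^-ddCt qPCR
# relative quantification with SEM over biological replicates.

#' Median-of-ratios size factors
#'
#' The reference for gene i is its geometric mean across samples; genes with
#' any zero count are excluded from the reference set. The size factor of
#' sample j is the median over included genes of count / reference.
#'
#' @param counts Nonnegative integer matrix, genes x samples, with dimnames.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  included <- rowSums(counts == 0) == 0L
  if (!any(included)) {
    stop("no gene has nonzero counts in every sample; size factors undefined",
         call. = FALSE)
  }
  lc <- log(counts[included, , drop = FALSE])
  ref <- rowMeans(lc)
  sf <- exp(apply(lc - ref, 2, stats::median))
  stats::setNames(sf, colnames(counts))
}

#' Divide counts by size factors
#'
#' @param counts Genes x samples matrix.
#' @param sf Named size factors covering every sample.
#' @return Numeric matrix of normalized values.
#' @export
normalize_counts <- function(counts, sf) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("counts must have sample names", call. = FALSE)
  if (!all(colnames(counts) %in% names(sf))) {
    stop("size factors missing for sample(s): ",
         paste(setdiff(colnames(counts), names(sf)), collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2, sf[colnames(counts)], "/")
}

#' Fold-change / p-value differential expression filter
#'
#' log2 fold change of group means with a 0.5 pseudocount; per-gene p-value
#' from a two-sided Welch test on log2(normalized + 1). A gene is called
#' differentially expressed iff |log2fc| strictly exceeds
#' \code{fc_threshold} and p < \code{alpha}.
#'
#' @param normalized Normalized matrix from [normalize_counts()].
#' @param groups Named character vector sample -> condition label.
#' @param treated,control The two condition labels to contrast.
#' @param fc_threshold Strict |log2FC| threshold (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @return data.frame with \code{gene_id}, \code{log2fc}, \code{pvalue},
#'   \code{is_de}, \code{direction}.
#' @export
differential_expression <- function(normalized, groups,
                                    treated = "treated", control = "control",
                                    fc_threshold = 2, alpha = 0.05) {
  t_idx <- colnames(normalized) %in% names(groups)[groups == treated]
  c_idx <- colnames(normalized) %in% names(groups)[groups == control]
  if (sum(t_idx) < 2L || sum(c_idx) < 2L) {
    stop("each condition needs at least 2 samples", call. = FALSE)
  }
  mt <- rowMeans(normalized[, t_idx, drop = FALSE])
  mc <- rowMeans(normalized[, c_idx, drop = FALSE])
  log2fc <- log2((mt + 0.5) / (mc + 0.5))
  lx <- log2(normalized[, t_idx, drop = FALSE] + 1)
  ly <- log2(normalized[, c_idx, drop = FALSE] + 1)
  pvalue <- vapply(seq_len(nrow(normalized)), function(i) {
    x <- lx[i, ]; y <- ly[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    stats::t.test(x, y)$p.value
  }, 0)
  is_de <- abs(log2fc) > fc_threshold & pvalue < alpha
  data.frame(gene_id = rownames(normalized), log2fc = log2fc, pvalue = pvalue,
             is_de = is_de,
             direction = ifelse(!is_de, "none", ifelse(log2fc > 0, "up", "down")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled-variance two-sample Student t-test
#'
#' Two-tailed, df = n_x + n_y - 2. Zero pooled variance with equal means
#' returns t = 0, p = 1 (constant replicate degeneracy).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return list with \code{t}, \code{df}, \code{pvalue}.
#' @export
student_t_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("each group needs at least 2 values", call. = FALSE)
  df <- nx + ny - 2L
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(list(t = 0, df = df, pvalue = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, pvalue = 0))
  }
  t <- (mean(x) - mean(y)) / se
  list(t = t, df = df, pvalue = 2 * stats::pt(-abs(t), df))
}

#' qPCR relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged to one Cq per (gene, biological
#' replicate); reference genes are combined by the arithmetic mean of their
#' Cq. Per tissue, dCt = Cq_target - mean(Cq_references); ddCt of each
#' treated replicate subtracts the mean control dCt; the fold change rq is
#' the mean over treated replicates of 2^-ddCt, with SEM over those per-
#' replicate values and a pooled-variance two-tailed t-test on the dCt
#' values of the two conditions.
#'
#' @param records data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{role} ("target"/"reference"), \code{tissue}, \code{condition}
#'   ("control"/"treated"), \code{bio_rep}, \code{tech_rep}, \code{cq}.
#' @return data.frame with \code{gene_id}, \code{tissue}, \code{rq},
#'   \code{sem}, \code{pvalue}, \code{n_bio}.
#' @export
ddct_relative_expression <- function(records) {
  needed <- c("sample_id", "gene_id", "role", "tissue", "condition",
              "bio_rep", "tech_rep", "cq")
  if (!all(needed %in% names(records))) {
    stop("Cq table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$cq <= 0)) stop("Cq values must be positive", call. = FALSE)
  # average technical replicates
  agg <- stats::aggregate(cq ~ gene_id + role + tissue + condition + bio_rep,
                          data = records, FUN = mean)
  out <- list()
  for (tis in unique(agg$tissue)) {
    a <- agg[agg$tissue == tis, , drop = FALSE]
    refs <- a[a$role == "reference", , drop = FALSE]
    targets <- unique(a$gene_id[a$role == "target"])
    # mean reference Cq per (condition, bio_rep)
    key <- function(d) paste(d$condition, d$bio_rep)
    if (nrow(refs) == 0L) {
      stop("no reference gene measured in tissue '", tis, "'", call. = FALSE)
    }
    ref_cq <- tapply(refs$cq, key(refs), mean)
    for (g in targets) {
      tg <- a[a$gene_id == g & a$role == "target", , drop = FALSE]
      miss <- setdiff(unique(key(tg)), names(ref_cq))
      if (length(miss)) {
        stop("missing reference Cq for tissue '", tis, "', replicate(s) ",
             paste(miss, collapse = "; "), call. = FALSE)
      }
      dct <- tg$cq - as.numeric(ref_cq[key(tg)])
      ctrl <- dct[tg$condition == "control"]
      trt <- dct[tg$condition == "treated"]
      if (length(ctrl) < 2L || length(trt) < 2L) {
        stop("gene '", g, "' in tissue '", tis,
             "' needs >= 2 biological replicates per condition", call. = FALSE)
      }
      ddct <- trt - mean(ctrl)
      rq_rep <- 2^(-ddct)
      tt <- student_t_test(trt, ctrl)
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, tissue = tis, rq = mean(rq_rep),
        sem = stats::sd(rq_rep) / sqrt(length(rq_rep)),
        pvalue = tt$pvalue, n_bio = length(trt), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
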