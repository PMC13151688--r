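# Motif machinery: matrix parsing (JASPAR PFM / MEME minimal dialects),
# log-odds scoring, the exact score-distribution dynamic program behind
# match p-values, FIMO-style promoter scanning, IUPAC consensus conversion
# and mismatch-free degenerate scanning, and target-gene ranking.

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param probs w x 4 matrix of base probabilities, columns A, C, G, T; each
#'   row must sum to 1 (within 1e-9).
#' @param background Length-4 base background distribution.
#' @param pseudocount Pseudocount that was folded in when the probabilities
#'   were formed (recorded for provenance; no further smoothing happens
#'   downstream).
#' @return An object of class \code{coexreg_pwm}.
#' @export
new_pwm <- function(motif_id, probs, background = rep(0.25, 4), pseudocount = 0) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 4L, nrow(probs) >= 1L)
  colnames(probs) <- DNA_BASES
  if (any(probs < 0)) stop("negative probabilities in motif ", motif_id, call. = FALSE)
  if (any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("probability rows of motif ", motif_id, " do not sum to 1", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0)) {
    stop("background must be a probability vector over A,C,G,T", call. = FALSE)
  }
  structure(list(motif_id = motif_id, width = nrow(probs), probs = probs,
                 background = stats::setNames(as.numeric(background), DNA_BASES),
                 pseudocount = pseudocount),
            class = "coexreg_pwm")
}

#' @export
print.coexreg_pwm <- function(x, ...) {
  cat(sprintf("<PWM %s> width %d, consensus %s\n", x$motif_id, x$width,
              pwm_to_iupac(x)))
  invisible(x)
}

#' Parse motif matrices (JASPAR PFM or MEME minimal dialect)
#'
#' JASPAR count columns are converted to probabilities with pseudocount
#' smoothing, p = (count + pc * bg) / (total + pc); MEME letter-probability
#' rows are taken as given and renormalized through the same smoothing
#' (treating each row as a unit-total count vector). This is the single
#' smoothing point of the scanning stack: no further epsilon is added when
#' log-odds are formed.
#'
#' @param x Path to a motif file, or a character vector of its lines.
#' @param dialect One of \code{"jaspar_pfm"}, \code{"meme"}.
#' @param pseudocount Smoothing mass (default 0.01).
#' @param background Base background; for MEME input, a background record in
#'   the file takes precedence.
#' @return A named list of \code{coexreg_pwm} objects.
#' @export
parse_motif_matrix <- function(x, dialect = c("jaspar_pfm", "meme"),
                               pseudocount = 0.01,
                               background = rep(0.25, 4)) {
  dialect <- match.arg(dialect)
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "jaspar_pfm") {
    parse_jaspar_pfm(lines, pseudocount, background)
  } else {
    parse_meme_minimal(lines, pseudocount, background)
  }
}

smooth_counts <- function(counts, pseudocount, background) {
  # counts: w x 4; returns probability matrix with pseudocount folded in
  if (any(counts < 0)) stop("negative motif counts", call. = FALSE)
  totals <- rowSums(counts)
  if (any(totals <= 0) && pseudocount <= 0) {
    stop("empty motif column with zero pseudocount", call. = FALSE)
  }
  probs <- sweep(counts, 1, totals + pseudocount, "/") +
    outer(rep(pseudocount, nrow(counts)) / (totals + pseudocount), background)
  probs
}

parse_jaspar_pfm <- function(lines, pseudocount, background) {
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no '>' motif header found", call. = FALSE)
  bounds <- c(headers, length(lines) + 1L)
  out <- list()
  for (h in seq_along(headers)) {
    block <- lines[(bounds[h] + 1L):(bounds[h + 1L] - 1L)]
    id <- strsplit(sub("^>\\s*", "", lines[headers[h]]), "\\s+")[[1]][1]
    if (length(block) != 4L) {
      stop("motif ", id, ": expected 4 base rows, got ", length(block), call. = FALSE)
    }
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1]]
      if (toupper(parts[1]) %in% DNA_BASES) {
        base <- toupper(parts[1]); parts <- parts[-1]
      } else base <- NA_character_
      vals <- suppressWarnings(as.numeric(parts))
      if (anyNA(vals)) stop("motif ", id, ": unparseable count row", call. = FALSE)
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!anyNA(bases) && !identical(sort(bases), DNA_BASES)) {
      stop("motif ", id, ": base rows must cover A, C, G, T", call. = FALSE)
    }
    if (anyNA(bases)) bases <- DNA_BASES
    widths <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(widths)) != 1L) {
      stop("motif ", id, ": ragged count rows", call. = FALSE)
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(counts) <- bases
    counts <- t(counts[DNA_BASES, , drop = FALSE])  # -> w x 4
    out[[id]] <- new_pwm(id, smooth_counts(counts, pseudocount, background),
                         background, pseudocount)
  }
  out
}

parse_meme_minimal <- function(lines, pseudocount, background) {
  bgline <- grep("^Background letter frequencies", lines)
  if (length(bgline) == 1L && bgline < length(lines)) {
    parts <- strsplit(trimws(lines[bgline + 1L]), "\\s+")[[1]]
    if (length(parts) >= 8L) {
      vals <- suppressWarnings(as.numeric(parts[c(FALSE, TRUE)]))
      keys <- toupper(parts[c(TRUE, FALSE)])
      if (!anyNA(vals) && all(DNA_BASES %in% keys)) {
        background <- vals[match(DNA_BASES, keys)]
        background <- background / sum(background)
      }
    }
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no 'MOTIF' record found", call. = FALSE)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    lp <- s + grep("^letter-probability matrix", lines[(s + 1L):length(lines)])[1]
    if (is.na(lp)) stop("motif ", id, ": no letter-probability matrix", call. = FALSE)
    w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[lp]))
    if (is.na(w)) stop("motif ", id, ": cannot read motif width", call. = FALSE)
    block <- lines[(lp + 1L):(lp + w)]
    rows <- lapply(strsplit(trimws(block), "\\s+"), function(p) {
      vals <- suppressWarnings(as.numeric(p))
      if (anyNA(vals) || length(vals) != 4L) {
        stop("motif ", id, ": probability row must have 4 entries", call. = FALSE)
      }
      vals
    })
    counts <- do.call(rbind, rows)
    counts <- counts / rowSums(counts)  # rows taken as-is, renormalized
    out[[id]] <- new_pwm(id, smooth_counts(counts, pseudocount, background),
                         background, pseudocount)
  }
  out
}

#' Log-odds scoring matrix of a PWM
#'
#' Scores are log2(p / background) in bits; integer scores at
#' \code{scale} units per bit support the exact p-value dynamic program.
#' Probabilities must be strictly positive (parse with a pseudocount).
#'
#' @param pwm A \code{coexreg_pwm}.
#' @param scale Integer granularity, units per bit (default 1000).
#' @return list with \code{motif_id}, \code{width}, \code{scores} (bits),
#'   \code{int_scores}, \code{scale}, \code{background}.
#' @export
make_log_odds <- function(pwm, scale = 1000L) {
  if (any(pwm$background <= 0)) stop("background entries must be positive", call. = FALSE)
  if (any(pwm$probs <= 0)) {
    stop("motif ", pwm$motif_id,
         ": zero probability entries; re-parse with a positive pseudocount",
         call. = FALSE)
  }
  scores <- sweep(log2(pwm$probs), 2, log2(pwm$background), "-")
  structure(list(motif_id = pwm$motif_id, width = pwm$width, scores = scores,
                 int_scores = round(scores * scale), scale = as.integer(scale),
                 background = pwm$background),
            class = "coexreg_lom")
}

#' Exact distribution of the integer log-odds score under the background
#'
#' Convolution dynamic program over motif positions: the probability mass
#' function of the total integer score of a random background word. Match
#' p-values are upper tails of this distribution.
#'
#' @param lom Log-odds matrix from [make_log_odds()].
#' @param background Base background (defaults to the one stored in `lom`).
#' @return list with \code{pmf}, \code{min_score}, \code{max_score}, and the
#'   precomputed upper-\code{tail} vector aligned with \code{pmf}.
#' @export
score_distribution <- function(lom, background = lom$background) {
  isc <- lom$int_scores
  stopifnot(nrow(isc) >= 1L)
  bg <- as.numeric(background)
  v <- 1
  lo <- 0L
  for (k in seq_len(nrow(isc))) {
    col <- as.integer(isc[k, ])
    nlo <- lo + min(col)
    nhi <- (lo + length(v) - 1L) + max(col)
    nv <- numeric(nhi - nlo + 1L)
    for (a in 1:4) {
      off <- lo + col[a] - nlo
      idx <- off + seq_along(v)
      nv[idx] <- nv[idx] + bg[a] * v
    }
    v <- nv
    lo <- nlo
  }
  tail <- rev(cumsum(rev(v)))
  list(pmf = v, min_score = lo, max_score = lo + length(v) - 1L, tail = tail)
}

#' Upper-tail p-value of integer scores
#'
#' @param dist Distribution from [score_distribution()].
#' @param s Integer score(s).
#' @return P(score >= s) under the background, per element.
#' @export
score_pvalue <- function(dist, s) {
  idx <- s - dist$min_score + 1L
  p <- numeric(length(s))
  p[idx <= 0L] <- 1
  inside <- idx >= 1L & idx <= length(dist$tail)
  p[inside] <- dist$tail[idx[inside]]
  # idx beyond max_score stays 0
  p
}

# reverse-complemented integer score matrix: score of the - strand window
# read 5'->3' equals scanning the stored sequence with this matrix
rc_int_scores <- function(isc) {
  isc[rev(seq_len(nrow(isc))), 4:1, drop = FALSE]
}

#' Scan promoters with a PWM, reporting exact p-values
#'
#' Every width-w window on the + strand (and, when \code{both_strands}, the
#' reverse-complemented window scored for the - strand) whose exact
#' background p-value is at or below \code{pvalue_max} is reported. Windows
#' containing N are skipped. Benjamini-Hochberg q-values are assigned per
#' motif over all tested windows of this scan.
#'
#' @param promoters data.frame from [extract_promoters()] or a named
#'   character vector of sequences.
#' @param pwm A \code{coexreg_pwm}.
#' @param pvalue_max Report hits with p-value <= this (default 1e-5).
#' @param both_strands Scan the - strand too (default TRUE).
#' @param scale Integer score granularity per bit.
#' @return data.frame with columns \code{motif_id}, \code{seq_id},
#'   \code{start0}, \code{strand}, \code{matched}, \code{score_bits},
#'   \code{pvalue}, \code{qvalue}; the number of tested windows is attached
#'   as attribute \code{n_tested}.
#' @export
scan_pwm <- function(promoters, pwm, pvalue_max = 1e-5, both_strands = TRUE,
                     scale = 1000L) {
  seqs <- as_promoter_seqs(promoters)
  lom <- make_log_odds(pwm, scale = scale)
  dist <- score_distribution(lom)
  w <- lom$width
  # smallest integer score whose tail is within the threshold
  ok <- dist$tail <= pvalue_max
  min_hit_score <- if (any(ok)) dist$min_score + which(ok)[1] - 1L else NA_integer_

  mats <- list("+" = lom$int_scores)
  if (both_strands) mats[["-"]] <- rc_int_scores(lom$int_scores)

  hit_seq <- character(); hit_start <- integer(); hit_strand <- character()
  hit_score <- integer(); hit_matched <- character()
  score_counts <- integer(length(dist$tail))  # tested windows per integer score
  for (gi in seq_along(seqs)) {
    codes <- match(strsplit(seqs[[gi]], "", fixed = TRUE)[[1]], DNA_BASES)
    L <- length(codes)
    if (L < w) next
    nwin <- L - w + 1L
    for (strand in names(mats)) {
      isc <- mats[[strand]]
      S <- numeric(nwin)
      for (k in seq_len(w)) S <- S + isc[k, codes[k:(k + nwin - 1L)]]
      tested <- !is.na(S)
      Si <- as.integer(S[tested]) - dist$min_score + 1L
      score_counts <- score_counts + tabulate(Si, nbins = length(score_counts))
      if (is.na(min_hit_score)) next
      at <- which(tested & S >= min_hit_score)
      if (length(at)) {
        m <- substr(rep(seqs[[gi]], length(at)), at, at + w - 1L)
        if (strand == "-") m <- reverse_complement(m)
        hit_seq <- c(hit_seq, rep(names(seqs)[gi], length(at)))
        hit_start <- c(hit_start, at - 1L)
        hit_strand <- c(hit_strand, rep(strand, length(at)))
        hit_score <- c(hit_score, as.integer(S[at]))
        hit_matched <- c(hit_matched, m)
      }
    }
  }
  n_tested <- sum(score_counts)
  out <- data.frame(motif_id = rep(pwm$motif_id, length(hit_seq)),
                    seq_id = hit_seq, start0 = hit_start, strand = hit_strand,
                    matched = hit_matched,
                    score_bits = hit_score / lom$scale,
                    pvalue = score_pvalue(dist, hit_score),
                    stringsAsFactors = FALSE)
  out$qvalue <- grouped_bh_qvalues(hit_score, dist, score_counts, n_tested)
  attr(out, "n_tested") <- n_tested
  out[order(out$pvalue, out$seq_id, out$start0), , drop = FALSE]
}

# BH q-values over all tested windows, computed exactly from the tally of
# windows per distinct integer score (windows with equal score share a
# p-value, so ranks only matter at group granularity).
grouped_bh_qvalues <- function(hit_scores, dist, score_counts, n_tested) {
  if (length(hit_scores) == 0L) return(numeric())
  present <- which(score_counts > 0L)          # ascending score
  present <- rev(present)                      # descending score = ascending p
  pvals <- dist$tail[present]
  cum_n <- cumsum(score_counts[present])       # rank of the last tied window
  raw <- pvals * n_tested / cum_n
  q <- pmin(1, rev(cummin(rev(raw))))
  q[match(hit_scores - dist$min_score + 1L, present)]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment with an explicit family size \code{m}, which may exceed
#' the number of supplied p-values (untested members are assumed
#' non-significant).
#'
#' @param pvalues p-values in (0, 1].
#' @param m Family size (default: number of p-values supplied).
#' @return q-values in input order, capped at 1.
#' @export
bh_qvalues <- function(pvalues, m = length(pvalues)) {
  if (any(pvalues <= 0 | pvalues > 1 | is.na(pvalues))) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(pvalues)) stop("m must be >= length(pvalues)", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH", n = m)
}

iupac_code_of <- local({
  map <- NULL
  function(base_set) {
    if (is.null(map)) {
      codes <- Biostrings::IUPAC_CODE_MAP
      map <<- stats::setNames(names(codes), unname(codes))
    }
    key <- paste(sort(base_set), collapse = "")
    code <- map[[key]]
    if (is.null(code)) stop("no IUPAC code for base set ", key, call. = FALSE)
    code
  }
})

#' Convert a PWM to an IUPAC consensus pattern
#'
#' Per column, bases with probability at or above \code{include_threshold}
#' form the degenerate set; an empty set falls back to the most probable
#' base.
#'
#' @param pwm A \code{coexreg_pwm}.
#' @param include_threshold Inclusion threshold in (0, 1] (default 0.25).
#' @return Single IUPAC string of the motif's width.
#' @export
pwm_to_iupac <- function(pwm, include_threshold = 0.25) {
  stopifnot(include_threshold > 0, include_threshold <= 1)
  codes <- apply(pwm$probs, 1, function(row) {
    set <- DNA_BASES[row >= include_threshold]
    if (length(set) == 0L) set <- DNA_BASES[which.max(row)]
    iupac_code_of(set)
  })
  paste(codes, collapse = "")
}

valid_iupac <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  all(chars %in% names(Biostrings::IUPAC_CODE_MAP))
}

#' Reverse complement of an IUPAC pattern
#'
#' @param pattern IUPAC string.
#' @return Reverse-complemented pattern (degenerate codes complemented:
#'   R<->Y, K<->M, B<->V, D<->H; S, W, N self-complementary).
#' @export
revcomp_iupac <- function(pattern) {
  pattern <- toupper(pattern)
  if (!valid_iupac(pattern)) stop("invalid IUPAC pattern: ", pattern, call. = FALSE)
  reverse_complement(pattern)
}

iupac_regex <- function(pattern) {
  sets <- iupac_sets()
  classes <- vapply(strsplit(pattern, "", fixed = TRUE)[[1]], function(ch) {
    bases <- sets[[ch]]
    if (ch == "N") bases <- c(bases, "N")  # only fully degenerate N matches an unknown base
    paste0("[", paste(bases, collapse = ""), "]")
  }, "")
  paste(classes, collapse = "")
}

#' Mismatch-free degenerate scan of promoters
#'
#' Exact set-membership matching of an IUPAC pattern at every offset, on
#' both strands by default (the - strand is found by matching the
#' reverse-complemented pattern against the stored sequence). An ambiguous
#' sequence base N matches only a fully degenerate pattern position N. Hits
#' carry score = pattern width and p/q-values of 1 (not applicable).
#'
#' @param promoters data.frame from [extract_promoters()] or a named
#'   character vector of sequences.
#' @param pattern IUPAC string.
#' @param both_strands Scan the - strand too (default TRUE).
#' @return data.frame with columns \code{pattern}, \code{seq_id},
#'   \code{start0}, \code{strand}, \code{matched}, \code{score},
#'   \code{pvalue}, \code{qvalue}.
#' @export
scan_iupac <- function(promoters, pattern, both_strands = TRUE) {
  pattern <- toupper(pattern)
  if (!valid_iupac(pattern)) stop("invalid IUPAC pattern: ", pattern, call. = FALSE)
  seqs <- as_promoter_seqs(promoters)
  w <- nchar(pattern)
  queries <- list("+" = pattern)
  if (both_strands) queries[["-"]] <- revcomp_iupac(pattern)
  rows <- list()
  for (strand in names(queries)) {
    rx <- paste0("(?=", iupac_regex(queries[[strand]]), ")")
    m <- gregexpr(rx, seqs, perl = TRUE)
    for (gi in seq_along(seqs)) {
      at <- m[[gi]]
      at <- at[at > 0L]
      if (length(at) == 0L) next
      matched <- substr(rep(seqs[[gi]], length(at)), at, at + w - 1L)
      if (strand == "-") matched <- reverse_complement(matched)
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = pattern, seq_id = names(seqs)[gi], start0 = at - 1L,
        strand = strand, matched = matched, score = w,
        pvalue = 1, qvalue = 1, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pattern = character(), seq_id = character(),
                      start0 = integer(), strand = character(),
                      matched = character(), score = integer(),
                      pvalue = numeric(), qvalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$seq_id, out$start0, out$strand), , drop = FALSE]
}

#' Example G-box position weight matrix
#'
#' A 10-column bHLH-style matrix: the palindromic G-box core CACGTG
#' (positions 3-8) at probability \code{core_prob}, flanked by the softer
#' consensus bases of ACCACGTGGT at \code{flank_prob}. The width matters:
#' a bare 6-bp core cannot reach match p-values below 4^-6 ~ 2.4e-4, so
#' scanning at the conventional 1e-5 threshold requires the flanking
#' columns, as with the ~10-bp bHLH matrices in motif databases.
#'
#' @param core_prob Probability of the consensus base in core columns.
#' @param flank_prob Probability of the consensus base in flank columns.
#' @return A \code{coexreg_pwm}.
#' @export
gbox_pwm <- function(core_prob = 0.97, flank_prob = 0.8) {
  consensus <- strsplit("ACCACGTGGT", "", fixed = TRUE)[[1]]
  conc <- c(rep(flank_prob, 2), rep(core_prob, 6), rep(flank_prob, 2))
  probs <- matrix((1 - conc) / 3, nrow = 10, ncol = 4,
                  dimnames = list(NULL, DNA_BASES))
  probs[cbind(1:10, match(consensus, DNA_BASES))] <- conc
  new_pwm("Gbox10", probs, pseudocount = 0)
}

#' Rank candidate target genes by best hit significance
#'
#' Per gene, the minimal p-value over its hits and the minimal q-value;
#' genes are ordered ascending by (best p, best q, gene id). Genes without
#' hits are absent.
#'
#' @param hits Hit data.frame from [scan_pwm()] (or concatenated scans),
#'   with \code{seq_id}, \code{pvalue}, \code{qvalue} columns.
#' @return data.frame with \code{gene_id}, \code{best_pvalue},
#'   \code{best_qvalue}, ordered by rank.
#' @export
rank_target_genes <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(gene_id = character(), best_pvalue = numeric(),
                      best_qvalue = numeric(), stringsAsFactors = FALSE))
  }
  by_gene <- split(hits[, c("pvalue", "qvalue")], hits$seq_id)
  out <- data.frame(gene_id = names(by_gene),
                    best_pvalue = vapply(by_gene, function(d) min(d$pvalue), 0),
                    best_qvalue = vapply(by_gene, function(d) min(d$qvalue), 0),
                    stringsAsFactors = FALSE)
  out <- out[order(out$best_pvalue, out$best_qvalue, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
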