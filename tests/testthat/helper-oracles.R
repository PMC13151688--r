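# Independent oracles and fixture builders used across the suite. These
# deliberately avoid the package's own code paths: enumeration, closed
# forms, and naive position-wise matching.

# All set partitions of n items as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(i, maxv, rgs) {
    if (i > n) {
      out[[length(out) + 1L]] <<- rgs
      return(invisible())
    }
    for (v in 1:(maxv + 1L)) {
      rgs[i] <- v
      rec(i + 1L, max(maxv, v), rgs)
    }
  }
  rec(1L, 0L, integer(n))
  out
}

# Exhaustive enumeration of all 4^w words: integer scores and probabilities.
enumerate_words <- function(int_scores, background) {
  sc <- 0
  pr <- 1
  for (k in seq_len(nrow(int_scores))) {
    sc <- as.vector(outer(sc, int_scores[k, ], "+"))
    pr <- as.vector(outer(pr, background, "*"))
  }
  list(score = sc, prob = pr)
}

# Random smoothed PWM of the given width.
random_pwm <- function(width, pseudocount = 0.01) {
  counts <- matrix(stats::rgamma(4 * width, shape = 0.8) * 50, ncol = 4)
  probs <- sweep(counts + pseudocount * 0.25, 1, rowSums(counts) + pseudocount, "/")
  new_pwm(paste0("rnd", width), probs, pseudocount = pseudocount)
}

# Naive position-wise set-membership matcher for IUPAC patterns (one
# strand). A sequence N matches only a pattern N.
IUPAC_EXPANSION <- c(A = "A", C = "C", G = "G", T = "T",
                     R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                     B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGTN")
IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

brute_iupac_offsets <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- length(pat)
  L <- length(chars)
  if (L < w) return(integer())
  ok <- rep(TRUE, L - w + 1L)
  for (k in seq_len(w)) {
    allowed <- strsplit(IUPAC_EXPANSION[[pat[k]]], "", fixed = TRUE)[[1]]
    ok <- ok & chars[k:(k + L - w)] %in% allowed
  }
  which(ok) - 1L
}

brute_revcomp_iupac <- function(pattern) {
  chars <- rev(strsplit(pattern, "", fixed = TRUE)[[1]])
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

# Edge list of a clique over labelled nodes.
clique_edges <- function(n, prefix, weight = 1) {
  pairs <- t(utils::combn(paste0(prefix, seq_len(n)), 2))
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], weight = weight,
             stringsAsFactors = FALSE)
}

# Random connected-ish undirected graph with every node incident to an edge.
random_small_graph <- function(n, p = 0.45) {
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    if (all(colSums(m) + rowSums(m) > 0)) break
  }
  idx <- which(m, arr.ind = TRUE)
  weighted_graph(data.frame(gene_a = paste0("n", idx[, 1]),
                            gene_b = paste0("n", idx[, 2]),
                            weight = round(stats::runif(nrow(idx), 0.5, 2), 3),
                            stringsAsFactors = FALSE))
}

# Closed-form one-sided hypergeometric tail by explicit term summation.
hyper_tail_sum <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  ks <- max(a, 0):min(K, n)
  if (length(ks) == 0L || a > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Hand-rolled BH step-up formula, independent of p.adjust.
bh_by_hand <- function(p, m = length(p)) {
  o <- order(p)
  ranked <- p[o] * m / seq_along(p)
  q <- rev(cummin(rev(ranked)))
  pmin(1, q)[order(o)]
}

# Minimal GFF3 content for a set of gene rows.
gff3_lines <- function(rows) {
  c("##gff-version 3", rows)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
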