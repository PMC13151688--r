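# Motif parsing, log-odds scoring, exact p-values, degenerate scanning and
# target ranking.

test_that("JASPAR counts become probabilities; malformed rows error", {
  txt <- c(">M1 test",
           "A [10  0  5 ]",
           "C [ 0 10  5 ]",
           "G [ 0  0  0 ]",
           "T [ 0  0  0 ]")
  pwms <- parse_motif_matrix(txt, "jaspar_pfm", pseudocount = 0)
  expect_equal(pwms$M1$probs[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(pwms$M1$probs[3, ], c(A = 0.5, C = 0.5, G = 0, T = 0))
  expect_equal(pwms$M1$width, 3L)
  # with pseudocount pc: p = (count + pc*bg) / (total + pc)
  sm <- parse_motif_matrix(txt, "jaspar_pfm", pseudocount = 0.4)
  expect_equal(unname(sm$M1$probs[1, "A"]), (10 + 0.4 * 0.25) / 10.4)
  expect_error(parse_motif_matrix(c(">M2", "A [1]", "C [1]", "G [1]"),
                                  "jaspar_pfm"), "4 base rows")
  neg <- c(">M3", "A [ -1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]")
  expect_error(parse_motif_matrix(neg, "jaspar_pfm"), "negative")
})

test_that("MEME minimal blocks parse with width and background", {
  txt <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "Background letter frequencies",
           "A 0.3 C 0.2 G 0.2 T 0.3", "",
           "MOTIF MX box",
           "letter-probability matrix: alength= 4 w= 6 nsites= 20 E= 0",
           rep(" 0.970000 0.010000 0.010000 0.010000", 6))
  pwms <- parse_motif_matrix(txt, "meme", pseudocount = 0)
  expect_equal(pwms$MX$width, 6L)
  expect_equal(unname(pwms$MX$background), c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(pwms$MX$probs[1, 1]), 0.97)
  bad <- c("MOTIF MY", "letter-probability matrix: alength= 4 w= 1",
           " 0.5 0.5 0.0")
  expect_error(parse_motif_matrix(bad, "meme"), "4 entries")
})

test_that("log-odds scores follow log2(p/bg)", {
  probs <- matrix(c(0.5, 0.25, 0.125, 0.125), 1, 4)
  lom <- make_log_odds(new_pwm("m", probs))
  expect_equal(unname(lom$scores[1, ]), c(1, 0, -1, -1))
  expect_equal(unname(lom$int_scores[1, ]), c(1000, 0, -1000, -1000))
  flat <- make_log_odds(new_pwm("f", matrix(0.25, 2, 4)))
  expect_true(all(flat$scores == 0))
  zero <- new_pwm("z", matrix(c(1, 0, 0, 0), 1, 4))
  expect_error(make_log_odds(zero), "pseudocount")
})

test_that("score distribution matches single-column and independence closed forms", {
  lom1 <- list(int_scores = matrix(c(2000L, 0L, 0L, 0L), 1, 4),
               background = rep(0.25, 4))
  d1 <- score_distribution(lom1)
  expect_equal(score_pvalue(d1, 2000L), 0.25)
  expect_equal(score_pvalue(d1, d1$min_score), 1)
  lom2 <- list(int_scores = matrix(c(2000L, 0L, 0L, 0L), 2, 4, byrow = TRUE),
               background = rep(0.25, 4))
  d2 <- score_distribution(lom2)
  expect_equal(score_pvalue(d2, 4000L), 1 / 16)
})

test_that("DP upper tails equal exhaustive word enumeration", {
  set.seed(101)
  for (i in 1:8) {
    pwm <- random_pwm(sample(1:8, 1))
    lom <- make_log_odds(pwm)
    d <- score_distribution(lom)
    words <- enumerate_words(lom$int_scores, pwm$background)
    for (s in sample(unique(words$score), min(15, length(unique(words$score))))) {
      expect_lt(abs(sum(words$prob[words$score >= s]) - score_pvalue(d, s)), 1e-12)
    }
    # monotone non-increasing tail, p(min_score) = 1
    expect_true(all(diff(d$tail) <= 1e-15))
    expect_equal(d$tail[1], 1)
  }
})

test_that("PWM scanning finds planted sites with enumeration-exact p-values", {
  core <- "CACGTG"
  probs <- matrix(0.01, 6, 4)
  probs[cbind(1:6, match(strsplit(core, "")[[1]], c("A", "C", "G", "T")))] <- 0.97
  pwm <- new_pwm("gbox", probs / rowSums(probs))
  set.seed(7)
  prom <- c(pX = paste0(random_dna(40), core, random_dna(40)))
  hits <- scan_pwm(prom, pwm, pvalue_max = 1e-3)
  planted <- hits[hits$start0 == 40L, ]
  # palindromic consensus: + and - hits at the same interval, equal score
  expect_setequal(planted$strand, c("+", "-"))
  expect_equal(length(unique(planted$score_bits)), 1L)
  lom <- make_log_odds(pwm)
  words <- enumerate_words(lom$int_scores, pwm$background)
  smax <- max(words$score)
  expect_equal(planted$pvalue[1], sum(words$prob[words$score >= smax]))
  # windows containing N are skipped
  nh <- scan_pwm(c(p = "CACNTG"), pwm, pvalue_max = 1)
  expect_equal(nrow(nh), 0L)
  expect_equal(attr(nh, "n_tested"), 0L)
})

test_that("both-strand hit sets are invariant under reverse-complementing promoters", {
  set.seed(12)
  pwm <- random_pwm(6)
  seqs <- c(g1 = random_dna(300), g2 = random_dna(300))
  fwd <- scan_pwm(seqs, pwm, pvalue_max = 0.01)
  rc <- vapply(seqs, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))), "")
  rev <- scan_pwm(rc, pwm, pvalue_max = 0.01)
  # offsets mirror, strands swap, scores preserved
  key_fwd <- sort(paste(fwd$seq_id, fwd$start0, fwd$strand, round(fwd$score_bits, 6)))
  key_rev <- sort(paste(rev$seq_id, 300 - 6 - rev$start0,
                        ifelse(rev$strand == "+", "-", "+"),
                        round(rev$score_bits, 6)))
  expect_equal(key_fwd, key_rev)
})

test_that("BH q-values follow the step-up formula with explicit family size", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_qvalues(0.2, m = 1), 0.2)
  expect_equal(bh_qvalues(rep(1, 4)), rep(1, 4))
  set.seed(5)
  p <- runif(40)
  expect_equal(bh_qvalues(p, m = 100), bh_by_hand(p, m = 100))
  expect_error(bh_qvalues(c(0.1, 0)), "0, 1")
  # scan q-values against the hand formula applied to all tested windows
  pwm <- random_pwm(5)
  seqs <- c(s1 = random_dna(120), s2 = random_dna(150))
  hits <- scan_pwm(seqs, pwm, pvalue_max = 1)  # keep every window
  expect_equal(hits$qvalue, bh_by_hand(hits$pvalue), tolerance = 1e-12)
})

test_that("IUPAC conversion uses the inclusion threshold with argmax fallback", {
  pwm <- new_pwm("t", rbind(c(1, 0, 0, 0),
                            c(0.5, 0, 0, 0.5),
                            c(0.25, 0.25, 0.25, 0.25),
                            c(0.2, 0.4, 0.2, 0.2)))
  expect_equal(pwm_to_iupac(pwm), "AWNC")
  # high threshold forces the argmax fallback
  expect_equal(pwm_to_iupac(pwm, include_threshold = 0.9), "AAAC")
})

test_that("IUPAC reverse complement maps codes correctly", {
  expect_equal(revcomp_iupac("CANNTG"), "CANNTG")
  expect_equal(revcomp_iupac("R"), "Y")
  expect_equal(revcomp_iupac("TGW"), "WCA")
  expect_error(revcomp_iupac("CAX"), "invalid")
})

test_that("degenerate scanning matches examples and reports both strands", {
  h <- scan_iupac(c(p = "ACACGTGA"), "CANNTG")
  expect_equal(sort(paste(h$start0, h$strand)), c("1 +", "1 -"))
  expect_equal(nrow(scan_iupac(c(p = "CACGAG"), "CACGTG")), 0L)
  # a consensus drawn from argmax bases always matches at offset 0
  set.seed(31)
  for (i in 1:20) {
    pwm <- random_pwm(sample(3:8, 1))
    consensus <- paste(c("A", "C", "G", "T")[apply(pwm$probs, 1, which.max)],
                       collapse = "")
    pat <- pwm_to_iupac(pwm)
    h <- scan_iupac(stats::setNames(consensus, "c"), pat)
    expect_true(any(h$start0 == 0L & h$strand == "+"))
  }
})

test_that("degenerate scanning equals the brute-force membership oracle", {
  set.seed(77)
  codes <- names(IUPAC_EXPANSION)
  for (i in 1:40) {
    w <- sample(3:8, 1)
    pat <- paste(sample(codes, w, replace = TRUE,
                        prob = c(rep(4, 4), rep(1, 11))), collapse = "")
    s <- random_dna(400)
    hits <- scan_iupac(stats::setNames(s, "s"), pat)
    expect_equal(sort(hits$start0[hits$strand == "+"]),
                 sort(brute_iupac_offsets(s, pat)))
    expect_equal(sort(hits$start0[hits$strand == "-"]),
                 sort(brute_iupac_offsets(s, brute_revcomp_iupac(pat))))
  }
})

test_that("target ranking orders genes by best p, then q, then id", {
  hits <- data.frame(seq_id = c("G2", "G1", "G3", "G3"),
                     pvalue = c(1e-6, 1e-7, 1e-6, 1e-2),
                     qvalue = c(0.02, 0.01, 0.01, 0.5),
                     stringsAsFactors = FALSE)
  r <- rank_target_genes(hits)
  expect_equal(r$gene_id, c("G1", "G3", "G2"))
  expect_equal(r$best_pvalue, c(1e-7, 1e-6, 1e-6))
  expect_equal(nrow(rank_target_genes(hits[0, ])), 0L)
})
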