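# Median-of-ratios normalization, the DE filter, and ddCt quantification.

test_that("size factors follow the median-of-ratios formula", {
  counts <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
                   dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(size_factors_median_of_ratios(counts), c(s1 = 1, s2 = 1))

  doubled <- counts
  doubled[, 2] <- 2 * counts[, 1]
  sf <- size_factors_median_of_ratios(doubled)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # genes with a zero count are excluded from the reference set
  with_zero <- rbind(doubled, gz = c(0, 100))
  expect_equal(size_factors_median_of_ratios(with_zero), sf)

  all_zero <- matrix(c(0, 5, 3, 0), 2, 2,
                     dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors_median_of_ratios(all_zero), "no gene")

  # equivariance: scaling one sample scales its factor
  scaled <- doubled
  scaled[, 1] <- scaled[, 1] * 5
  expect_equal(unname(size_factors_median_of_ratios(scaled)),
               unname(sf * c(5, 1)) / sqrt(5))  # up to the common rescale
})

test_that("normalization divides by per-sample factors", {
  counts <- matrix(c(10, 0, 4, 6), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  norm <- normalize_counts(counts, c(s1 = 2, s2 = 1))
  expect_equal(norm["a", "s1"], 5)
  expect_equal(norm["b", "s1"], 0)
  expect_equal(norm[, "s2"], counts[, "s2"])
  expect_error(normalize_counts(counts, c(s1 = 2)), "s2")
})

test_that("the DE filter applies strict thresholds with direction labels", {
  # means chosen so |log2fc| is exactly 2 for gene 'edge'
  norm <- rbind(flat = c(5, 5, 5, 5),
                edge = c(1.5, 1.5, 7.5, 7.5),
                up = c(1, 1.4, 60, 63),
                down = c(60, 63, 1, 1.4))
  colnames(norm) <- paste0("s", 1:4)
  groups <- stats::setNames(rep(c("control", "treated"), each = 2),
                            colnames(norm))
  de <- differential_expression(norm, groups)
  expect_equal(de$log2fc[de$gene_id == "flat"], 0)
  expect_false(de$is_de[de$gene_id == "flat"])
  expect_equal(de$log2fc[de$gene_id == "edge"], 2)
  expect_false(de$is_de[de$gene_id == "edge"])  # strict inequality
  expect_true(de$is_de[de$gene_id == "up"])
  expect_equal(de$direction[de$gene_id == "up"], "up")
  expect_equal(de$direction[de$gene_id == "down"], "down")
  expect_error(differential_expression(norm[, 1:3],
                                       groups[1:3]), "2 samples")
})

test_that("planted high-fold-change genes are recovered from synthetic counts", {
  cfg <- synthetic_config(seed = 15)
  cm <- synth_count_matrix(cfg)
  norm <- normalize_counts(cm$counts, size_factors_median_of_ratios(cm$counts))
  de <- differential_expression(norm, cm$groups)
  planted <- names(cm$truth$de_labels)
  est <- de$log2fc[match(planted, de$gene_id)]
  expect_true(all(abs(est - cm$truth$de_labels) < 0.5))
  expect_true(mean(de$is_de[match(planted, de$gene_id)]) >= 0.9)
})

test_that("the pooled t statistic matches its closed form and the stats oracle", {
  tt <- student_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 * sqrt(3 / 2))
  expect_equal(tt$df, 4)
  or <- stats::t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tt$pvalue, or$p.value)
  same <- student_t_test(c(2, 2), c(2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$pvalue, 1)
  expect_error(student_t_test(1, c(1, 2)), "at least 2")
})

make_cq <- function(target_treated_shift = 0, ref_shift_treated = 0,
                    sample_shift = NULL) {
  rows <- expand.grid(gene_id = c("TG", "Actin", "GAPDH"),
                      condition = c("control", "treated"),
                      bio_rep = 1:3, tech_rep = 1:2,
                      stringsAsFactors = FALSE)
  rows$role <- ifelse(rows$gene_id == "TG", "target", "reference")
  rows$tissue <- "root"
  rows$sample_id <- paste("root", rows$condition, rows$bio_rep, sep = "_")
  rows$cq <- ifelse(rows$role == "reference", 20, 30)
  trt <- rows$condition == "treated"
  rows$cq[trt & rows$role == "target"] <-
    rows$cq[trt & rows$role == "target"] + target_treated_shift
  rows$cq[trt & rows$role == "reference"] <-
    rows$cq[trt & rows$role == "reference"] + ref_shift_treated
  if (!is.null(sample_shift)) {
    rows$cq <- rows$cq + sample_shift[rows$sample_id]
  }
  rows
}

test_that("ddCt identities: no change, 2^3 induction, reference normalization", {
  expect_equal(ddct_relative_expression(make_cq())$rq, 1)
  expect_equal(ddct_relative_expression(make_cq(target_treated_shift = -3))$rq, 8)
  # target and references both shift: normalization cancels it
  both <- make_cq(target_treated_shift = 1, ref_shift_treated = 1)
  expect_equal(ddct_relative_expression(both)$rq, 1)
})

test_that("ddCt is invariant to per-sample Cq offsets", {
  ids <- paste("root", rep(c("control", "treated"), each = 3), 1:3, sep = "_")
  shift <- stats::setNames(c(0.7, -1.2, 0.3, 2.5, -0.4, 1.1), ids)
  base <- ddct_relative_expression(make_cq(target_treated_shift = -2))
  shifted <- ddct_relative_expression(make_cq(target_treated_shift = -2,
                                              sample_shift = shift))
  expect_equal(shifted$rq, base$rq)
  expect_equal(shifted$pvalue, base$pvalue)
})

test_that("noisy Cq still recovers the planted fold change to ~10%", {
  errs <- vapply(1:60, function(s) {
    cfg <- synthetic_config(seed = s, cq_noise_sd = 0.15)
    cq <- synth_cq_table(cfg)
    rr <- ddct_relative_expression(cq$cq)
    truth <- cfg$true_rq
    key <- paste(rr$gene_id, rr$tissue)
    tkey <- paste(truth$gene_id, truth$tissue)
    stats::median(abs(log2(rr$rq / truth$rq[match(key, tkey)])))
  }, 0)
  expect_lt(stats::median(errs), 0.2)
})
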