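# Spearman edge construction, map-equation codelength, community detection
# and anchor subnetworks.

test_that("monotone profiles give rho = 1 edges; constant genes are excluded", {
  x <- 1:10
  mat <- rbind(g1 = x, g2 = x^2 + 1, g3 = rep(4, 10), g4 = 10:1)
  colnames(mat) <- paste0("s", 1:10)
  res <- spearman_edge_list(mat, r_min = 0.7, alpha = 0.01)
  expect_equal(nrow(res$edges), 1L)
  expect_equal(sort(c(res$edges$gene_a, res$edges$gene_b)), c("g1", "g2"))
  expect_equal(res$edges$rho, 1)
  expect_equal(res$edges$p_raw, 0)
  # g3 is constant: 3 genes tested, m = 3 pairs
  expect_equal(res$m, 3)
  expect_error(spearman_edge_list(mat[, 1:3]), "4 samples")
})

test_that("rho equals the rank-then-correlate oracle, including ties", {
  set.seed(9)
  n <- 12
  for (i in 1:10) {
    x <- sample(1:6, n, replace = TRUE)   # heavy ties
    y <- x + stats::rnorm(n, 0, 2)
    mat <- rbind(a = x, b = y)
    colnames(mat) <- paste0("s", 1:n)
    res <- spearman_edge_list(mat, r_min = -1, alpha = 2)
    expect_equal(res$edges$rho[1], stats::cor(x, y, method = "spearman"))
    # t-approximation p-value
    r <- res$edges$rho[1]
    expect_equal(res$edges$p_raw[1],
                 2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2))
  }
})

test_that("edge retention is one-sided and Bonferroni-corrected", {
  set.seed(21)
  mat <- rbind(up = 1:8, down = 8:1, noise = rnorm(8))
  colnames(mat) <- paste0("s", 1:8)
  res <- spearman_edge_list(mat, r_min = 0.7, alpha = 0.05)
  # up/down correlate at -1: never an edge (one-sided filter)
  expect_false(any(res$edges$rho < 0))
  expect_true(all(res$edges$p_bonf == pmin(1, res$m * res$edges$p_raw)))
})

test_that("codelength matches the hand formula on two bridged triangles", {
  ed <- data.frame(gene_a = c("a", "a", "b", "d", "d", "e", "c"),
                   gene_b = c("b", "c", "c", "e", "f", "f", "d"),
                   weight = 1, stringsAsFactors = FALSE)
  g <- weighted_graph(ed)
  part <- stats::setNames(c("1", "1", "1", "2", "2", "2"),
                          c("a", "b", "c", "d", "e", "f"))
  r <- map_equation_codelength(g, part)
  # independent evaluation: p = s/2W, q = cut/2W, entropies by hand
  p <- c(2, 2, 3, 3, 2, 2) / 14
  q <- c(1, 1) / 14
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  pin <- c(sum(p[1:3]), sum(p[4:6]))
  Lhand <- sum(q) * H(q / sum(q)) +
    (q[1] + pin[1]) * H(c(q[1], p[1:3]) / (q[1] + pin[1])) +
    (q[2] + pin[2]) * H(c(q[2], p[4:6]) / (q[2] + pin[2]))
  expect_equal(r$L, Lhand)
  expect_equal(r$q_exit_total, 1 / 7)
  expect_error(map_equation_codelength(g, part[1:5]), "unassigned")
})

test_that("one-module codelength is the visit-rate entropy; rates sum to 1", {
  set.seed(33)
  for (i in 1:5) {
    g <- random_small_graph(sample(4:8, 1))
    one <- map_equation_codelength(g, rep("1", length(g$nodes)))
    p <- g$strength / (2 * g$W)
    expect_equal(sum(p), 1)
    expect_equal(one$L, -sum(p * log2(p)))
    expect_equal(one$q_exit_total, 0)
    # any partition: L >= 0, q_i <= 1
    part <- sample(1:3, length(g$nodes), replace = TRUE)
    r <- map_equation_codelength(g, part)
    expect_gte(r$L, 0)
    expect_true(all(r$module_terms$q <= 1))
  }
})

test_that("singleton partition never beats one module on a 3-clique", {
  g <- weighted_graph(clique_edges(3, "v"))
  one <- map_equation_codelength(g, rep(1, 3))$L
  singl <- map_equation_codelength(g, 1:3)$L
  expect_gte(singl, one)
})

test_that("greedy detection recovers planted cliques and is deterministic", {
  g <- weighted_graph(rbind(clique_edges(5, "x"), clique_edges(5, "y"),
                            data.frame(gene_a = "x1", gene_b = "y1", weight = 1)))
  det <- detect_communities(g, trials = 10, seed = 4)
  groups <- split(names(det$partition), det$partition)
  expect_length(groups, 2L)
  expect_setequal(vapply(groups, function(m) paste(sort(substr(m, 1, 1)), collapse = ""),
                         ""), c("xxxxx", "yyyyy"))
  expect_identical(det$partition, detect_communities(g, trials = 10, seed = 4)$partition)
  # never worse than the one-module partition
  one <- map_equation_codelength(g, rep(1, 10))$L
  expect_lte(det$codelength$L, one)
  single <- detect_communities(weighted_graph(clique_edges(6, "z")),
                               trials = 5, seed = 1)
  expect_length(unique(single$partition), 1L)
})

test_that("greedy detection attains the exhaustive optimum on small graphs", {
  set.seed(55)
  hits <- 0
  for (i in 1:12) {
    g <- random_small_graph(sample(4:7, 1))
    parts <- all_partitions(length(g$nodes))
    Lopt <- min(vapply(parts, function(p) map_equation_codelength(g, p)$L, 0))
    det <- detect_communities(g, trials = 10, seed = i)
    hits <- hits + (det$codelength$L <= Lopt + 1e-9)
  }
  expect_gte(hits, 11)
  # and always on the planted two-clique graph
  g2 <- weighted_graph(rbind(clique_edges(4, "x"), clique_edges(4, "y"),
                             data.frame(gene_a = "x1", gene_b = "y1", weight = 1)))
  Lopt <- min(vapply(all_partitions(8),
                     function(p) map_equation_codelength(g2, p)$L, 0))
  expect_equal(detect_communities(g2, trials = 10, seed = 2)$codelength$L, Lopt)
})

test_that("top-level labels are ordered by descending module flow", {
  g <- weighted_graph(rbind(clique_edges(7, "big"), clique_edges(4, "sm")))
  det <- detect_communities(g, trials = 5, seed = 1)
  groups <- split(names(det$partition), det$partition)
  expect_equal(length(groups[["1"]]), 7L)
  expect_equal(length(groups[["2"]]), 4L)
})

test_that("hierarchy refinement splits bridged cliques and respects max_depth", {
  g <- weighted_graph(rbind(clique_edges(4, "x"), clique_edges(4, "y"),
                            data.frame(gene_a = "x1", gene_b = "y1", weight = 1)))
  flat <- stats::setNames(rep("1", 8), g$nodes)
  ref <- refine_hierarchy(g, flat, max_depth = 2, seed = 3)
  expect_setequal(unique(ref), c("1:1", "1:2"))
  expect_identical(refine_hierarchy(g, flat, max_depth = 1), flat)
  # a single clique module stays unsplit
  g1 <- weighted_graph(clique_edges(5, "z"))
  flat1 <- stats::setNames(rep("1", 5), g1$nodes)
  expect_identical(refine_hierarchy(g1, flat1, max_depth = 3, seed = 1), flat1)
})

test_that("anchor subnetworks keep only anchor-incident edges", {
  ed <- data.frame(gene_a = c("A", "A", "A", "B", "X"),
                   gene_b = c("B", "C", "D", "C", "Y"),
                   weight = c(0.9, 0.8, 0.7, 0.95, 0.75),
                   stringsAsFactors = FALSE)
  g <- weighted_graph(ed)
  sub <- extract_anchor_subnetwork(g, "A")
  expect_setequal(sub$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(sub$edges), 3L)
  expect_equal(sub$neighbor_counts, c(A = 3L))
  # B-C exists but is not anchor-incident once A is the only anchor
  expect_false(any(sub$edges$gene_a == "B" & sub$edges$gene_b == "C"))
  # absent anchor: counted 0, not in node set
  sub2 <- extract_anchor_subnetwork(g, c("A", "ZZ"))
  expect_equal(sub2$neighbor_counts[["ZZ"]], 0L)
  expect_false("ZZ" %in% sub2$nodes)
  # edge-count identity: sum of neighbor counts minus doubly-anchored edges
  sub3 <- extract_anchor_subnetwork(g, c("A", "B"))
  both_anchored <- sum(sub3$edges$gene_a %in% c("A", "B") &
                         sub3$edges$gene_b %in% c("A", "B"))
  expect_equal(nrow(sub3$edges),
               sum(sub3$neighbor_counts) - both_anchored)
})

test_that("permuting gene order changes no retained edge", {
  set.seed(61)
  cfg <- synthetic_config(seed = 2, genes_per_chrom = 40, n_modules = 2,
                          module_size = 10, n_de = 4)
  cm <- synth_count_matrix(cfg)
  norm <- normalize_counts(cm$counts, size_factors_median_of_ratios(cm$counts))
  a <- spearman_edge_list(norm)
  b <- spearman_edge_list(norm[sample(nrow(norm)), ])
  canon <- function(e) sort(paste(pmin(e$gene_a, e$gene_b),
                                  pmax(e$gene_a, e$gene_b)))
  expect_equal(canon(a$edges), canon(b$edges))
})
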