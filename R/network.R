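# Co-expression network construction and map-equation community detection.
#
# The two-level map equation for an undirected weighted graph:
#   L = q * H(Q) + sum_i (q_i + p_i) * H(P_i)
# with node visit rates p_a = s_a / 2W (s_a = strength, W = total edge
# weight), module exit rates q_i = cut(i) / 2W, q = sum q_i. Expanding the
# entropies gives the computational form used throughout:
#   L = plogp(q) - 2 sum_i plogp(q_i) + sum_i plogp(q_i + p_in_i)
#       - sum_a plogp(p_a)
# The last term does not depend on the partition, so local moves only track
# the first three.

#' Build a validated undirected weighted graph
#'
#' @param edges data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{weight} (positive; no self-loops or duplicate unordered pairs).
#' @param nodes Optional character vector of node ids (defaults to the nodes
#'   incident to at least one edge).
#' @return An object of class \code{coexreg_graph} with adjacency indices,
#'   node strengths and total weight.
#' @export
weighted_graph <- function(edges, nodes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (any(edges$weight <= 0)) stop("edge weights must be positive", call. = FALSE)
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed", call. = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  i <- match(edges$gene_a, nodes)
  j <- match(edges$gene_b, nodes)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint missing from node set", call. = FALSE)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- paste(i, j)
  if (anyDuplicated(key)) stop("duplicate edges (unordered pairs must be unique)", call. = FALSE)
  n <- length(nodes)
  strength <- numeric(n)
  agg_i <- tapply(edges$weight, i, sum)
  agg_j <- tapply(edges$weight, j, sum)
  strength[as.integer(names(agg_i))] <- strength[as.integer(names(agg_i))] + agg_i
  strength[as.integer(names(agg_j))] <- strength[as.integer(names(agg_j))] + agg_j
  adj <- rep(list(integer()), n)
  adj_w <- rep(list(numeric()), n)
  ord_i <- split(seq_along(i), i)
  ord_j <- split(seq_along(j), j)
  for (v in names(ord_i)) {
    vi <- as.integer(v)
    adj[[vi]] <- c(adj[[vi]], j[ord_i[[v]]])
    adj_w[[vi]] <- c(adj_w[[vi]], edges$weight[ord_i[[v]]])
  }
  for (v in names(ord_j)) {
    vi <- as.integer(v)
    adj[[vi]] <- c(adj[[vi]], i[ord_j[[v]]])
    adj_w[[vi]] <- c(adj_w[[vi]], edges$weight[ord_j[[v]]])
  }
  structure(list(nodes = nodes, ei = i, ej = j, w = edges$weight,
                 strength = strength, W = sum(edges$weight),
                 adj = adj, adj_w = adj_w),
            class = "coexreg_graph")
}

#' @export
print.coexreg_graph <- function(x, ...) {
  cat(sprintf("<graph> %d nodes, %d edges, total weight %.4g\n",
              length(x$nodes), length(x$w), x$W))
  invisible(x)
}

as_membership <- function(graph, partition) {
  n <- length(graph$nodes)
  if (!is.null(names(partition))) {
    if (!all(graph$nodes %in% names(partition))) {
      stop("partition leaves node(s) unassigned: ",
           paste(utils::head(setdiff(graph$nodes, names(partition)), 3), collapse = ", "),
           call. = FALSE)
    }
    partition <- partition[graph$nodes]
  } else if (length(partition) != n) {
    stop("unnamed partition must have one entry per node", call. = FALSE)
  }
  if (anyNA(partition)) stop("partition contains NA assignments", call. = FALSE)
  as.integer(factor(as.character(partition)))
}

#' Two-level map-equation codelength of a partition
#'
#' @param graph A \code{coexreg_graph}.
#' @param partition Module labels: a named vector (names = node ids) or a
#'   vector aligned with \code{graph$nodes}. Each distinct label is one
#'   module.
#' @return list with \code{L} (bits), \code{q_exit_total}, and
#'   \code{module_terms} (per-module exit rate \code{q}, visit mass
#'   \code{p_in}, and codebook usage \code{q_plus_p}).
#' @export
map_equation_codelength <- function(graph, partition) {
  memb <- as_membership(graph, partition)
  two_w <- 2 * graph$W
  p_a <- graph$strength / two_w
  k <- max(memb)
  pin <- vapply(seq_len(k), function(m) sum(p_a[memb == m]), 0)
  cut_edge <- memb[graph$ei] != memb[graph$ej]
  q <- numeric(k)
  if (any(cut_edge)) {
    wcut <- graph$w[cut_edge] / two_w
    for (side in list(memb[graph$ei][cut_edge], memb[graph$ej][cut_edge])) {
      agg <- tapply(wcut, side, sum)
      q[as.integer(names(agg))] <- q[as.integer(names(agg))] + agg
    }
  }
  Q <- sum(q)
  L <- plogp(Q) - 2 * sum(plogp(q)) + sum(plogp(q + pin)) - sum(plogp(p_a))
  labels <- levels(factor(as.character(
    if (!is.null(names(partition))) partition[graph$nodes] else partition)))
  list(L = L, q_exit_total = Q,
       module_terms = data.frame(module = labels, q = q, p_in = pin,
                                 q_plus_p = q + pin, stringsAsFactors = FALSE))
}

# One sweep-to-convergence of map-equation local moves at one aggregation
# level. p: visit rates; pext: normalized external strength; adjacency in
# 2W-normalized weights. Returns the integer membership.
local_moves <- function(p, pext, adj, adj_wn, tol = 1e-10) {
  n <- length(p)
  memb <- seq_len(n)
  q <- pext            # singleton modules: exit = external strength
  pin <- p
  Q <- sum(q)
  mod_size <- rep(1L, n)
  free_labels <- integer()
  repeat {
    improved <- FALSE
    for (v in sample.int(n)) {
      nb <- adj[[v]]
      if (length(nb) == 0L) next
      mv <- memb[v]
      nbm <- memb[nb]
      e_to <- rowsum(adj_wn[[v]], nbm)           # v's weight into each module
      mods <- as.integer(rownames(e_to))
      e_vi <- if (mv %in% mods) e_to[match(mv, mods), 1] else 0
      # leaving module mv
      q_i_new <- q[mv] - pext[v] + 2 * e_vi
      pin_i_new <- pin[mv] - p[v]
      base_i <- -2 * (plogp(q_i_new) - plogp(q[mv])) +
        (plogp(q_i_new + pin_i_new) - plogp(q[mv] + pin[mv]))
      cand <- mods[mods != mv]
      if (mod_size[mv] > 1L) {
        # moving out into a fresh singleton module is also a candidate
        new_lab <- if (length(free_labels)) free_labels[1] else NA_integer_
        if (!is.na(new_lab)) cand <- c(cand, new_lab)
      }
      if (length(cand) == 0L) next
      best_dJ <- -tol; best_j <- NA_integer_
      for (mj in cand) {
        e_vj <- if (mj %in% mods) e_to[match(mj, mods), 1] else 0
        q_j_new <- q[mj] + pext[v] - 2 * e_vj
        pin_j_new <- pin[mj] + p[v]
        Q_new <- Q - q[mv] - q[mj] + q_i_new + q_j_new
        dJ <- (plogp(Q_new) - plogp(Q)) + base_i -
          2 * (plogp(q_j_new) - plogp(q[mj])) +
          (plogp(q_j_new + pin_j_new) - plogp(q[mj] + pin[mj]))
        if (dJ < best_dJ - 1e-15 || (dJ < best_dJ + 1e-15 && !is.na(best_j) && mj < best_j)) {
          best_dJ <- dJ; best_j <- mj
        }
      }
      if (!is.na(best_j)) {
        mj <- best_j
        e_vj <- if (mj %in% mods) e_to[match(mj, mods), 1] else 0
        q_new_j <- q[mj] + pext[v] - 2 * e_vj
        Q <- Q - q[mv] - q[mj] + q_i_new + q_new_j
        q[mv] <- q_i_new; pin[mv] <- pin_i_new
        q[mj] <- q_new_j; pin[mj] <- pin[mj] + p[v]
        mod_size[mv] <- mod_size[mv] - 1L
        if (mod_size[mv] == 0L) free_labels <- c(free_labels, mv)
        if (mj %in% free_labels) free_labels <- setdiff(free_labels, mj)
        mod_size[mj] <- mod_size[mj] + 1L
        memb[v] <- mj
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  memb
}

# Full greedy optimization: local moves, module aggregation, repeat.
# Returns membership over the original supernode indexing.
greedy_partition <- function(p, pext, adj, adj_wn, edges_a, edges_b, edges_wn,
                             tol = 1e-10) {
  assign_orig <- seq_along(p)  # original node -> current supernode
  repeat {
    memb <- local_moves(p, pext, adj, adj_wn, tol)
    memb <- match(memb, sort(unique(memb)))  # contiguous, numeric order
    k <- max(memb)
    if (k == length(p)) break  # nothing merged at this level: converged
    assign_orig <- memb[assign_orig]
    if (k == 1L) break
    # aggregate supernodes into modules; a module's external strength is the
    # normalized weight of its cut edges (each cross edge counted once)
    p_new <- as.numeric(rowsum(p, memb))
    cross <- memb[edges_a] != memb[edges_b]
    ea <- memb[edges_a][cross]; eb <- memb[edges_b][cross]; ew <- edges_wn[cross]
    swap <- ea > eb; tmp <- ea[swap]; ea[swap] <- eb[swap]; eb[swap] <- tmp
    if (length(ea)) {
      key <- paste(ea, eb)
      first <- !duplicated(key)
      ew <- as.numeric(rowsum(ew, key)[unique(key), ])
      ea <- ea[first]; eb <- eb[first]
    }
    if (length(ea) == 0L) break  # modules fully disconnected: nothing to refine
    pext_new <- numeric(k)
    adj_new <- rep(list(integer()), k)
    adjw_new <- rep(list(numeric()), k)
    for (e in seq_along(ea)) {
      a <- ea[e]; b <- eb[e]; wv <- ew[e]
      adj_new[[a]] <- c(adj_new[[a]], b); adjw_new[[a]] <- c(adjw_new[[a]], wv)
      adj_new[[b]] <- c(adj_new[[b]], a); adjw_new[[b]] <- c(adjw_new[[b]], wv)
      pext_new[a] <- pext_new[a] + wv; pext_new[b] <- pext_new[b] + wv
    }
    p <- p_new; pext <- pext_new; adj <- adj_new; adj_wn <- adjw_new
    edges_a <- ea; edges_b <- eb; edges_wn <- ew
  }
  assign_orig
}

#' Detect communities by multi-trial greedy map-equation minimization
#'
#' Each trial visits nodes in a seeded random order, moving each node to the
#' neighboring module with the largest codelength decrease (ties to the
#' lowest module label), then aggregates modules into supernodes and
#' repeats until converged. The best of \code{trials} runs is returned, with
#' top-level labels numbered by descending module flow (exit + visit rate).
#'
#' @param graph A \code{coexreg_graph}.
#' @param trials Number of independent restarts (default 10).
#' @param seed Integer seed; the same seed yields the identical partition.
#' @return list with \code{partition} (named character vector node ->
#'   module label) and \code{codelength} (the [map_equation_codelength()]
#'   report of the winning partition).
#' @export
detect_communities <- function(graph, trials = 10L, seed = 1L) {
  n <- length(graph$nodes)
  if (n == 0L) stop("graph has no nodes", call. = FALSE)
  two_w <- 2 * graph$W
  p <- graph$strength / two_w
  pext <- p  # original nodes have no internal weight
  adj_wn <- lapply(graph$adj_w, function(wv) wv / two_w)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  best <- NULL
  best_L <- Inf
  for (t in seq_len(trials)) {
    set.seed(seed + t - 1L)
    memb <- greedy_partition(p, pext, graph$adj, adj_wn,
                             graph$ei, graph$ej, graph$w / two_w)
    L <- map_equation_codelength(graph, memb)$L
    if (L < best_L - 1e-12) {
      best_L <- L
      best <- memb
    }
  }
  # relabel by descending module flow
  rep0 <- map_equation_codelength(graph, best)
  labs <- rep0$module_terms$module
  ord <- order(-rep0$module_terms$q_plus_p, suppressWarnings(as.numeric(labs)))
  new_of <- stats::setNames(as.character(seq_along(ord)), labs[ord])
  partition <- stats::setNames(unname(new_of[as.character(best)]), graph$nodes)
  list(partition = partition,
       codelength = map_equation_codelength(graph, partition))
}

induced_subgraph_edges <- function(graph, node_set) {
  keep <- graph$nodes[graph$ei] %in% node_set & graph$nodes[graph$ej] %in% node_set
  data.frame(gene_a = graph$nodes[graph$ei][keep],
             gene_b = graph$nodes[graph$ej][keep],
             weight = graph$w[keep], stringsAsFactors = FALSE)
}

#' Hierarchical refinement of a partition
#'
#' Within each module, communities are re-detected on the induced subgraph;
#' a split is kept iff it lowers that subgraph's standalone two-level
#' codelength by more than \code{tol} bits. Labels extend as parent:child,
#' recursing to \code{max_depth} levels.
#'
#' @param graph A \code{coexreg_graph}.
#' @param partition Named module labels from [detect_communities()].
#' @param max_depth Maximum number of label levels (default 4).
#' @param trials,seed Passed to the per-module [detect_communities()] calls.
#' @param tol Minimum codelength improvement to accept a split.
#' @return Named character vector of hierarchical labels (e.g. "1:2").
#' @export
refine_hierarchy <- function(graph, partition, max_depth = 4L, trials = 10L,
                             seed = 1L, tol = 1e-10) {
  if (max_depth <= 1L) return(partition)
  out <- partition
  for (lab in unique(partition)) {
    members <- names(partition)[partition == lab]
    if (length(members) < 2L) next
    sub_edges <- induced_subgraph_edges(graph, members)
    if (nrow(sub_edges) == 0L) next
    sub <- weighted_graph(sub_edges, nodes = members)
    det <- detect_communities(sub, trials = trials, seed = seed)
    if (length(unique(det$partition)) < 2L) next
    one <- map_equation_codelength(sub, rep("1", length(members)))
    if (det$codelength$L < one$L - tol) {
      child <- refine_hierarchy(sub, det$partition, max_depth = max_depth - 1L,
                                trials = trials, seed = seed, tol = tol)
      out[members] <- paste(lab, child[members], sep = ":")
    }
  }
  out
}

#' Spearman co-expression edge list under Bonferroni control
#'
#' Spearman rho is the Pearson correlation of average-ranked profiles;
#' two-sided p-values use the t approximation with df = n - 2 (rho of
#' exactly +-1 gives p = 0). Genes whose ranks have zero variance are
#' excluded before pairing, and the Bonferroni family size m is the number
#' of pairs actually tested. An edge is retained iff rho >= \code{r_min}
#' (one-sided: negative correlations never form edges) and m * p <
#' \code{alpha}; the edge weight is rho.
#'
#' @param normalized Genes x samples matrix (>= 4 samples).
#' @param r_min Correlation threshold (default 0.7).
#' @param alpha Bonferroni-corrected p-value threshold (default 0.01).
#' @return list with \code{edges} (data.frame \code{gene_a}, \code{gene_b},
#'   \code{rho}, \code{p_raw}, \code{p_bonf}), \code{graph}
#'   (a \code{coexreg_graph} over nodes with >= 1 edge), and \code{m}.
#' @export
spearman_edge_list <- function(normalized, r_min = 0.7, alpha = 0.01) {
  nsamp <- ncol(normalized)
  if (nsamp < 4L) stop("need at least 4 samples", call. = FALSE)
  ranks <- t(apply(normalized, 1, rank))
  keep <- apply(ranks, 1, stats::var) > 0
  ranks <- ranks[keep, , drop = FALSE]
  g <- nrow(ranks)
  m <- g * (g - 1) / 2
  if (g < 2L) {
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        rho = numeric(), p_raw = numeric(), p_bonf = numeric(),
                        stringsAsFactors = FALSE)
    return(list(edges = empty, graph = weighted_graph(empty, nodes = rownames(ranks)),
                m = m))
  }
  rho <- stats::cor(t(ranks))
  ut <- which(upper.tri(rho) & rho >= r_min, arr.ind = TRUE)
  r <- rho[ut]
  p_raw <- ifelse(abs(r) >= 1, 0,
                  2 * stats::pt(-abs(r) * sqrt((nsamp - 2) / (1 - r^2)), nsamp - 2))
  p_bonf <- pmin(1, m * p_raw)
  sel <- p_bonf < alpha
  edges <- data.frame(gene_a = rownames(ranks)[ut[sel, 1]],
                      gene_b = rownames(ranks)[ut[sel, 2]],
                      rho = r[sel], p_raw = p_raw[sel], p_bonf = p_bonf[sel],
                      stringsAsFactors = FALSE)
  graph <- weighted_graph(data.frame(gene_a = edges$gene_a, gene_b = edges$gene_b,
                                     weight = edges$rho, stringsAsFactors = FALSE))
  list(edges = edges, graph = graph, m = m)
}

#' Extract the anchor-incident subnetwork
#'
#' Nodes are the anchors present in the graph plus all their direct
#' neighbors; edges are the graph edges with at least one anchor endpoint.
#' Anchors without neighbors (including anchors absent from the graph) are
#' excluded from the node set but reported with a neighbor count of 0.
#'
#' @param graph A \code{coexreg_graph}.
#' @param anchors Character vector of anchor node ids (nonempty).
#' @return list with \code{anchor_ids}, \code{nodes}, \code{edges}
#'   (data.frame \code{gene_a}, \code{gene_b}, \code{weight}), and
#'   \code{neighbor_counts} (named integer over all requested anchors).
#' @export
extract_anchor_subnetwork <- function(graph, anchors) {
  if (length(anchors) == 0L) stop("anchor set must be nonempty", call. = FALSE)
  anchors <- unique(anchors)
  idx <- match(anchors, graph$nodes)
  counts <- stats::setNames(integer(length(anchors)), anchors)
  present <- !is.na(idx)
  counts[present] <- lengths(graph$adj[idx[present]])
  a_end <- graph$nodes[graph$ei] %in% anchors
  b_end <- graph$nodes[graph$ej] %in% anchors
  keep <- a_end | b_end
  edges <- data.frame(gene_a = graph$nodes[graph$ei][keep],
                      gene_b = graph$nodes[graph$ej][keep],
                      weight = graph$w[keep], stringsAsFactors = FALSE)
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  list(anchor_ids = anchors, nodes = nodes, edges = edges,
       neighbor_counts = counts)
}

#' Write a subnetwork as GraphML
#'
#' Node attribute \code{category} distinguishes anchors from neighbors and
#' \code{module_path} carries community labels; the edge attribute
#' \code{rho} is the correlation weight. Requires the igraph package.
#'
#' @param subnet Result of [extract_anchor_subnetwork()].
#' @param path Output path.
#' @param partition Optional named module labels for the node attribute.
#' @return `path`, invisibly.
#' @export
write_subnetwork_graphml <- function(subnet, path, partition = NULL) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export requires the igraph package", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(subnet$edges, directed = FALSE)
  igraph::E(g)$rho <- subnet$edges$weight
  vn <- igraph::V(g)$name
  igraph::V(g)$category <- ifelse(vn %in% subnet$anchor_ids, "anchor", "neighbor")
  if (!is.null(partition)) {
    igraph::V(g)$module_path <- ifelse(vn %in% names(partition),
                                       unname(partition[vn]), "")
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
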