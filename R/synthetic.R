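# Seeded synthetic corpora with machine-readable ground truth: a genome +
# annotation with planted promoter motifs, module-structured negative
# binomial counts with planted size factors and differential expression,
# and qPCR Cq tables with known relative quantities.
#
# Every generator seeds the R RNG from the config (restoring the caller's
# RNG state afterwards), so identical configs give identical bytes.

#' Default study configuration for the synthetic corpus
#'
#' The defaults define the simulated study: 2 chromosomes x 250 genes with
#' 2000-bp promoters, a planted G-box (CACGTG) in the promoters of the
#' module-1 genes, 5 expression modules of 40 genes driven by latent
#' factors, 12 + 12 samples (control/treated), negative binomial counts
#' with dispersion 0.05, planted size factors log-uniform in [0.5, 2], and
#' 40 planted differentially expressed background genes at |log2FC| = 3.
#'
#' @param seed Integer master seed.
#' @param n_chroms,genes_per_chrom Genome layout.
#' @param promoter_len Upstream window length (bp).
#' @param gene_len Length of each gene body (bp).
#' @param planted_pattern IUPAC string or a \code{coexreg_pwm}; planted
#'   instances are literal realizations of the pattern (IUPAC positions
#'   sampled uniformly from their base sets, PWM columns sampled from their
#'   probabilities).
#' @param n_modules,module_size Planted co-expression modules.
#' @param n_samples Samples per condition.
#' @param factor_strength Loading scale of the latent module factors.
#' @param nb_dispersion Negative binomial dispersion phi
#'   (variance = mu + phi mu^2).
#' @param planted_log2fc Planted |log2 fold change| of the DE genes.
#' @param n_de Number of planted DE genes (half up, half down), drawn from
#'   the non-module background so the treatment shift does not masquerade
#'   as a co-expression module.
#' @param size_factor_range Planted size factor range (log-uniform).
#' @param cq_noise_sd Cq measurement noise, cycles.
#' @param true_rq data.frame(gene_id, tissue, rq) of planted qPCR fold
#'   changes.
#' @return A list of class \code{coexreg_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             n_chroms = 2L,
                             genes_per_chrom = 250L,
                             promoter_len = 2000L,
                             gene_len = 600L,
                             planted_pattern = "CACGTG",
                             n_modules = 5L,
                             module_size = 40L,
                             n_samples = 12L,
                             factor_strength = 1,
                             nb_dispersion = 0.05,
                             planted_log2fc = 3,
                             n_de = 40L,
                             size_factor_range = c(0.5, 2),
                             cq_noise_sd = 0.15,
                             true_rq = data.frame(
                               gene_id = rep(c("T_UP8", "T_DN4", "T_NC"), 2),
                               tissue = rep(c("root", "shoot"), each = 3),
                               rq = rep(c(8, 0.25, 1), 2),
                               stringsAsFactors = FALSE)) {
  n_genes <- n_chroms * genes_per_chrom
  stopifnot(n_modules * module_size + n_de <= n_genes,
            nb_dispersion > 0, size_factor_range[1] > 0,
            size_factor_range[2] >= size_factor_range[1],
            n_samples >= 2L, promoter_len >= 1L)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  module_membership <- stats::setNames(
    rep(seq_len(n_modules), each = module_size),
    gene_ids[seq_len(n_modules * module_size)])
  de_ids <- gene_ids[n_modules * module_size + seq_len(n_de)]
  de_labels <- stats::setNames(
    rep(c(planted_log2fc, -planted_log2fc), length.out = n_de), de_ids)
  structure(list(
    seed = as.integer(seed), n_chroms = n_chroms,
    genes_per_chrom = genes_per_chrom, promoter_len = promoter_len,
    gene_len = gene_len, planted_pattern = planted_pattern,
    target_gene_ids = names(module_membership)[module_membership == 1L],
    n_modules = n_modules, module_size = module_size,
    n_samples = n_samples, factor_strength = factor_strength,
    nb_dispersion = nb_dispersion, planted_log2fc = planted_log2fc,
    de_labels = de_labels, size_factor_range = size_factor_range,
    cq_noise_sd = cq_noise_sd, true_rq = true_rq,
    gene_ids = gene_ids, module_membership = module_membership),
    class = "coexreg_config")
}

with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  expr
}

plant_realization <- function(pattern) {
  if (inherits(pattern, "coexreg_pwm")) {
    bases <- apply(pattern$probs, 1, function(p) sample(DNA_BASES, 1, prob = p))
    return(paste(bases, collapse = ""))
  }
  sets <- iupac_sets()
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    s <- sets[[ch]]
    s[sample.int(length(s), 1)]
  }, ""), collapse = "")
}

pattern_width <- function(pattern) {
  if (inherits(pattern, "coexreg_pwm")) pattern$width else nchar(pattern)
}

#' Synthetic genome with planted promoter motifs
#'
#' Chromosomes are i.i.d. uniform ACGT; genes sit in fixed slots with at
#' least \code{promoter_len} clearance on both sides and random strands.
#' One realization of the planted pattern is written into the promoter of
#' each target gene at a recorded offset (on the promoter's own strand).
#'
#' @param config A [synthetic_config()].
#' @return list with \code{genome} (named character), \code{genes}
#'   (gene-model data.frame), and \code{truth} (motif placements).
#' @export
synth_genome_with_motifs <- function(config) {
  with_seed(config$seed, {
    plen <- config$promoter_len
    glen <- config$gene_len
    slot <- 2L * plen + glen
    chrom_len <- config$genes_per_chrom * slot + plen
    w <- pattern_width(config$planted_pattern)
    if (w > plen) stop("planted pattern wider than the promoter", call. = FALSE)
    chrom_ids <- sprintf("chr%d", seq_len(config$n_chroms))
    genome <- vapply(chrom_ids, function(chr) {
      paste(sample(DNA_BASES, chrom_len, replace = TRUE), collapse = "")
    }, "")
    genes <- data.frame(
      gene_id = config$gene_ids,
      chrom = rep(chrom_ids, each = config$genes_per_chrom),
      start = rep(plen + slot * (seq_len(config$genes_per_chrom) - 1L) + plen + 1L,
                  config$n_chroms),
      stringsAsFactors = FALSE)
    genes$end <- genes$start + glen - 1L
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    placements <- list()
    for (g in config$target_gene_ids) {
      row <- genes[genes$gene_id == g, ]
      inst <- plant_realization(config$planted_pattern)
      offset0 <- sample.int(plen - w + 1L, 1L) - 1L
      if (row$strand == "+") {
        # promoter occupies [start-1-plen, start-1) 0-based
        at1 <- (row$start - 1L - plen) + offset0 + 1L
        piece <- inst
      } else {
        # promoter is the reverse complement of [end, end+plen) 0-based
        at1 <- row$end + plen - offset0 - w + 1L
        piece <- reverse_complement(inst)
      }
      substr(genome[row$chrom], at1, at1 + w - 1L) <- piece
      placements[[g]] <- list(offset0 = offset0, strand = "+",
                              instance = inst)
    }
    list(genome = genome, genes = genes,
         truth = list(motif_placements = placements))
  })
}

#' Write gene models as GFF3
#'
#' @param genes data.frame with gene_id, chrom, start, end, strand.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tcoexreg\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
                     genes$chrom, genes$start, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Module-structured negative binomial count matrix
#'
#' Per sample j and module m a latent factor f_mj ~ N(0, 1); gene loadings
#' a_i ~ U(0.8, 1.2); baseline beta_i ~ U(ln 50, ln 500). The log mean is
#' beta_i + factor_strength * a_i * f_m(i),j plus, for treated samples of
#' planted DE genes, log2fc * ln 2 (so the planted value is exactly a log2
#' fold change). Counts are NB(mean = s_j exp(mu), dispersion phi) with
#' planted size factors s_j log-uniform in the configured range.
#'
#' @param config A [synthetic_config()].
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{groups} (named sample -> condition), and \code{truth}
#'   (module membership, DE log2fc labels, size factors).
#' @export
synth_count_matrix <- function(config) {
  with_seed(config$seed + 1L, {
    n_genes <- length(config$gene_ids)
    ns <- config$n_samples
    sample_ids <- sprintf("S%02d", seq_len(2L * ns))
    groups <- stats::setNames(rep(c("control", "treated"), each = ns), sample_ids)
    beta <- stats::runif(n_genes, log(50), log(500))
    loading <- stats::runif(n_genes, 0.8, 1.2)
    f <- matrix(stats::rnorm(config$n_modules * 2L * ns),
                nrow = config$n_modules)
    sf <- exp(stats::runif(2L * ns, log(config$size_factor_range[1]),
                           log(config$size_factor_range[2])))
    mod_of <- rep(NA_integer_, n_genes)
    mod_of[match(names(config$module_membership), config$gene_ids)] <-
      config$module_membership
    lfc <- rep(0, n_genes)
    lfc[match(names(config$de_labels), config$gene_ids)] <- config$de_labels
    mu_log <- matrix(beta, n_genes, 2L * ns)
    has_mod <- !is.na(mod_of)
    mu_log[has_mod, ] <- mu_log[has_mod, ] +
      config$factor_strength * loading[has_mod] * f[mod_of[has_mod], , drop = FALSE]
    treated_cols <- groups == "treated"
    mu_log[, treated_cols] <- mu_log[, treated_cols] + lfc * log(2)
    mu <- sweep(exp(mu_log), 2, sf, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nrow = n_genes,
                     dimnames = list(config$gene_ids, sample_ids))
    list(counts = counts, groups = groups,
         truth = list(module_membership = config$module_membership,
                      de_labels = config$de_labels,
                      size_factors = stats::setNames(sf, sample_ids)))
  })
}

#' Synthetic qPCR Cq table with known relative quantities
#'
#' 3 biological x 4 technical replicates per condition and tissue; two
#' reference genes (Actin, GAPDH) at Cq ~ 20, targets at Cq ~ 30 in the
#' control condition and 30 - log2(rq) when treated, all with Gaussian
#' measurement noise of \code{cq_noise_sd} cycles.
#'
#' @param config A [synthetic_config()].
#' @param true_rq data.frame(gene_id, tissue, rq); defaults to the config's.
#' @param n_bio,n_tech Replicate structure.
#' @return list with \code{cq} (long-format data.frame) and \code{truth}.
#' @export
synth_cq_table <- function(config, true_rq = config$true_rq,
                           n_bio = 3L, n_tech = 4L) {
  stopifnot(all(true_rq$rq > 0))
  with_seed(config$seed + 2L, {
    refs <- c("Actin", "GAPDH")
    rows <- list()
    emit <- function(sid, gene, role, tis, cond, b, base) {
      data.frame(sample_id = sid, gene_id = gene, role = role, tissue = tis,
                 condition = cond, bio_rep = b, tech_rep = seq_len(n_tech),
                 cq = base + stats::rnorm(n_tech, 0, config$cq_noise_sd),
                 stringsAsFactors = FALSE)
    }
    for (tis in unique(true_rq$tissue)) {
      for (cond in c("control", "treated")) {
        for (b in seq_len(n_bio)) {
          sid <- paste(tis, cond, b, sep = "_")
          for (ref in refs) {
            rows[[length(rows) + 1L]] <- emit(sid, ref, "reference", tis, cond, b, 20)
          }
          tr <- true_rq[true_rq$tissue == tis, , drop = FALSE]
          for (r in seq_len(nrow(tr))) {
            base <- if (cond == "treated") 30 - log2(tr$rq[r]) else 30
            rows[[length(rows) + 1L]] <- emit(sid, tr$gene_id[r], "target",
                                              tis, cond, b, base)
          }
        }
      }
    }
    cq <- do.call(rbind, rows)
    rownames(cq) <- NULL
    list(cq = cq, truth = list(true_rq = true_rq))
  })
}

#' Emit the full synthetic bundle with its truth JSON
#'
#' Writes genome FASTA, GFF3 annotation, count matrix TSV, sample sheet,
#' Cq CSV, the planted motif pattern file, an anchor list (the first two
#' genes of every planted module), a truth JSON and a manifest recording
#' the seed and parameters.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing directory.
#' @return Invisible list of the in-memory artifacts (genome, genes,
#'   counts, groups, cq, truth, paths).
#' @export
synth_truth_bundle <- function(config, dir, overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite) {
    stop("output directory exists (use overwrite = TRUE): ", dir, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- synth_genome_with_motifs(config)
  cm <- synth_count_matrix(config)
  cq <- synth_cq_table(config)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    gff3 = file.path(dir, "genes.gff3"),
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    cq = file.path(dir, "cq.csv"),
    motifs = file.path(dir, "motifs.txt"),
    anchors = file.path(dir, "anchors.txt"),
    truth = file.path(dir, "truth.json"),
    manifest = file.path(dir, "manifest.json"))
  write_fasta(gen$genome, paths$genome)
  write_gff3_genes(gen$genes, paths$gff3)
  utils::write.table(data.frame(gene_id = rownames(cm$counts), cm$counts,
                                check.names = FALSE),
                     paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = names(cm$groups),
                                group = unname(cm$groups)),
                     paths$samples, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cq$cq, paths$cq, row.names = FALSE, quote = FALSE)
  pat <- if (inherits(config$planted_pattern, "coexreg_pwm")) {
    pwm_to_iupac(config$planted_pattern)
  } else config$planted_pattern
  writeLines(pat, paths$motifs)
  # anchors: the first two genes of each planted module
  anchors <- unlist(lapply(split(names(config$module_membership),
                                 config$module_membership),
                           utils::head, 2L), use.names = FALSE)
  writeLines(anchors, paths$anchors)
  truth <- list(motif_placements = gen$truth$motif_placements,
                module_membership = as.list(cm$truth$module_membership),
                de_labels = as.list(cm$truth$de_labels),
                size_factors = as.list(cm$truth$size_factors),
                true_rq = config$true_rq)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  manifest <- unclass(config)
  manifest$planted_pattern <- pat
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(genome = gen$genome, genes = gen$genes, counts = cm$counts,
                 groups = cm$groups, cq = cq$cq,
                 truth = truth, anchors = anchors, paths = paths))
}
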