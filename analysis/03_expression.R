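#!/usr/bin/env Rscript
# Step 3: median-of-ratios normalization, the strict |log2FC| > 2 &
# p < 0.05 differential expression filter, and 2^-ddCt qPCR fold changes.

library(coexreg)

tab <- utils::read.delim("results/bundle/counts.tsv", check.names = FALSE)
counts <- as.matrix(tab[, -1])
rownames(counts) <- tab$gene_id
samples <- utils::read.delim("results/bundle/samples.tsv")
groups <- stats::setNames(samples$group, samples$sample_id)

sf <- size_factors_median_of_ratios(counts)
norm <- normalize_counts(counts, sf)
utils::write.table(data.frame(sample_id = names(sf), size_factor = sf),
                   "results/size_factors.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(gene_id = rownames(norm), round(norm, 4),
                              check.names = FALSE),
                   "results/normalized_counts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

de <- differential_expression(norm, groups, fc_threshold = 2, alpha = 0.05)
utils::write.table(de, "results/de_results.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cq <- utils::read.csv("results/bundle/cq.csv")
rq <- ddct_relative_expression(cq)
utils::write.table(rq, "results/qpcr_rq.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("size factors span %.2f-%.2f\n", min(sf), max(sf)))
cat(sprintf("DE filter: %d up, %d down of %d genes\n",
            sum(de$direction == "up"), sum(de$direction == "down"), nrow(de)))
cat("qPCR fold changes (treated vs control):\n")
print(rq, digits = 3)
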