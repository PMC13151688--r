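#!/usr/bin/env Rscript
# Step 5: transcription-factor-family motif enrichment per co-expression
# community (one-sided Fisher, BH-corrected, log2 proportion enrichment).

library(coexreg)

hits <- utils::read.delim("results/iupac_hits.tsv")
part_tab <- utils::read.delim("results/communities.tsv")
# enrichment is interpreted at the top level of the module hierarchy
top <- sub(":.*$", "", part_tab$module_path)
partition <- stats::setNames(top, part_tab$gene_id)

prom_bed <- utils::read.table("results/promoters.bed", sep = "\t")
universe <- prom_bed$V4

families <- stats::setNames("bHLH", unique(hits$pattern))
hitmat <- gene_family_hit_matrix(hits, families, universe)
enr <- community_family_enrichment(partition, hitmat,
                                   q_max = 0.01, p_max = 0.05)
utils::write.table(enr, "results/family_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("%d (community x family) tests; %d significant at BH q <= 0.01\n",
            sum(!is.na(enr$pvalue)), sum(enr$significant_q)))
print(utils::head(enr[, c("community", "family", "a", "b", "pvalue", "qvalue",
                          "log2_enrichment")], 5), digits = 3)
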