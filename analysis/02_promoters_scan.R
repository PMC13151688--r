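#!/usr/bin/env Rscript
# Step 2: extract 2000-bp promoter windows from the corpus and scan them
# with the planted degenerate pattern (mismatch-free, both strands) and a
# G-box position weight matrix with exact match p-values; rank candidate
# target genes by best significance.

library(coexreg)

dir.create("results", showWarnings = FALSE)
genome <- read_genome_fasta("results/bundle/genome.fasta")
genes <- parse_gff3_genes("results/bundle/genes.gff3")
promoters <- extract_promoters(genes, genome, upstream_len = 2000)

write_promoters_bed(promoters, "results/promoters.bed")
write_fasta(stats::setNames(promoters$sequence, promoters$gene_id),
            "results/promoters.fasta")
counts <- chromosome_counts(genes)
utils::write.table(data.frame(chrom = names(counts), n_genes = counts),
                   "results/chromosome_counts.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

pattern <- readLines("results/bundle/motifs.txt")[1]
iupac_hits <- scan_iupac(promoters, pattern)
utils::write.table(iupac_hits, "results/iupac_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

pwm <- gbox_pwm()
pwm_hits <- scan_pwm(promoters, pwm, pvalue_max = 1e-5)
utils::write.table(pwm_hits, "results/pwm_hits.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

ranking <- rank_target_genes(pwm_hits)
utils::write.table(ranking, "results/target_ranking.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("%d promoters scanned (%s)\n", nrow(promoters), pattern))
cat(sprintf(" degenerate hits: %d in %d genes\n", nrow(iupac_hits),
            length(unique(iupac_hits$seq_id))))
cat(sprintf(" PWM hits at p<=1e-5: %d in %d genes (motif %s, consensus %s)\n",
            nrow(pwm_hits), length(unique(pwm_hits$seq_id)),
            pwm$motif_id, pwm_to_iupac(pwm)))
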