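#!/usr/bin/env Rscript
# Step 1: emit the seeded synthetic study corpus with its ground truth.
#
# The bundle stands in for the study's external inputs: a genome +
# annotation whose target-gene promoters carry a planted G-box, a
# module-structured RNA-seq count matrix with planted size factors and
# differential expression, and a qPCR Cq table with known fold changes.

library(coexreg)

out_dir <- "results/bundle"
cfg <- synthetic_config(seed = 42)
bundle <- synth_truth_bundle(cfg, out_dir, overwrite = TRUE)

cat("Synthetic corpus written to", out_dir, "\n")
cat(sprintf(" genome: %d chromosomes, %s bp total\n",
            length(bundle$genome),
            format(sum(nchar(bundle$genome)), big.mark = ",")))
cat(sprintf(" genes: %d (%d module genes in %d modules, %d DE genes, %d motif targets)\n",
            nrow(bundle$genes), length(cfg$module_membership), cfg$n_modules,
            length(cfg$de_labels), length(cfg$target_gene_ids)))
cat(sprintf(" samples: %d control + %d treated;  qPCR: %d Cq rows\n",
            sum(bundle$groups == "control"), sum(bundle$groups == "treated"),
            nrow(bundle$cq)))
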