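#!/usr/bin/env Rscript
# Stage 1 — synthetic cohorts.
# Generates the rat sequencing-subset count matrix (4/5/5/5 animals,
# 748 miRNAs, planted marker effects from the printed RT-qPCR fold
# changes), the matching Cq table (reference miR-28-3p, hemolysis pair
# miR-23a/miR-451), and writes everything under results/analysis/data.

suppressPackageStartupMessages(library(mirtbi))
seed <- 7L
out <- "results/analysis/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- default_rat_design("sequencing", seed = seed)
sim <- simulate_count_matrix(design)
write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write.table(sim$meta, file.path(out, "sample_meta.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

assays <- c("miR-9a-3p", "miR-136-3p", "miR-434-3p", "miR-28-3p",
            "miR-23a", "miR-451")
hemolyzed <- sim$meta$sample_id[sim$meta$a414 > 0.25]
cq <- simulate_cq_table(sim$meta, assays,
                        effects = design$effect_table[paste0("rno-", assays[1:3])],
                        hemolyzed = hemolyzed, seed = seed + 1L)
write.table(as.data.frame(cq), file.path(out, "cq_table.csv"), sep = ",",
            quote = FALSE, row.names = FALSE)

cat(sprintf("cohort: %d miRNAs x %d samples (%s)\n",
            nrow(sim$counts$counts), ncol(sim$counts$counts),
            paste(table(sim$meta$group)[unique(sim$meta$group)],
                  collapse = "/")))
cat(sprintf("planted hemolysis (a414 > 0.25): %d/%d samples\n",
            length(hemolyzed), nrow(sim$meta)))
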