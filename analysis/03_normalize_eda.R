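#!/usr/bin/env Rscript
# Stage 3 — normalization and exploratory structure.
# Counts-per-million by the miRNA-mapped totals, the count >= 1 in >= 80%
# of samples prevalence filter, PCA / Spearman / complete-linkage
# clustering, per-group detection Venn counts, and the reference-assay
# stability ranking on the planted PCR panel.

suppressPackageStartupMessages(library(mirtbi))
dat <- "results/analysis/data"
out <- "results/analysis"
cm <- read_count_matrix(file.path(dat, "counts.tsv"))
meta <- read.delim(file.path(dat, "sample_meta.tsv"))
cq <- read.delim(file.path(dat, "cq_table.csv"), sep = ",")

cpm_mat <- cpm(cm)
filt <- prevalence_filter(cm)
cat(sprintf("prevalence filter: %d of %d miRNAs retained\n",
            nrow(filt$counts), nrow(cm$counts)))

eda <- eda_summary(cpm_mat, meta$group)
print(eda)
cat(sprintf("PC1+PC2 explain %.0f%% of the variance\n",
            100 * sum(eda$explained_variance[1:2])))

# stability ranking over the PCR panel assays measured in the cohort
wide <- do.call(rbind, lapply(split(cq, cq$assay), function(d) {
  setNames(d$cq[match(meta$sample_id, d$sample_id)], meta$sample_id)
}))
stab <- normfinder_stability(2^-wide, meta$group)
cat("stability ranking (most stable first):\n")
print(stab, row.names = FALSE, digits = 3)

write.table(data.frame(mirna_id = rownames(cpm_mat), cpm_mat,
                       check.names = FALSE),
            file.path(out, "cpm.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(stab, file.path(out, "stability.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(explained_variance = eda$explained_variance,
       venn = eda$venn[c("per_group", "n_detected", "n_shared_all",
                         "shared_percent")]),
  file.path(out, "eda_summary.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote cpm.tsv, stability.tsv, eda_summary.json\n")
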