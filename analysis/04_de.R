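#!/usr/bin/env Rscript
# Stage 4 — differential expression.
# Simplified NB Wald test (median-of-ratios size factors, method-of-moments
# dispersion, t-referenced Wald statistic, BH FDR < 0.05) for each pairwise
# group contrast of the rat cohort.

suppressPackageStartupMessages(library(mirtbi))
dat <- "results/analysis/data"
out <- "results/analysis"
cm <- read_count_matrix(file.path(dat, "counts.tsv"))
meta <- read.delim(file.path(dat, "sample_meta.tsv"))

contrasts <- list(c("sham", "naive"), c("mTBI", "naive"), c("sTBI", "naive"),
                  c("mTBI", "sham"), c("sTBI", "sham"), c("sTBI", "mTBI"))
tabs <- lapply(contrasts, function(ct) {
  res <- nb_wald_test(cm, meta, ct)
  print(res)
  cbind(contrast = paste(ct, collapse = "_vs_"), as.data.frame(res))
})
write.table(do.call(rbind, tabs), file.path(out, "de_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote de_results.tsv\n")
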