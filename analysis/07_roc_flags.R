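#!/usr/bin/env Rscript
# Stage 7 — diagnostics.
# Kruskal-Wallis/Mann-Whitney group comparisons, ROC with optimal cutpoints
# (maximizing sensitivity + specificity) for the rat contrasts, and the
# human cohort: mean + 1 SD elevated-subpopulation flags cross-tabulated
# with S100B > 0.1 ug/L.

suppressPackageStartupMessages(library(mirtbi))
out <- "results/analysis"
seed <- 7L
cn <- read.delim(file.path(out, "copy_numbers.tsv"))
meta <- read.delim(file.path(out, "copy_number_meta.tsv"))

cuts <- list()
for (assay in unique(cn$assay)) {
  d <- cn[cn$assay == assay, ]
  m <- meta[meta$assay == assay, ]
  v <- setNames(d$copies_per_well, d$sample_id)
  gc <- group_compare(v, m)
  cat(sprintf("%s: Kruskal-Wallis p = %.2g\n", assay, gc$kw_p))
  for (ct in list(c("mTBI", "naive"), c("sTBI", "mTBI"))) {
    cp <- optimal_cutpoint(v[m$sample_id[m$group == ct[1]]],
                           v[m$sample_id[m$group == ct[2]]],
                           comparison = ct)
    cat("  "); print(cp)
    cuts[[length(cuts) + 1L]] <- data.frame(
      assay = assay, contrast = paste(ct, collapse = "/"),
      auc = cp$auc, auc_p = cp$auc_p, cutoff = cp$cutoff,
      sensitivity = cp$sensitivity, specificity = cp$specificity)
  }
}
write.table(do.call(rbind, cuts), file.path(out, "cutpoints.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

human <- default_human_cohort("miR-9-3p", seed = seed + 30L)
fl <- flag_elevated(human$copies, human$meta, reference_group = "control",
                    k_sd = 1,
                    covariate = setNames(human$meta$s100b,
                                         human$meta$sample_id),
                    covariate_cutoff = 0.1)
cat("\nhuman miR-9-3p, elevated above control mean + 1 SD:\n")
print(fl)
jsonlite::write_json(
  list(threshold = fl$threshold, n_elevated = as.list(fl$n_elevated),
       crosstab = as.data.frame(fl$crosstab),
       n_covariate_unknown = fl$n_covariate_unknown),
  file.path(out, "elevated_flags.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote cutpoints.tsv, elevated_flags.json\n")
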