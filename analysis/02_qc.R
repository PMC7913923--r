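#!/usr/bin/env Rscript
# Stage 2 — sample-level quality control.
# Hemolysis by 414-nm absorbance (> 0.25) and by delta-Cq(miR-23a -
# miR-451) (> 5 cycles), plus Cq range checks for the endogenous and
# hemolysis assays. The two hemolysis methods are independent and may
# disagree; both flags are reported, no sample is excluded.

suppressPackageStartupMessages(library(mirtbi))
dat <- "results/analysis/data"
out <- "results/analysis"
meta <- read.delim(file.path(dat, "sample_meta.tsv"))
cq <- read.delim(file.path(dat, "cq_table.csv"), sep = ",")

abs_res <- assess_absorbance(meta)
print(abs_res)
dcq_res <- assess_dcq(cq)
cat(sprintf("delta-Cq > 5: %d/%d samples flagged\n",
            sum(dcq_res$hemolyzed_by_dcq, na.rm = TRUE), nrow(dcq_res)))

report <- build_qc_report(abs_res, cq,
                          list("miR-28-3p" = c(24, 36),
                               "miR-23a" = c(24, 36),
                               "miR-451" = c(20, 36)))
print(report)
qc_report_json(report, file.path(out, "qc_report.json"))
cat("wrote", file.path(out, "qc_report.json"), "\n")
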