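#!/usr/bin/env Rscript
# Stage 5 — nested-CV logistic-regression feature selection.
# mTBI vs naive on prevalence-filtered raw counts: leave-one-out outer
# loop, stratified 3-fold inner grid search, permutation-tested CV AUC,
# fold-averaged normalized importance, and the top-5 candidate set
# annotated with DE significance.

suppressPackageStartupMessages(library(mirtbi))
dat <- "results/analysis/data"
out <- "results/analysis"
seed <- 7L
cm <- read_count_matrix(file.path(dat, "counts.tsv"))
meta <- read.delim(file.path(dat, "sample_meta.tsv"))

filt <- prevalence_filter(cm)
keep <- meta$group %in% c("naive", "mTBI")
X <- t(filt$counts[, meta$sample_id[keep], drop = FALSE])
y <- factor(meta$group[keep], levels = c("naive", "mTBI"))

grid <- hyper_grid(lambda = c(0.1, 1), n_features = c(2, 5, 10),
                   method = "fscore", penalty = c("l1", "l2"))
pt <- permutation_test(X, y, grid, n_permutations = 99, seed = seed,
                       positive = "mTBI")
print(pt$observed)

de <- nb_wald_test(cm, meta, c("mTBI", "naive"))
cand <- select_candidates(pt$observed, de, top_k = 5)
cat("top-5 candidates (de_significant marks the validation-priority set):\n")
print(as.data.frame(cand), row.names = FALSE, digits = 3)

nested_cv_json(pt$observed, file.path(out, "nested_cv.json"))
write.table(as.data.frame(cand), file.path(out, "candidates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote nested_cv.json, candidates.tsv\n")
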