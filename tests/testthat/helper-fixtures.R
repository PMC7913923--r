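# small fixtures built in code, shared across test files

toy_count_matrix <- function() {
  counts <- matrix(c(10, 0, 5,
                     2, 8, 1),
                   nrow = 3, ncol = 2,
                   dimnames = list(c("m1", "m2", "m3"), c("A", "B")))
  count_matrix(counts)
}

toy_meta <- function(groups) {
  data.frame(sample_id = names(groups), group = unname(groups))
}

# wide Cq matrix (sample x assay) to long cq_table-shaped data frame
cq_long <- function(wide) {
  df <- expand.grid(sample_id = rownames(wide), assay = colnames(wide),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$cq <- as.vector(wide)
  df
}

# simple two-group null features for mlselect tests
null_features <- function(n_per_class = 5, p = 6, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p,
              dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
  list(X = X, y = factor(rep(c("ctl", "tbi"), each = n_per_class)))
}
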