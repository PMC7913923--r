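test_that("CPM matches the per-cell definition and its edge cases", {
  # single miRNA holding the whole library
  cm <- count_matrix(matrix(10, 1, 1, dimnames = list("m", "s")),
                     mirna_mapped_total = 10)
  expect_equal(as.numeric(cpm(cm)), 1e6)

  # two equal counts split the million
  cm <- count_matrix(matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "s")))
  expect_equal(as.numeric(cpm(cm)), c(5e5, 5e5))

  # brute-force per-cell oracle on a 3x2 toy
  counts <- matrix(c(3, 0, 7, 1, 5, 4), 3, 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tot <- c(20, 15)
  cm <- count_matrix(counts, tot)
  want <- counts
  for (i in 1:3) for (j in 1:2) want[i, j] <- counts[i, j] / tot[j] * 1e6
  expect_equal(cpm(cm), want, tolerance = 1e-9)

  # in-matrix totals: columns sum to one million
  cm <- toy_count_matrix()
  expect_equal(unname(colSums(cpm(cm))), c(1e6, 1e6))

  # scale equivariance: doubling counts and totals changes nothing
  cm2 <- count_matrix(2 * cm$counts, 2 * cm$mirna_mapped_total)
  expect_equal(cpm(cm2), cpm(cm))

  expect_error(count_matrix(matrix(1, 1, 1), mirna_mapped_total = 0),
               "positive")
})

test_that("prevalence filter retains miRNAs by the ceil(fraction * n) rule", {
  mk <- function(nonzero, n = 10) {
    matrix(c(rep(1, nonzero), rep(0, n - nonzero)), 1, n,
           dimnames = list("m", sprintf("s%02d", 1:n)))
  }
  keep8 <- prevalence_filter(count_matrix(rbind(mk(8), ref = rep(5, 10))))
  expect_true("m" %in% rownames(keep8$counts))
  keep7 <- prevalence_filter(count_matrix(rbind(mk(7), ref = rep(5, 10))))
  expect_false("m" %in% rownames(keep7$counts))

  # strictest case: min_fraction 1 drops any miRNA with a zero
  cmz <- count_matrix(rbind(mk(9), ref = rep(5, 10)))
  expect_false("m" %in%
                 rownames(prevalence_filter(cmz, min_fraction = 1)$counts))

  expect_error(prevalence_filter(toy_count_matrix(), min_fraction = 0),
               "min_fraction")
})

test_that("prevalence filter agrees with a brute-force row scan and is idempotent", {
  set.seed(42)
  counts <- matrix(rnbinom(50 * 19, mu = 5, size = 2), 50, 19,
                   dimnames = list(sprintf("m%02d", 1:50),
                                   sprintf("s%02d", 1:19)))
  cm <- count_matrix(counts, colSums(counts) + 100)
  filt <- prevalence_filter(cm, min_count = 1, min_fraction = 0.8)
  keep_oracle <- character()
  for (i in seq_len(nrow(counts))) {
    n_present <- 0
    for (j in seq_len(ncol(counts))) {
      if (counts[i, j] >= 1) n_present <- n_present + 1
    }
    if (n_present >= ceiling(0.8 * ncol(counts))) {
      keep_oracle <- c(keep_oracle, rownames(counts)[i])
    }
  }
  expect_gt(length(keep_oracle), 0)
  expect_identical(rownames(filt$counts), keep_oracle)
  expect_identical(prevalence_filter(filt)$counts, filt$counts)
})

test_that("2^-deltaCt relative expression follows its closed form", {
  wide <- matrix(c(25, 22, 26, 25, 25, 25), 3, 2,
                 dimnames = list(c("s1", "s2", "s3"),
                                 c("target", "miR-28-3p")))
  rel <- delta_ct_relative(cq_long(wide))
  v <- setNames(rel$value, rel$sample_id)
  expect_equal(unname(v[c("s1", "s2", "s3")]), c(1, 8, 0.5))
  expect_true(all(rel$value > 0))

  # invariant to a per-sample constant shift of all Cq values
  shifted <- cq_long(wide + c(3, -1, 5))
  expect_equal(delta_ct_relative(shifted)$value, rel$value)

  # samples without a reference Cq are skipped with a warning
  noref <- cq_long(wide)[-4, ]  # drop s1's reference
  expect_warning(rel2 <- delta_ct_relative(noref), "s1")
  expect_false("s1" %in% rel2$sample_id)
})

test_that("stability ranking scores a constant assay 0 and penalizes group shifts", {
  groups <- rep(c("A", "B"), each = 3)
  x <- matrix(rnorm(12, 10), 2, 6,
              dimnames = list(c("stable", "shifted"), NULL))
  x["stable", ] <- 7
  x["shifted", ] <- x["shifted", ] + 5 * (groups == "B")
  res <- normfinder_stability(x, groups, log2_transform = FALSE)
  expect_equal(res$assay[1], "stable")
  expect_equal(res$stability_value[res$assay == "stable"], 0)
  expect_gt(res$stability_value[res$assay == "shifted"], 0)

  expect_error(normfinder_stability(x, c("A", "A", "A", "A", "A", "B")),
               ">= 2 samples")
})

test_that("stability decomposition matches a hand variance decomposition", {
  set.seed(7)
  groups <- rep(c("g1", "g2", "g3"), times = c(3, 4, 3))
  x <- matrix(rnorm(40, 8, 1), 4, 10,
              dimnames = list(paste0("assay", 1:4), NULL))
  res <- normfinder_stability(x, groups, log2_transform = FALSE)
  for (a in rownames(x)) {
    v <- x[a, ]
    m_g <- c(mean(v[groups == "g1"]), mean(v[groups == "g2"]),
             mean(v[groups == "g3"]))
    s2_g <- c(var(v[groups == "g1"]), var(v[groups == "g2"]),
              var(v[groups == "g3"]))
    n_g <- c(3, 4, 3)
    d_g <- m_g - mean(m_g)
    expect_equal(res$inter_group_variance[res$assay == a],
                 sum(d_g^2) / 2, tolerance = 1e-8)
    expect_equal(res$intra_group_variance[res$assay == a],
                 mean(s2_g), tolerance = 1e-8)
    expect_equal(res$stability_value[res$assay == a],
                 mean(abs(d_g) + sqrt(s2_g / n_g)), tolerance = 1e-8)
  }
  expect_true(!is.unsorted(res$stability_value))
})

test_that("small-RNA input normalization computes dilution factors and CV%", {
  eq <- small_rna_input_normalize(c(a = 0.3, b = 0.3, c = 0.3))
  expect_equal(unname(eq$dilution_factors), c(1, 1, 1))
  expect_equal(eq$cv_before_percent, 0)

  two <- small_rna_input_normalize(c(a = 0.2, b = 0.4), target = 0.2)
  expect_equal(unname(two$dilution_factors), c(1, 2))
  expect_equal(two$cv_after_percent, 0)

  x <- c(0.18, 0.4, 1.21)
  got <- small_rna_input_normalize(x, target = 0.18)$cv_before_percent
  expect_equal(got, 100 * sqrt(sum((x - mean(x))^2) / 2) / mean(x),
               tolerance = 1e-9)

  expect_error(small_rna_input_normalize(c(0.2, 0.4), target = 0.3),
               "target")
})

test_that("EDA summary: PCA fractions, Spearman matrix, clustering, Venn counts", {
  set.seed(5)
  base <- matrix(rexp(6 * 1, rate = 0.01), 6, 1)
  mat <- cbind(s1 = base[, 1], s2 = base[, 1], s3 = rexp(6, 0.01),
               s4 = rexp(6, 0.01))
  rownames(mat) <- paste0("m", 1:6)
  e <- eda_summary(mat, groups = c("A", "A", "B", "B"))
  expect_equal(e$spearman["s1", "s2"], 1)
  expect_equal(e$spearman, t(e$spearman))
  expect_equal(unname(diag(e$spearman)), rep(1, 4))
  expect_equal(e$dendrogram$merge[1, ], c(-1, -2))  # identical samples merge first

  # data confined to a 1-D subspace (on the log scale the PCA runs on):
  # first component explains everything
  v <- c(1, 3, 7, 2, 5, 4)
  m1 <- 2^outer(v / 2, c(1, 1.5, 2, 2.5)) - 1
  rownames(m1) <- paste0("m", 1:6); colnames(m1) <- paste0("s", 1:4)
  e1 <- eda_summary(m1, groups = c("A", "A", "B", "B"))
  expect_equal(e1$explained_variance[1], 1, tolerance = 1e-8)

  # Venn counts against hand enumeration on a 6-miRNA, 2-group toy
  vm <- rbind(both1 = c(1, 0, 2, 0), both2 = c(0, 3, 1, 1),
              onlyA = c(4, 1, 0, 0), onlyB1 = c(0, 0, 5, 0),
              onlyB2 = c(0, 0, 0, 2), none = c(0, 0, 0, 0))
  colnames(vm) <- paste0("s", 1:4)
  ev <- eda_summary(vm, groups = c("A", "A", "B", "B"))
  expect_equal(unname(ev$venn$per_group), c(3, 4))
  expect_equal(ev$venn$n_detected, 5)
  expect_equal(ev$venn$n_shared_all, 2)
  expect_equal(ev$venn$shared_percent, round(100 * 2 / 5))

  # constant sample is reported, correlations undefined
  cmat <- cbind(s1 = c(1, 2, 3), s2 = c(2, 2, 2), s3 = c(3, 1, 2))
  rownames(cmat) <- paste0("m", 1:3)
  expect_warning(ec <- eda_summary(cmat, c("A", "A", "B")), "constant")
  expect_equal(ec$constant_samples, "s2")
})
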