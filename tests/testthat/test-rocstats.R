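# brute-force AUC: fraction of concordant (pos > neg) pairs, half for ties
auc_oracle <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# exhaustive cutpoint oracle: best sens+spec over every observed value and
# the infinities, under the >= positive rule
youden_oracle <- function(pos, neg) {
  cands <- c(-Inf, sort(unique(c(pos, neg))), Inf)
  best <- -Inf
  for (ct in cands) {
    s <- 100 * mean(pos >= ct) + 100 * mean(neg < ct)
    if (s > best) best <- s
  }
  best
}

test_that("group comparison: exact enumeration and order symmetry", {
  meta <- toy_meta(c(a1 = "A", a2 = "A", a3 = "A",
                     b1 = "B", b2 = "B", b3 = "B"))
  v <- c(a1 = 1, a2 = 2, a3 = 3, b1 = 4, b2 = 5, b3 = 6)
  gc <- group_compare(v, meta)
  pw <- gc$pairwise
  expect_equal(pw$U, 0)
  expect_equal(pw$p, 0.1)  # exact two-sided p for complete separation, n=3/3
  expect_true(gc$kw_p < 0.1)

  # swapping the argument order maps U -> n1*n2 - U with the same p
  mw_ab <- mann_whitney(v[1:3], v[4:6])
  mw_ba <- mann_whitney(v[4:6], v[1:3])
  expect_equal(mw_ba$U, 3 * 3 - mw_ab$U)
  expect_equal(mw_ba$p, mw_ab$p)

  meta_s <- rbind(meta, data.frame(sample_id = "c1", group = "C"))
  vs <- c(v, c1 = 10)
  expect_warning(gcs <- group_compare(vs, meta_s), "singleton")
  expect_equal(sort(gcs$groups), c("A", "B"))
})

test_that("Spearman correlation matches the rank formula with a t-approximation p", {
  up <- spearman_cor(1:6, c(2, 5, 9, 11, 30, 31))
  expect_equal(up$rho, 1)
  down <- spearman_cor(1:6, -c(2, 5, 9, 11, 30, 31))
  expect_equal(down$rho, -1)

  x <- c(3, 1, 4, 1.5, 5); y <- c(2, 7, 1, 8, 2.5)
  got <- spearman_cor(x, y)
  rho_hand <- cor(rank(x), rank(y))
  t_hand <- rho_hand * sqrt(3 / (1 - rho_hand^2))
  expect_equal(got$rho, rho_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df = 3), tolerance = 1e-12)

  expect_warning(const <- spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(const$rho))
})

test_that("ROC AUC: separation, ties, oracle agreement and complementarity", {
  expect_equal(roc_auc(c(4, 5, 6), c(1, 2, 3))$auc, 1)
  expect_equal(roc_auc(rep(2, 4), rep(2, 5))$auc, 0.5)

  set.seed(19)
  for (i in 1:25) {
    pos <- sample(0:8, sample(2:8, 1), replace = TRUE)
    neg <- sample(0:8, sample(2:8, 1), replace = TRUE)
    r <- roc_auc(pos, neg)
    expect_equal(r$auc, auc_oracle(pos, neg), tolerance = 1e-12)
    expect_equal(r$auc + roc_auc(neg, pos)$auc, 1, tolerance = 1e-12)
    # AUC is the pairwise Mann-Whitney U scaled by 1/(n1*n2)
    expect_equal(r$auc,
                 mann_whitney(pos, neg)$U / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
  # invariance under a strictly monotone transform of the scores
  pos <- c(0.2, 0.5, 0.9); neg <- c(0.1, 0.4, 0.45)
  expect_equal(roc_auc(exp(pos), exp(neg))$auc, roc_auc(pos, neg)$auc)

  expect_error(roc_auc(numeric(0), 1:3), "non-empty")
})

test_that("optimal cutpoint maximizes sensitivity + specificity", {
  cp <- optimal_cutpoint(c(4, 5, 6), c(1, 2, 3))
  expect_gt(cp$cutoff, 3); expect_lt(cp$cutoff, 4)
  expect_equal(cp$sensitivity, 100)
  expect_equal(cp$specificity, 100)

  deg <- optimal_cutpoint(c(2, 2), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$youden_sum, 100)

  set.seed(23)
  for (i in 1:25) {
    pos <- sample(0:12, 10, replace = TRUE)
    neg <- sample(0:12, 10, replace = TRUE)
    cp <- optimal_cutpoint(pos, neg)
    expect_equal(cp$youden_sum, youden_oracle(pos, neg), tolerance = 1e-9)
    # achieved sum dominates every candidate threshold
    for (ct in c(sort(unique(c(pos, neg))), -Inf, Inf)) {
      expect_gte(cp$youden_sum + 1e-9,
                 100 * mean(pos >= ct) + 100 * mean(neg < ct))
    }
  }
})

test_that("ROC AUC agrees with the pROC reference implementation", {
  set.seed(29)
  for (i in 1:10) {
    pos <- rnorm(8, 1); neg <- rnorm(6)
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = c(rep(1, 8), rep(0, 6)), predictor = c(pos, neg),
      direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(pos, neg)$auc, ref, tolerance = 1e-12)
  }
})

test_that("elevation flagging uses mean + k*SD of the reference, strictly", {
  meta <- toy_meta(c(r1 = "ctl", r2 = "ctl", r3 = "ctl",
                     p1 = "mTBI", p2 = "mTBI"))
  v <- c(r1 = 7, r2 = 14, r3 = 21, p1 = 22, p2 = 21)  # ref mean 14, SD 7
  fl <- flag_elevated(v, meta, "ctl", k_sd = 1)
  expect_equal(fl$threshold, 21)
  flags <- setNames(fl$flags$elevated, fl$flags$sample_id)
  expect_true(flags[["p1"]])   # 22 > 21
  expect_false(flags[["p2"]])  # 21 is not strictly above

  fl0 <- flag_elevated(v, meta, "ctl", k_sd = 0)
  expect_equal(fl0$threshold, 14)
  expect_equal(unname(fl0$n_elevated["mTBI"]), 2)

  expect_error(flag_elevated(v, toy_meta(c(r1 = "ctl", p1 = "m")), "ctl"),
               ">= 2")
})

test_that("covariate cross-tabulation matches hand enumeration", {
  meta <- toy_meta(c(r1 = "ctl", r2 = "ctl",
                     m1 = "mTBI", m2 = "mTBI", m3 = "mTBI", m4 = "mTBI"))
  v <- c(r1 = 10, r2 = 12, m1 = 30, m2 = 30, m3 = 5, m4 = 5)
  s100b <- c(r1 = NA, r2 = NA, m1 = 0.3, m2 = 0.05, m3 = 0.3, m4 = NA)
  fl <- flag_elevated(v, meta, "ctl", k_sd = 1,
                      covariate = s100b, covariate_cutoff = 0.1)
  # threshold = 11 + 1*sd(10,12) = 12.41; m1, m2 elevated
  ct <- fl$crosstab
  expect_equal(ct["elevated", "covariate_elevated"], 1)        # m1
  expect_equal(ct["elevated", "covariate_normal"], 1)          # m2
  expect_equal(ct["not_elevated", "covariate_elevated"], 1)    # m3
  expect_equal(ct["not_elevated", "covariate_normal"], 0)
  expect_equal(fl$n_covariate_unknown, 1)                      # m4
})
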