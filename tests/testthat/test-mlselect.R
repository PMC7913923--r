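small_grid <- function() {
  hyper_grid(lambda = 1, n_features = 2, method = "fscore", penalty = "l2")
}

test_that("a perfectly separating feature yields CV AUC 1 and dominant importance", {
  set.seed(2)
  X <- cbind(sep = c(1:5, 101:105) + rnorm(10, 0, 0.1),
             n1 = rnorm(10), n2 = rnorm(10), n3 = rnorm(10))
  y <- factor(rep(c("ctl", "tbi"), each = 5))
  r <- nested_cv(X, y, grid = hyper_grid(lambda = c(0.1, 1),
                                         n_features = c(1, 2),
                                         method = c("rfe", "fscore"),
                                         penalty = c("l1", "l2")),
                 seed = 3)
  expect_equal(r$cv_auc, 1)
  expect_equal(names(r$importance)[1], "sep")
  expect_equal(sum(r$importance), 1, tolerance = 1e-9)
})

test_that("nested CV on label-independent features stays near chance", {
  aucs <- vapply(1:100, function(i) {
    nf <- null_features(n_per_class = 5, p = 4, seed = 100 + i)
    nested_cv(nf$X, nf$y, grid = small_grid(), seed = i)$cv_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("nested CV is deterministic under a fixed seed and validates labels", {
  nf <- null_features(seed = 7)
  r1 <- nested_cv(nf$X, nf$y, grid = small_grid(), seed = 5)
  r2 <- nested_cv(nf$X, nf$y, grid = small_grid(), seed = 5)
  expect_identical(r1$outer_predictions, r2$outer_predictions)
  expect_identical(r1$fold_coefs, r2$fold_coefs)
  expect_identical(r1$importance, r2$importance)

  expect_error(nested_cv(nf$X, factor(rep("a", 10))), "binary")
  expect_error(nested_cv(nf$X, factor(c("a", rep("b", 9)))), ">= 2 samples")
})

test_that("held-out feature values cannot leak into the fold model", {
  nf <- null_features(n_per_class = 4, p = 5, seed = 9)
  r1 <- nested_cv(nf$X, nf$y, grid = small_grid(), seed = 11)
  X2 <- nf$X
  X2[3, ] <- 1e6  # absurd constants in the held-out row of fold 3
  r2 <- nested_cv(X2, nf$y, grid = small_grid(), seed = 11)
  expect_identical(r1$fold_coefs[3, ], r2$fold_coefs[3, ])
})

test_that("feature importance is the normalized fold average with deterministic ordering", {
  # fold 1: |coef| (a = 2, b = 0); fold 2: (a = 0, b = 4)
  # hand average: a = 1, b = 2 -> normalized 1/3 and 2/3, ordered (b, a)
  rep <- structure(list(fold_coefs = rbind(c(a = 2, b = 0),
                                           c(a = 0, b = 4))),
                   class = "nested_cv_report")
  fi <- feature_importance(rep)
  expect_equal(fi$feature, c("b", "a"))
  expect_equal(fi$importance, c(2 / 3, 1 / 3))

  one <- structure(list(fold_coefs = rbind(c(a = 0, b = 3))),
                   class = "nested_cv_report")
  fi1 <- feature_importance(one)
  expect_equal(fi1$importance[fi1$feature == "b"], 1)

  allz <- structure(list(fold_coefs = rbind(c(a = 0, b = 0))),
                    class = "nested_cv_report")
  expect_warning(fiz <- feature_importance(allz), "uniform")
  expect_equal(fiz$importance, c(0.5, 0.5))
})

test_that("permutation test: add-one formula, its floor, and significance on separable data", {
  set.seed(4)
  y <- factor(rep(c("ctl", "tbi"), each = 5))
  nf <- null_features(n_per_class = 5, p = 3, seed = 41)
  pt1 <- permutation_test(nf$X, y, grid = small_grid(), n_permutations = 10,
                          seed = 5)
  # the reported p is exactly the add-one estimator over the permuted AUCs
  expect_equal(pt1$p_value,
               (1 + sum(pt1$permuted_auc >= pt1$observed$cv_auc)) / 11)
  # the estimator can never reach zero
  expect_gte(pt1$p_value, 1 / 11)

  expect_error(permutation_test(nf$X, y, grid = small_grid(),
                                n_permutations = 0), "n_permutations")

  # strongly separable data with 199 permutations reaches p <= 0.05
  Xs <- cbind(sep = c(1:5, 101:105), n1 = rnorm(10))
  pt2 <- permutation_test(Xs, y, grid = small_grid(), n_permutations = 199,
                          seed = 6)
  expect_equal(pt2$observed$cv_auc, 1)
  expect_lte(pt2$p_value, 0.05)
})

test_that("candidate selection intersects top-k importance with DE significance", {
  coefs <- rbind(setNames(c(10, 8, 6, 4, 3, 2, 1, 0.5, 0.2, 0.1),
                          sprintf("m%02d", 1:10)))
  rep <- structure(list(fold_coefs = coefs), class = "nested_cv_report")
  de <- data.frame(mirna_id = sprintf("m%02d", 1:10),
                   significant = c(TRUE, TRUE, TRUE, rep(FALSE, 7)))
  cand <- select_candidates(rep, de, top_k = 5)
  expect_equal(nrow(cand), 5)
  expect_equal(sum(cand$de_significant), 3)
  expect_equal(cand$feature[1:3], c("m01", "m02", "m03"))

  expect_equal(nrow(select_candidates(rep, de, top_k = 0)), 0)
  expect_warning(tr <- select_candidates(rep, de, top_k = 99), "truncated")
  expect_equal(nrow(tr), 10)
})
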