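#' Hyperparameter grid for nested-CV logistic regression
#'
#' Cartesian grid over regularization strength, number of selected features,
#' feature-selection method (recursive feature elimination with step 1, or
#' a univariate F-score filter) and penalty type (L1 lasso / L2 ridge).
#'
#' @param lambda regularization strengths.
#' @param n_features candidate numbers of selected features.
#' @param method feature-selection methods, subset of `c("rfe", "fscore")`.
#' @param penalty penalty types, subset of `c("l1", "l2")`.
#' @return Data frame with one row per configuration.
#' @export
hyper_grid <- function(lambda = c(0.01, 0.1, 1, 10),
                       n_features = c(1, 2, 5, 10, 20),
                       method = c("rfe", "fscore"),
                       penalty = c("l1", "l2")) {
  expand.grid(lambda = lambda, n_features = n_features, method = method,
              penalty = penalty, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)
}

# training-set standardization statistics; computed on training rows only so
# that no information about a held-out sample leaks into the transform
.std_stats <- function(X) {
  list(mean = colMeans(X), sd = apply(X, 2, sd))
}

.standardize <- function(X, stats) {
  sweep(sweep(X, 2, stats$mean, "-"), 2, stats$sd, "/")
}

# one-way (two-class) ANOVA F statistic per feature, vectorized
.f_score <- function(X, y01) {
  n1 <- sum(y01 == 1); n0 <- sum(y01 == 0); n <- n1 + n0
  m1 <- colMeans(X[y01 == 1, , drop = FALSE])
  m0 <- colMeans(X[y01 == 0, , drop = FALSE])
  m <- colMeans(X)
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((X[y01 == 1, , drop = FALSE] -
                    matrix(m1, n1, ncol(X), byrow = TRUE))^2) +
    colSums((X[y01 == 0, , drop = FALSE] -
               matrix(m0, n0, ncol(X), byrow = TRUE))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[!is.finite(f)] <- Inf  # zero within-class variance with a mean gap
  f
}

# penalized logistic fit at one (lambda, penalty); glmnet needs >= 2
# columns, so single-feature fits are padded with a constant zero column.
# Observations are class-balance weighted: leave-one-out training sets are
# inherently imbalanced against the held-out sample's class, and an
# unweighted intercept tilts every held-out score away from its own class,
# dragging the pooled null CV AUC far below chance
.fit_logistic <- function(X, y01, lambda, penalty) {
  feats <- colnames(X)
  Xfit <- X
  if (ncol(Xfit) < 2) {
    Xfit <- cbind(Xfit, `.pad.` = 0)
  }
  w <- length(y01) / (2 * ifelse(y01 == 1, sum(y01 == 1), sum(y01 == 0)))
  fit <- suppressWarnings(glmnet::glmnet(
    Xfit, y01, family = "binomial", weights = w,
    alpha = if (penalty == "l1") 1 else 0,
    lambda = lambda * c(16, 8, 4, 2, 1),
    standardize = FALSE
  ))
  cf <- as.matrix(predict(fit, type = "coefficients", s = lambda))[, 1]
  beta <- cf[feats]
  names(beta) <- feats
  list(intercept = cf[1], beta = beta)
}

.predict_prob <- function(model, X) {
  as.numeric(stats::plogis(model$intercept +
                             X[, names(model$beta), drop = FALSE] %*% model$beta))
}

# rank-formulation AUC of scores against binary truth (1 = positive)
.score_auc <- function(scores, y01) {
  np <- sum(y01 == 1); nn <- sum(y01 == 0)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y01 == 1]) - np * (np + 1) / 2) / (np * nn)
}

# feature selection on standardized training data; returns feature names
.select_features <- function(Xs, y01, method, k, lambda, penalty) {
  k <- min(k, ncol(Xs))
  if (k == ncol(Xs)) return(colnames(Xs))
  if (method == "fscore") {
    f <- .f_score(Xs, y01)
    ord <- order(-f, colnames(Xs))
    sort(colnames(Xs)[ord[seq_len(k)]])
  } else {  # RFE, eliminating the weakest coefficient one step at a time
    feats <- colnames(Xs)
    while (length(feats) > k) {
      m <- .fit_logistic(Xs[, feats, drop = FALSE], y01, lambda, penalty)
      ab <- abs(m$beta)
      weakest <- names(ab)[ab == min(ab)]
      drop <- sort(weakest, decreasing = TRUE)[1]
      feats <- setdiff(feats, drop)
    }
    sort(feats)
  }
}

# fold-averaged |coefficient|, normalized to sum to one; descending order
# with lexicographic tie-breaking by feature id
.importance_from_coefs <- function(fold_coefs) {
  imp_raw <- colMeans(abs(fold_coefs))
  if (all(imp_raw == 0)) {
    warning("all coefficients zero in every fold; importance set uniform")
    imp <- setNames(rep(1 / length(imp_raw), length(imp_raw)),
                    names(imp_raw))
  } else {
    imp <- imp_raw / sum(imp_raw)
  }
  imp[order(-imp, names(imp))]
}

# stratified fold assignment, deterministic under the current RNG state
.stratified_folds <- function(y01, k) {
  fold <- integer(length(y01))
  for (cls in unique(y01)) {
    idx <- sample(which(y01 == cls))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# train one outer fold: zero-variance drop, inner grid search, refit;
# receives only training data, so held-out feature values cannot leak into
# standardization statistics, selection or fitting
.fit_outer_fold <- function(Xtr, ytr01, grid, inner_folds, fold_seed,
                            all_features) {
  keep <- apply(Xtr, 2, sd) > 0
  Xtr <- Xtr[, keep, drop = FALSE]
  if (ncol(Xtr) == 0) stop("no non-constant features in training fold")

  if (nrow(grid) > 1) {
    set.seed(fold_seed)
    fold <- .stratified_folds(ytr01, inner_folds)
    inner_auc <- vapply(seq_len(nrow(grid)), function(ci) {
      g <- grid[ci, ]
      scores <- rep(NA_real_, length(ytr01))
      for (f in seq_len(inner_folds)) {
        tr <- fold != f
        if (length(unique(ytr01[tr])) < 2 || !any(fold == f)) next
        st <- .std_stats(Xtr[tr, , drop = FALSE])
        ok <- st$sd > 0
        Xs <- .standardize(Xtr[tr, ok, drop = FALSE],
                           lapply(st, `[`, ok))
        sel <- .select_features(Xs, ytr01[tr], g$method, g$n_features,
                                g$lambda, g$penalty)
        m <- .fit_logistic(Xs[, sel, drop = FALSE], ytr01[tr],
                           g$lambda, g$penalty)
        Xv <- .standardize(Xtr[fold == f, ok, drop = FALSE],
                           lapply(st, `[`, ok))
        scores[fold == f] <- .predict_prob(m, Xv)
      }
      has <- !is.na(scores)
      .score_auc(scores[has], ytr01[has])
    }, numeric(1))
    inner_auc[is.na(inner_auc)] <- -Inf
    best <- which.max(inner_auc)  # ties resolve to the first grid row
  } else {
    best <- 1L
  }
  g <- grid[best, ]
  st <- .std_stats(Xtr)
  Xs <- .standardize(Xtr, st)
  sel <- .select_features(Xs, ytr01, g$method, g$n_features, g$lambda,
                          g$penalty)
  m <- .fit_logistic(Xs[, sel, drop = FALSE], ytr01, g$lambda, g$penalty)
  beta_full <- setNames(numeric(length(all_features)), all_features)
  beta_full[names(m$beta)] <- m$beta
  list(model = m, stats = st, selected = sel, config = g,
       beta_full = beta_full)
}

#' Nested leave-one-out cross-validated logistic-regression selection
#'
#' Outer loop: leave-one-out. Within each outer training set, zero-variance
#' features are dropped, features are standardized to zero mean / unit
#' variance using training statistics only, and an inner stratified
#' cross-validation grid search (over regularization strength, selection
#' method, number of features and L1/L2 penalty) maximizes the inner AUC.
#' The winning configuration is refit on the full outer training set and
#' scores the held-out sample with its predicted positive-class
#' probability. The cross-validated AUC is the rank-formulation AUC over
#' the held-out scores only.
#'
#' @param features numeric matrix, samples x features (raw counts; apply
#'   [prevalence_filter()] upstream).
#' @param labels binary factor (or coercible), one label per sample; the
#'   positive class is `positive` (default: the second factor level).
#' @param grid a [hyper_grid()] data frame.
#' @param inner_folds folds of the inner stratified CV (leave-one-out inner
#'   loops are degenerate for AUC at these sample sizes).
#' @param seed integer seed controlling the inner fold assignments.
#' @param positive label of the positive class.
#' @return An object of class `nested_cv_report`: list with `comparison`,
#'   `outer_predictions` (data frame `sample`, `label`, `score`), `cv_auc`,
#'   `importance` (named, descending, sums to one), `selected_grid` (per
#'   outer fold), `fold_coefs` (folds x features matrix of standardized
#'   coefficients), `permutation_p`/`n_permutations` (NA until
#'   [permutation_test()] is run).
#' @export
nested_cv <- function(features, labels, grid = hyper_grid(),
                      inner_folds = 3, seed = 1L, positive = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- sprintf("f%03d", seq_len(ncol(features)))
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must be binary")
  if (any(table(labels) < 2)) stop("both classes need >= 2 samples")
  if (is.null(positive)) positive <- levels(labels)[2]
  if (!positive %in% levels(labels)) stop("unknown positive class")
  y01 <- as.integer(labels == positive)
  n <- nrow(features)
  if (is.null(rownames(features))) {
    rownames(features) <- sprintf("s%03d", seq_len(n))
  }

  scores <- numeric(n)
  fold_coefs <- matrix(0, n, ncol(features),
                       dimnames = list(rownames(features), colnames(features)))
  sel_grid <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- .fit_outer_fold(features[-i, , drop = FALSE], y01[-i], grid,
                           inner_folds, fold_seed = seed + 7919L * i,
                           all_features = colnames(features))
    ok <- fit$stats$sd > 0
    Xh <- .standardize(features[i, ok, drop = FALSE],
                       lapply(fit$stats, `[`, ok))
    scores[i] <- .predict_prob(fit$model, Xh)
    fold_coefs[i, ] <- fit$beta_full
    sel_grid[[i]] <- fit$config
  }

  imp <- .importance_from_coefs(fold_coefs)

  structure(list(
    comparison = c(positive = positive,
                   negative = setdiff(levels(labels), positive)),
    outer_predictions = data.frame(sample = rownames(features),
                                   label = as.character(labels),
                                   score = scores),
    cv_auc = .score_auc(scores, y01),
    importance = imp,
    selected_grid = do.call(rbind, sel_grid),
    fold_coefs = fold_coefs,
    permutation_p = NA_real_,
    n_permutations = NA_integer_,
    seed = seed
  ), class = "nested_cv_report")
}

#' @export
print.nested_cv_report <- function(x, ...) {
  cat(sprintf("nested LOOCV %s vs %s: CV AUC %.3f",
              x$comparison[["positive"]], x$comparison[["negative"]],
              x$cv_auc))
  if (!is.na(x$permutation_p)) {
    cat(sprintf(" (permutation p = %.4g, %d permutations)",
                x$permutation_p, x$n_permutations))
  }
  cat("\ntop features by importance:\n")
  print(round(head(x$importance, 5), 4))
  invisible(x)
}

#' Permutation test for the cross-validated AUC
#'
#' Repeats the full nested CV on uniformly permuted labels and reports the
#' add-one permutation p-value
#' `p = (1 + #permuted cv_auc >= observed) / (n_permutations + 1)`.
#'
#' @inheritParams nested_cv
#' @param n_permutations number of label permutations (>= 1).
#' @return List with `p_value`, `observed` (the observed
#'   `nested_cv_report`, with its permutation fields filled in) and
#'   `permuted_auc`.
#' @export
permutation_test <- function(features, labels, grid = hyper_grid(),
                             n_permutations = 1000, inner_folds = 3,
                             seed = 1L, positive = NULL) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  obs <- nested_cv(features, labels, grid, inner_folds, seed, positive)
  perm_auc <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    set.seed(seed + 104729L * b)
    perm <- sample(labels)
    rep_b <- nested_cv(features, perm, grid, inner_folds,
                       seed = seed + 104729L * b, positive)
    perm_auc[b] <- rep_b$cv_auc
  }
  p <- (1 + sum(perm_auc >= obs$cv_auc)) / (n_permutations + 1)
  obs$permutation_p <- p
  obs$n_permutations <- as.integer(n_permutations)
  list(p_value = p, observed = obs, permuted_auc = perm_auc)
}

#' Fold-averaged normalized feature importance
#'
#' Importance of a feature is the mean over outer folds of the absolute
#' standardized logistic-regression coefficient (features eliminated in a
#' fold contribute 0 for that fold), normalized so the importances sum to
#' one, in descending order with lexicographic tie-breaking.
#'
#' @param report a `nested_cv_report`.
#' @return Data frame with `feature` and `importance`.
#' @export
feature_importance <- function(report) {
  stopifnot(inherits(report, "nested_cv_report"))
  imp <- .importance_from_coefs(report$fold_coefs)
  data.frame(feature = names(imp),
             importance = as.numeric(imp),
             row.names = NULL)
}

#' Candidate selection: top-k importance intersected with DE
#'
#' Takes the `top_k` features by importance and annotates each with whether
#' it is significant in the differential-expression results; the flagged
#' intersection is the validation-priority set.
#'
#' @param report a `nested_cv_report`.
#' @param de_results a `de_result` data frame from [nb_wald_test()].
#' @param top_k number of candidates.
#' @return An object of class `candidate_set`: data frame with `feature`,
#'   `importance`, `de_significant`.
#' @export
select_candidates <- function(report, de_results, top_k = 5) {
  imp <- feature_importance(report)
  if (top_k > nrow(imp)) {
    warning("top_k exceeds the number of features; truncated to ", nrow(imp))
    top_k <- nrow(imp)
  }
  top <- imp[seq_len(top_k), , drop = FALSE]
  sig <- de_results$mirna_id[de_results$significant]
  top$de_significant <- top$feature %in% sig
  structure(top, class = c("candidate_set", "data.frame"))
}

#' Serialize a nested-CV report to JSON
#'
#' @param report a `nested_cv_report`.
#' @param path optional output path.
#' @return JSON string, or `path` invisibly when written.
#' @export
nested_cv_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "nested_cv_report"))
  obj <- list(comparison = as.list(report$comparison),
              cv_auc = report$cv_auc,
              permutation_p = report$permutation_p,
              n_permutations = report$n_permutations,
              outer_predictions = report$outer_predictions,
              importance = as.list(report$importance),
              selected_grid = report$selected_grid)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
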