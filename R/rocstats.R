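#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()] that reports the U statistic
#' for `x` versus `y` and a two-sided p-value: exact when the combined
#' sample size is at most 20 and there are no ties, the tie-corrected normal
#' approximation (with continuity correction) otherwise.
#'
#' @param x,y numeric samples.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !ties
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Omnibus and pairwise nonparametric group comparison
#'
#' Kruskal-Wallis test (with tie correction) across all groups with at
#' least 2 samples, followed by all pairwise two-sided Mann-Whitney U
#' tests. Singleton groups are excluded with a warning.
#'
#' @param values named numeric vector, sample id -> value.
#' @param meta data frame with `sample_id` and `group`.
#' @return An object of class `group_comparison`: list with `groups`,
#'   `kw_statistic`, `kw_p` and `pairwise` (data frame `group_a`, `group_b`,
#'   `U`, `p`).
#' @export
group_compare <- function(values, meta) {
  v <- values[meta$sample_id]
  g <- meta$group[!is.na(v)]
  v <- v[!is.na(v)]
  sizes <- table(g)
  if (any(sizes < 2)) {
    warning("excluding singleton group(s): ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- g %in% names(sizes)[sizes >= 2]
    v <- v[keep]; g <- g[keep]
  }
  gs <- unique(g)
  if (length(gs) < 2) stop("at least 2 groups with >= 2 samples are required")
  kw <- kruskal.test(v, factor(g))
  pairs <- combn(gs, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    mw <- mann_whitney(v[g == a], v[g == b])
    data.frame(group_a = a, group_b = b, U = mw$U, p = mw$p)
  }))
  structure(list(groups = gs,
                 kw_statistic = unname(kw$statistic),
                 kw_p = kw$p.value,
                 pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis over %d groups: chi2 = %.3f, p = %.4g\n",
              length(x$groups), x$kw_statistic, x$kw_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation with mid-ranks for ties; the two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom. A constant input vector leaves the correlation
#' undefined (`NA`, with a warning).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("at least 3 paired observations are required")
  if (var(x) == 0 || var(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' ROC AUC with Mann-Whitney significance
#'
#' AUC is computed by the rank (Mann-Whitney) formulation with mid-rank tie
#' handling: `AUC = U / (n_pos * n_neg)`, under the convention that higher
#' values indicate the positive class. Significance of the AUC is the
#' two-sided Mann-Whitney U test.
#'
#' @param positive values of the positive class.
#' @param negative values of the negative class.
#' @return List with `auc`, `p`, `n_positive`, `n_negative`.
#' @export
roc_auc <- function(positive, negative) {
  if (length(positive) == 0 || length(negative) == 0) {
    stop("both classes must be non-empty")
  }
  r <- rank(c(positive, negative))
  np <- length(positive); nn <- length(negative)
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  mw <- mann_whitney(positive, negative)
  list(auc = u / (np * nn), p = mw$p, n_positive = np, n_negative = nn)
}

#' Optimal cutpoint maximizing sensitivity + specificity
#'
#' Candidate cutoffs are the midpoints between adjacent distinct observed
#' values, plus -Inf and +Inf. A value at or above the cutoff is classified
#' positive (the elevated-marker direction). The chosen cutoff maximizes
#' sensitivity + specificity; among ties the cutoff with the highest
#' specificity wins, and remaining ties go to the smallest cutoff. When all
#' observed values are equal the problem is degenerate (best achievable
#' sensitivity + specificity is 100) and the result is flagged.
#'
#' @inheritParams roc_auc
#' @param comparison optional label pair `c(positive_group, negative_group)`.
#' @return An object of class `cutpoint_result`: list with `comparison`,
#'   `auc`, `auc_p`, `cutoff`, `sensitivity` and `specificity` (percent),
#'   `youden_sum` (sensitivity + specificity) and `degenerate`.
#' @export
optimal_cutpoint <- function(positive, negative, comparison = NULL) {
  ra <- roc_auc(positive, negative)
  vals <- sort(unique(c(positive, negative)))
  cands <- c(-Inf, if (length(vals) > 1) (vals[-1] + vals[-length(vals)]) / 2, Inf)
  sens <- vapply(cands, function(ct) 100 * mean(positive >= ct), numeric(1))
  spec <- vapply(cands, function(ct) 100 * mean(negative < ct), numeric(1))
  total <- sens + spec
  best <- which(total == max(total))
  best <- best[spec[best] == max(spec[best])]
  best <- best[which.min(cands[best])]
  structure(list(comparison = comparison,
                 auc = ra$auc, auc_p = ra$p,
                 cutoff = cands[best],
                 sensitivity = sens[best],
                 specificity = spec[best],
                 youden_sum = total[best],
                 degenerate = length(vals) == 1),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  if (!is.null(x$comparison)) {
    cat(sprintf("%s vs %s: ", x$comparison[1], x$comparison[2]))
  }
  cat(sprintf("AUC %.3f (p = %.4g), cutoff %s: sensitivity %.0f%%, specificity %.0f%%%s\n",
              x$auc, x$auc_p, format(x$cutoff), x$sensitivity, x$specificity,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Flag samples elevated above the reference group
#'
#' A sample is flagged when its value strictly exceeds
#' `mean(reference) + k_sd * SD(reference)` (sample SD). When a covariate
#' with a clinical cutoff is supplied (e.g. S100B at 0.1 ug/L), the flags
#' are cross-tabulated against covariate elevation; samples missing the
#' covariate land in an `unknown` margin.
#'
#' @param values named numeric vector, sample id -> value.
#' @param meta data frame with `sample_id` and `group`.
#' @param reference_group label of the reference (control) group, >= 2
#'   samples.
#' @param k_sd number of SDs above the reference mean.
#' @param covariate optional named numeric vector, sample id -> covariate.
#' @param covariate_cutoff covariate elevation cutoff (strict >).
#' @return An object of class `flag_table`: list with `threshold`, `flags`
#'   (data frame `sample_id`, `group`, `value`, `elevated`,
#'   `covariate_elevated`), `n_elevated` (per group) and, with a covariate,
#'   `crosstab` (2x2 counts over non-reference samples) and
#'   `n_covariate_unknown`.
#' @export
flag_elevated <- function(values, meta, reference_group, k_sd = 1,
                          covariate = NULL, covariate_cutoff = NULL) {
  ref_ids <- meta$sample_id[meta$group == reference_group]
  ref <- values[ref_ids]
  ref <- ref[!is.na(ref)]
  if (length(ref) < 2) stop("reference group needs >= 2 samples")
  thr <- mean(ref) + k_sd * sd(ref)
  v <- values[meta$sample_id]
  flags <- data.frame(sample_id = meta$sample_id,
                      group = meta$group,
                      value = as.numeric(v),
                      elevated = as.numeric(v) > thr)
  out <- list(threshold = thr, reference_group = reference_group, k_sd = k_sd)
  if (!is.null(covariate)) {
    if (is.null(covariate_cutoff)) stop("covariate_cutoff required with a covariate")
    cv <- covariate[meta$sample_id]
    flags$covariate_elevated <- as.numeric(cv) > covariate_cutoff
    nonref <- flags$group != reference_group
    known <- nonref & !is.na(flags$covariate_elevated) & !is.na(flags$elevated)
    ct <- table(factor(flags$elevated[known], levels = c(TRUE, FALSE),
                       labels = c("elevated", "not_elevated")),
                factor(flags$covariate_elevated[known], levels = c(TRUE, FALSE),
                       labels = c("covariate_elevated", "covariate_normal")))
    out$crosstab <- ct
    out$n_covariate_unknown <- sum(nonref & is.na(flags$covariate_elevated))
  }
  out$flags <- flags
  out$n_elevated <- tapply(flags$elevated, flags$group,
                           function(x) sum(x, na.rm = TRUE))
  structure(out, class = "flag_table")
}

#' @export
print.flag_table <- function(x, ...) {
  cat(sprintf("elevated threshold (%s mean + %g SD): %.3g\n",
              x$reference_group, x$k_sd, x$threshold))
  print(x$n_elevated)
  if (!is.null(x$crosstab)) print(x$crosstab)
  invisible(x)
}
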