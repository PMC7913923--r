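#' Median-of-ratios size factors
#'
#' Library-size normalization for count data: the reference for each miRNA
#' is its geometric mean across samples (computed over miRNAs with
#' all-positive counts), and each sample's size factor is the median of its
#' count/reference ratios. When no miRNA has all-positive counts the
#' geometric means fall back to the positive subset of each row, with a
#' warning.
#'
#' @param cm a [count_matrix].
#' @return Named positive numeric vector, one size factor per sample.
#' @export
size_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  counts <- cm$counts
  allpos <- rowSums(counts == 0) == 0
  if (any(allpos)) {
    use <- counts[allpos, , drop = FALSE]
    geo <- exp(rowMeans(log(use)))
  } else {
    warning("no miRNA with all-positive counts; using positive-subset geometric means")
    pos_geo <- apply(counts, 1, function(r) {
      if (any(r > 0)) exp(mean(log(r[r > 0]))) else NA_real_
    })
    use <- counts[!is.na(pos_geo), , drop = FALSE]
    geo <- pos_geo[!is.na(pos_geo)]
  }
  sf <- apply(use, 2, function(col) {
    r <- col / geo
    median(r[is.finite(r) & r > 0])
  })
  if (any(!is.finite(sf) | sf <= 0)) stop("could not compute positive size factors")
  sf
}

#' Negative-binomial Wald test for differential expression
#'
#' An intentionally simplified NB pipeline: counts are normalized by
#' median-of-ratios size factors; a per-miRNA dispersion is estimated by
#' method-of-moments, `max((var - mean)/mean^2, floor)`, pooling the
#' within-group variances; a two-group NB means model gives the log2 fold
#' change `log2(mean_A / mean_B)` for contrast `(A, B)`; and the Wald
#' statistic on the log fold change is referred to a t distribution with
#' `nA + nB - 2` degrees of freedom (a small-sample-calibrated Wald
#' reference). P-values are Benjamini-Hochberg adjusted across the tested
#' miRNAs. There is no dispersion shrinkage toward a trend, no fold-change
#' shrinkage and no independent filtering.
#'
#' miRNAs with all-zero counts in both groups are excluded from testing and
#' listed in the `excluded` attribute. A group mean of exactly zero (with
#' signal in the other group) receives a half-count continuity correction so
#' that the fold change stays finite.
#'
#' @param cm a [count_matrix].
#' @param meta data frame with `sample_id` and `group`.
#' @param contrast character pair `c(groupA, groupB)`; positive log2 fold
#'   changes mean higher in `groupA`.
#' @param alpha FDR significance level.
#' @param dispersion_floor lower bound for the method-of-moments dispersion.
#' @return Data frame of class `de_result` with `mirna_id`, `base_mean`,
#'   `log2_fold_change`, `wald_p`, `fdr`, `significant`, `direction`.
#' @export
nb_wald_test <- function(cm, meta, contrast, alpha = 0.05,
                         dispersion_floor = 1e-8) {
  stopifnot(inherits(cm, "count_matrix"), length(contrast) == 2)
  sel <- meta$group %in% contrast
  if (!all(contrast %in% meta$group)) stop("contrast groups not found in metadata")
  meta <- meta[sel, , drop = FALSE]
  idx <- match(meta$sample_id, colnames(cm$counts))
  if (anyNA(idx)) stop("metadata samples missing from the count matrix")
  sub <- count_matrix(cm$counts[, idx, drop = FALSE],
                      cm$mirna_mapped_total[idx])
  ia <- meta$group == contrast[1]
  ib <- meta$group == contrast[2]
  na <- sum(ia); nb <- sum(ib)
  if (na < 2 || nb < 2) stop("both contrast groups need >= 2 samples")

  sf <- size_factors(sub)
  norm <- sweep(sub$counts, 2, sf, "/")

  zero_both <- rowSums(sub$counts) == 0
  excluded <- rownames(sub$counts)[zero_both]
  norm <- norm[!zero_both, , drop = FALSE]

  mu_a <- rowMeans(norm[, ia, drop = FALSE])
  mu_b <- rowMeans(norm[, ib, drop = FALSE])
  # half-count continuity correction when one group is all zero
  zero_a <- mu_a == 0
  zero_b <- mu_b == 0
  mu_a[zero_a] <- 0.5 / na
  mu_b[zero_b] <- 0.5 / nb

  v_a <- apply(norm[, ia, drop = FALSE], 1, var)
  v_b <- apply(norm[, ib, drop = FALSE], 1, var)
  v_pool <- ((na - 1) * v_a + (nb - 1) * v_b) / (na + nb - 2)
  m_pool <- (mu_a + mu_b) / 2
  disp <- pmax((v_pool - m_pool) / m_pool^2, dispersion_floor)

  se <- sqrt((1 / mu_a + disp) / na + (1 / mu_b + disp) / nb)
  lfc <- log2(mu_a / mu_b)
  wald <- log(mu_a / mu_b) / se
  p <- 2 * pt(-abs(wald), df = na + nb - 2)
  fdr <- p.adjust(p, method = "BH")

  out <- data.frame(
    mirna_id = rownames(norm),
    base_mean = rowMeans(norm),
    log2_fold_change = lfc,
    wald_p = p,
    fdr = fdr,
    significant = fdr < alpha,
    direction = ifelse(lfc >= 0, "up", "down"),
    row.names = NULL
  )
  structure(out, class = c("de_result", "data.frame"),
            contrast = contrast, alpha = alpha, excluded = excluded)
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("DE %s vs %s: %d/%d significant at FDR < %g (%d up, %d down)\n",
              ct[1], ct[2], sum(x$significant), nrow(x),
              attr(x, "alpha"),
              sum(x$significant & x$direction == "up"),
              sum(x$significant & x$direction == "down")))
  invisible(as.data.frame(x))
}
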