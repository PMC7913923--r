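#' Counts-per-million normalization
#'
#' Scales each raw count by the per-sample total number of reads mapped to
#' miRNAs: `cpm[i, s] = counts[i, s] / mirna_mapped_total[s] * 1e6`. When the
#' totals are the in-matrix column sums, every column of the result sums to
#' one million; with externally supplied mapped totals (which may include
#' filtered miRNAs) column sums can be smaller.
#'
#' @param cm a [count_matrix].
#' @return Numeric matrix of CPM values with the same dimnames.
#' @export
cpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  tot <- cm$mirna_mapped_total
  if (any(tot <= 0)) {
    stop("zero miRNA-mapped total for sample(s): ",
         paste(names(tot)[tot <= 0], collapse = ", "))
  }
  sweep(cm$counts, 2, tot, "/") * 1e6
}

#' Prevalence filter on raw counts
#'
#' Retains miRNAs with a count of at least `min_count` in at least
#' `ceiling(min_fraction * n_samples)` samples (the study used count >= 1 in
#' at least 80% of samples). Row order is preserved and the per-sample
#' mapped totals are carried along unchanged.
#'
#' @param cm a [count_matrix].
#' @param min_count minimum count for a sample to count as "present".
#' @param min_fraction required fraction of samples, in (0, 1].
#' @return A filtered [count_matrix]; the retained ids are also available as
#'   `rownames(x$counts)`.
#' @export
prevalence_filter <- function(cm, min_count = 1, min_fraction = 0.8) {
  stopifnot(inherits(cm, "count_matrix"))
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  if (nrow(cm$counts) == 0 || ncol(cm$counts) == 0) {
    stop("cannot filter an empty count matrix")
  }
  need <- ceiling(min_fraction * ncol(cm$counts))
  keep <- rowSums(cm$counts >= min_count) >= need
  count_matrix(cm$counts[keep, , drop = FALSE], cm$mirna_mapped_total)
}

#' Relative quantification by 2^-deltaCt
#'
#' Expresses each target assay relative to the endogenous reference assay in
#' the same sample: `value = 2^-(Cq_target - Cq_reference)`. Samples without
#' a reference Cq are skipped with a warning. Values are strictly positive
#' and invariant to adding a constant to all Cq values of a sample.
#'
#' @param cq a `cq_table` (long data frame `sample_id`, `assay`, `cq`).
#' @param reference_assay endogenous normalizer (default the most stable
#'   endogenous miRNA of the study, miR-28-3p).
#' @return Data frame with `sample_id`, `assay`, `value` for all non-reference
#'   assays.
#' @export
delta_ct_relative <- function(cq, reference_assay = "miR-28-3p") {
  stopifnot(is.data.frame(cq), all(c("sample_id", "assay", "cq") %in% names(cq)))
  ref <- cq[cq$assay == reference_assay, ]
  missing_ref <- setdiff(unique(cq$sample_id), ref$sample_id)
  if (length(missing_ref)) {
    warning("no reference Cq for sample(s), skipped: ",
            paste(missing_ref, collapse = ", "))
  }
  tgt <- cq[cq$assay != reference_assay & cq$sample_id %in% ref$sample_id, ]
  ref_cq <- ref$cq[match(tgt$sample_id, ref$sample_id)]
  data.frame(sample_id = tgt$sample_id,
             assay = tgt$assay,
             value = 2^-(tgt$cq - ref_cq),
             row.names = NULL)
}

#' Reference-assay stability ranking (NormFinder-style)
#'
#' Model-based decomposition of each assay's variation into an inter-group
#' component (variance of the group means around their grand mean) and an
#' intra-group component (within-group sample variance), combined into a
#' single stability value: the mean over groups of
#' `|group deviation| + sqrt(within-group variance / n_g)`. Lower is more
#' stable; an assay constant across all samples scores exactly 0. By default
#' the input is log2(x + 1) transformed, matching the approximately additive
#' noise model the decomposition assumes; raw mode reproduces the scale
#' obtained when the algorithm is run directly on read counts.
#'
#' @param data numeric matrix, assays in rows, samples in columns.
#' @param groups group label per sample.
#' @param log2_transform apply log2(x + 1) before the decomposition.
#' @return Data frame (one row per assay, most stable first) with
#'   `assay`, `intra_group_variance`, `inter_group_variance`,
#'   `stability_value`.
#' @export
normfinder_stability <- function(data, groups, log2_transform = TRUE) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("at least 2 assays are required")
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(data))
  sizes <- table(groups)
  if (length(sizes) < 2) stop("at least 2 groups are required")
  if (any(sizes < 2)) {
    stop("every group needs >= 2 samples; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (log2_transform) data <- log2(data + 1)
  gs <- names(sizes)
  res <- lapply(seq_len(nrow(data)), function(i) {
    x <- data[i, ]
    m_g <- vapply(gs, function(g) mean(x[groups == g]), numeric(1))
    v_g <- vapply(gs, function(g) var(x[groups == g]), numeric(1))
    d_g <- m_g - mean(m_g)
    data.frame(
      assay = rownames(data)[i],
      intra_group_variance = mean(v_g),
      inter_group_variance = sum(d_g^2) / (length(gs) - 1),
      stability_value = mean(abs(d_g) + sqrt(v_g / as.numeric(sizes[gs])))
    )
  })
  out <- do.call(rbind, res)
  out[order(out$stability_value, out$assay), , drop = FALSE]
}

#' Small-RNA input concentration normalization
#'
#' Dilutes every sample to a common target concentration before reverse
#' transcription, so that equal small-RNA masses enter each reaction:
#' `factor = concentration / target` (>= 1). Reports the percent coefficient
#' of variation of the concentrations before and after normalization.
#'
#' @param concentrations named positive numeric, ng/uL per sample.
#' @param target target concentration; must not exceed the smallest input
#'   concentration.
#' @return List with `dilution_factors` (named), `cv_before_percent`,
#'   `cv_after_percent`.
#' @export
small_rna_input_normalize <- function(concentrations,
                                      target = min(concentrations)) {
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (target > min(concentrations)) {
    stop("target exceeds the smallest concentration; cannot up-concentrate")
  }
  factors <- concentrations / target
  list(dilution_factors = factors,
       cv_before_percent = cv_percent(concentrations),
       cv_after_percent = if (length(concentrations) >= 2)
         cv_percent(concentrations / factors) else 0)
}

#' Shared-detection percentage for a Venn summary
#'
#' Percentage (rounded to whole percent) of detected miRNAs that are
#' detected in every group.
#'
#' @param n_shared number detected in all groups.
#' @param n_detected total number detected in at least one group.
#' @return Integer percent.
#' @export
shared_detection_percent <- function(n_shared, n_detected) {
  stopifnot(n_detected > 0, n_shared >= 0, n_shared <= n_detected)
  round(100 * n_shared / n_detected)
}

#' Exploratory summary: PCA, Spearman correlation, clustering, Venn counts
#'
#' PCA is run on log2(x + 1)-transformed values with feature centering
#' (samples as observations); explained-variance fractions are reported per
#' component. Pairwise sample Spearman correlations use mid-ranks;
#' correlations involving a constant sample are undefined and reported as
#' such. Samples are clustered by complete linkage on the distance 1 - rho.
#' Venn counts treat a miRNA as detected in a group when its value is > 0 in
#' at least one sample of that group.
#'
#' @param mat numeric matrix (e.g. CPM), miRNAs in rows, samples in columns.
#' @param groups group label per sample.
#' @return An object of class `eda_summary`: list with
#'   `explained_variance` (fractions per component), `spearman` (sample
#'   correlation matrix), `constant_samples`, `dendrogram` (hclust),
#'   `venn` (per-group detected counts, `n_detected`, `n_shared_all`,
#'   `shared_percent`).
#' @export
eda_summary <- function(mat, groups) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stop("at least 3 samples are required")
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(mat))

  lg <- log2(mat + 1)
  keep <- apply(lg, 1, function(r) var(r) > 0)
  pc <- prcomp(t(lg[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)

  const <- apply(mat, 2, function(x) var(x) == 0)
  rho <- suppressWarnings(cor(mat, method = "spearman"))
  diag(rho) <- 1
  if (any(const)) {
    warning("constant sample vector(s): ",
            paste(colnames(mat)[const], collapse = ", "),
            "; their correlations are undefined")
  }
  d <- 1 - rho
  d[is.na(d)] <- 1  # undefined correlations get maximal distance for clustering
  hc <- hclust(as.dist(d), method = "complete")

  gs <- unique(groups)
  detected <- lapply(gs, function(g) {
    rownames(mat)[rowSums(mat[, groups == g, drop = FALSE] > 0) >= 1]
  })
  names(detected) <- gs
  any_det <- unique(unlist(detected))
  all_det <- Reduce(intersect, detected)
  venn <- list(per_group = vapply(detected, length, integer(1)),
               n_detected = length(any_det),
               n_shared_all = length(all_det),
               shared_percent = shared_detection_percent(length(all_det),
                                                        max(length(any_det), 1)),
               detected = detected)
  structure(list(explained_variance = expl,
                 spearman = rho,
                 constant_samples = colnames(mat)[const],
                 dendrogram = hc,
                 venn = venn),
            class = "eda_summary")
}

#' @export
print.eda_summary <- function(x, ...) {
  cat(sprintf("EDA: PC1 %.0f%%, PC2 %.0f%% of variance; %d/%d miRNAs (%d%%) detected in all groups\n",
              100 * x$explained_variance[1],
              100 * ifelse(length(x$explained_variance) > 1,
                           x$explained_variance[2], 0),
              x$venn$n_shared_all, x$venn$n_detected, x$venn$shared_percent))
  invisible(x)
}
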