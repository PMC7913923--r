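#' A single ddPCR well
#'
#' One droplet digital PCR reaction: either per-droplet fluorescence
#' amplitudes plus the calling threshold, or the already-called
#' positive/total droplet counts. Assay-specific thresholds in the study
#' were 10000 AU for miR-9a-3p and miR-434-3p and 6000 AU for miR-136-3p.
#'
#' @param sample_id sample label.
#' @param assay assay name.
#' @param replicate replicate index (>= 1).
#' @param n_positive,n_total called droplet counts (used when `amplitudes`
#'   is `NULL`).
#' @param amplitudes numeric vector of droplet fluorescence amplitudes (AU).
#' @param threshold calling threshold in AU; droplets with amplitude at or
#'   above the threshold are positive.
#' @return An object of class `droplet_well`.
#' @export
droplet_well <- function(sample_id, assay, replicate = 1L,
                         n_positive = NULL, n_total = NULL,
                         amplitudes = NULL, threshold = NULL) {
  if (replicate < 1) stop("replicate index must be >= 1")
  if (is.null(amplitudes)) {
    if (is.null(n_positive) || is.null(n_total)) {
      stop("either amplitudes or (n_positive, n_total) must be given")
    }
    if (n_total < 1) stop("n_total must be >= 1")
    if (n_positive > n_total) stop("n_positive cannot exceed n_total")
    if (n_positive < 0) stop("n_positive must be non-negative")
  } else {
    if (length(amplitudes) == 0) stop("amplitudes must be nonempty")
    if (is.null(threshold)) stop("a calling threshold is required with amplitudes")
  }
  structure(list(sample_id = sample_id, assay = assay,
                 replicate = as.integer(replicate),
                 n_positive = n_positive, n_total = n_total,
                 amplitudes = amplitudes, threshold = threshold),
            class = "droplet_well")
}

#' Absolute quantification of one well by Poisson inversion
#'
#' With `p` the positive-droplet fraction, template occupancy is Poisson
#' with rate `lambda = -ln(1 - p)` per droplet, and the copy estimate is
#' `lambda * n_total` (template molecules among the analyzed droplets). A
#' saturated well (`p = 1`) carries no quantitative information and is an
#' error. The alternative `"reaction"` mode rescales the per-droplet rate to
#' the nominal 20-uL reaction volume via the droplet volume,
#' `copies = lambda * 20 uL / droplet_nl`; it is off by default because the
#' study's printed copy magnitudes follow the per-analyzed-droplet
#' convention.
#'
#' @param well a [droplet_well].
#' @param volume_mode `"droplets"` (default) or `"reaction"`.
#' @param droplet_nl droplet volume in nanoliters (used by `"reaction"`).
#' @return Estimated copies (numeric scalar).
#' @export
quantify_well <- function(well, volume_mode = c("droplets", "reaction"),
                          droplet_nl = 0.85) {
  stopifnot(inherits(well, "droplet_well"))
  volume_mode <- match.arg(volume_mode)
  if (!is.null(well$amplitudes)) {
    n_total <- length(well$amplitudes)
    n_positive <- sum(well$amplitudes >= well$threshold)
  } else {
    n_total <- well$n_total
    n_positive <- well$n_positive
  }
  p <- n_positive / n_total
  if (p >= 1) {
    stop("saturated well (all droplets positive) for sample ", well$sample_id)
  }
  lambda <- -log(1 - p)
  switch(volume_mode,
         droplets = lambda * n_total,
         reaction = lambda * 20e3 / droplet_nl)
}

#' Mean copies over replicate wells
#'
#' The per-sample copy number is the arithmetic mean of the per-well copy
#' estimates over the replicates (the study ran duplicates).
#'
#' @param wells list of [droplet_well] objects for one (sample, assay).
#' @param ... passed to [quantify_well()].
#' @return A one-row data frame with `sample_id`, `assay`, `copies_per_well`,
#'   `n_replicates`.
#' @export
summarize_replicates <- function(wells, ...) {
  stopifnot(length(wells) >= 1)
  assays <- unique(vapply(wells, `[[`, character(1), "assay"))
  samples <- unique(vapply(wells, `[[`, character(1), "sample_id"))
  if (length(assays) != 1) stop("mixed assays in one replicate set: ",
                                paste(assays, collapse = ", "))
  if (length(samples) != 1) stop("mixed samples in one replicate set: ",
                                 paste(samples, collapse = ", "))
  copies <- vapply(wells, quantify_well, numeric(1), ...)
  data.frame(sample_id = samples, assay = assays,
             copies_per_well = mean(copies),
             n_replicates = length(wells))
}

#' Copy-number table for a whole cohort of wells
#'
#' Groups wells by (sample, assay) and applies [summarize_replicates()].
#'
#' @param wells list of [droplet_well] objects.
#' @param ... passed to [quantify_well()].
#' @return Data frame, one row per (sample, assay).
#' @export
quantify_cohort <- function(wells, ...) {
  key <- vapply(wells, function(w) paste(w$sample_id, w$assay, sep = "\r"),
                character(1))
  out <- lapply(split(wells, key), summarize_replicates, ...)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(match(out$sample_id, unique(out$sample_id))), , drop = FALSE]
}

#' Fold change between group mean copy numbers
#'
#' Ratio of arithmetic group means for contrast `(A, B)`, reported to one
#' decimal as printed in the study's figures.
#'
#' @param copies data frame with `sample_id` and `copies_per_well` (e.g.
#'   from [quantify_cohort()]), or a named numeric vector.
#' @param meta data frame with `sample_id` and `group`.
#' @param contrast character pair `c(groupA, groupB)`; the reported value is
#'   mean(A)/mean(B).
#' @param digits rounding used for the reported fold value (round-half-up,
#'   the usual reporting convention; base R's round-half-even would turn a
#'   ratio of exactly 5.05 into 5.0 rather than the reported 5.1).
#' @return Rounded fold change; the unrounded ratio and the two group means
#'   are attached as attributes `ratio` and `group_means`.
#' @export
group_fold_change <- function(copies, meta, contrast, digits = 1) {
  if (is.data.frame(copies)) {
    copies <- setNames(copies$copies_per_well, copies$sample_id)
  }
  stopifnot(length(contrast) == 2)
  va <- copies[meta$sample_id[meta$group == contrast[1]]]
  vb <- copies[meta$sample_id[meta$group == contrast[2]]]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) == 0 || length(vb) == 0) stop("both contrast groups must be non-empty")
  ma <- mean(va); mb <- mean(vb)
  if (mb == 0) stop("zero denominator group mean for ", contrast[2])
  scale <- 10^digits
  structure(floor(ma / mb * scale + 0.5) / scale,
            ratio = ma / mb,
            group_means = setNames(c(ma, mb), contrast))
}

#' Percent coefficient of variation
#'
#' `100 * sample SD / mean` (n - 1 denominator in the SD).
#'
#' @param values numeric vector, length >= 2.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("cv_percent needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("cv_percent undefined for zero mean")
  100 * sd(values) / m
}

#' Write / read droplet wells as long-format CSV
#'
#' Columns: `sample_id`, `assay`, `replicate`, `n_positive`, `n_total`,
#' `threshold`. Amplitude-level wells are called at their threshold before
#' writing, so the text representation stays small.
#'
#' @param wells list of [droplet_well] objects.
#' @param path file path.
#' @return `write_droplet_csv` returns `path` invisibly; `read_droplet_csv`
#'   returns a list of [droplet_well] objects.
#' @export
write_droplet_csv <- function(wells, path) {
  rows <- lapply(wells, function(w) {
    if (!is.null(w$amplitudes)) {
      data.frame(sample_id = w$sample_id, assay = w$assay,
                 replicate = w$replicate,
                 n_positive = sum(w$amplitudes >= w$threshold),
                 n_total = length(w$amplitudes),
                 threshold = w$threshold)
    } else {
      data.frame(sample_id = w$sample_id, assay = w$assay,
                 replicate = w$replicate,
                 n_positive = w$n_positive, n_total = w$n_total,
                 threshold = if (is.null(w$threshold)) NA else w$threshold)
    }
  })
  write.table(do.call(rbind, rows), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_droplet_csv
#' @export
read_droplet_csv <- function(path) {
  df <- read.delim(path, sep = ",")
  lapply(seq_len(nrow(df)), function(i) {
    droplet_well(sample_id = df$sample_id[i], assay = df$assay[i],
                 replicate = df$replicate[i],
                 n_positive = df$n_positive[i], n_total = df$n_total[i],
                 threshold = if (is.na(df$threshold[i])) NULL else df$threshold[i])
  })
}
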