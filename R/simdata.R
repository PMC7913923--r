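#' Simulation design for a synthetic plasma miRNA cohort
#'
#' Describes the statistical structure of a cohort: group labels and sizes,
#' the number of miRNAs, a negative-binomial count model (log2 baseline
#' abundance, between-miRNA abundance spread, NB size parameter), per-sample
#' library sizes and planted per-group log2 fold effects.
#'
#' @param group_names character vector of group labels.
#' @param group_sizes positive integers, one per group.
#' @param n_mirnas number of miRNAs to simulate; must be at least the number
#'   of miRNAs keyed in `effect_table`.
#' @param baseline_log2_mean log2 of the typical per-miRNA mean count at the
#'   reference library size.
#' @param baseline_log2_sd between-miRNA spread of log2 mean abundance.
#' @param dispersion NB size parameter shared across miRNAs (larger = closer
#'   to Poisson; size 10 corresponds to a dispersion alpha of 0.1).
#' @param library_size_range pair `c(low, high)` of per-sample miRNA-mapped
#'   totals, drawn uniformly; expected counts scale with the drawn total
#'   relative to the midpoint of the range.
#' @param effect_table named list: miRNA id -> named numeric vector of
#'   per-group log2 fold effects relative to the first (reference) group.
#' @param seed integer seed making the whole cohort reproducible.
#' @return An object of class `sim_design`.
#' @export
sim_design <- function(group_names, group_sizes, n_mirnas,
                       baseline_log2_mean = 7, baseline_log2_sd = 2,
                       dispersion = 10,
                       library_size_range = c(8e5, 1.2e6),
                       effect_table = list(), seed = 1L) {
  if (length(group_names) != length(group_sizes)) {
    stop("group_names and group_sizes must have the same length")
  }
  if (any(group_sizes < 1)) stop("all group sizes must be >= 1")
  if (n_mirnas < length(effect_table)) {
    stop("n_mirnas must be at least the number of effect miRNAs")
  }
  if (dispersion <= 0) stop("dispersion (NB size) must be positive")
  if (length(library_size_range) != 2 ||
      any(library_size_range <= 0) ||
      library_size_range[1] > library_size_range[2]) {
    stop("library_size_range must be a positive pair low <= high")
  }
  bad <- vapply(effect_table, function(e) {
    is.null(names(e)) || !all(names(e) %in% group_names)
  }, logical(1))
  if (any(bad)) stop("effect_table entries must be named by group")
  structure(
    list(group_names = as.character(group_names),
         group_sizes = as.integer(group_sizes),
         n_mirnas = as.integer(n_mirnas),
         baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd,
         dispersion = dispersion,
         library_size_range = library_size_range,
         effect_table = effect_table,
         seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' Printed ddPCR group-mean copy numbers used as planted truths
#'
#' Mean miRNA copies per 20-uL ddPCR reaction well for the validated markers,
#' as reported for the rat lateral fluid-percussion cohort and the human
#' cohort (unnormalized RNA input). These means parameterize the default
#' synthetic cohorts so that simulated copy-number data carry the same group
#' structure that the study reports.
#'
#' @param cohort `"rat"` or `"human"`.
#' @return A data frame with one row per assay and one column per group;
#'   entries are mean copies/20-uL well (NA where no mean was reported).
#' @export
ddpcr_reference_means <- function(cohort = c("rat", "human")) {
  cohort <- match.arg(cohort)
  if (cohort == "rat") {
    data.frame(
      assay = c("miR-9a-3p", "miR-136-3p", "miR-434-3p"),
      naive = c(4.6, 6.0, 6.2),
      sham  = c(5.1, 12.2, 15.9),
      mTBI  = c(19.2, 16.7, 28.7),
      sTBI  = c(118.8, 30.3, 87.0),
      row.names = NULL
    )
  } else {
    data.frame(
      assay = c("miR-9-3p", "miR-136-3p"),
      control = c(31, 380),
      mTBI    = c(57, 859),
      sTBI    = c(302, NA),
      row.names = NULL
    )
  }
}

#' Printed RT-qPCR fold changes of the validated markers versus naive
#'
#' Whole-cohort 2^-dCt fold changes (relative to the naive group) for the
#' three validated markers, as reported for the rat cohort. These are the
#' expression-level effects the count generator plants: unlike ddPCR
#' copies/well (whose cDNA dilutions differ between assays), the 2^-dCt
#' ratios are on a common relative-expression scale.
#'
#' @return Data frame with one row per assay and columns `sham`, `mTBI`,
#'   `sTBI` holding fold changes versus naive.
#' @export
rtqpcr_reference_folds <- function() {
  data.frame(
    assay = c("miR-9a-3p", "miR-136-3p", "miR-434-3p"),
    sham = c(2.4, 2.4, 3.8),
    mTBI = c(14.8, 4.3, 7.1),
    sTBI = c(65.9, 9.7, 17.2),
    row.names = NULL
  )
}

#' Default synthetic rat cohort design
#'
#' Mirrors the study design: groups naive/sham/mTBI/sTBI with n = 4/5/5/5 in
#' the sequencing subset and n = 5/8/10/8 in the whole cohort. The three
#' validated markers are planted with per-group log2 effects taken from the
#' printed whole-cohort RT-qPCR fold changes ([rtqpcr_reference_folds()]);
#' two further candidates are planted at low abundance with a moderate
#' effect, mimicking the low-count machine-learning hits that failed PCR
#' validation.
#'
#' @param cohort `"sequencing"` (n = 4/5/5/5) or `"whole"` (n = 5/8/10/8).
#' @param n_mirnas number of miRNAs; the default matches the 748 detected.
#' @param seed integer seed.
#' @return A [sim_design].
#' @export
default_rat_design <- function(cohort = c("sequencing", "whole"),
                               n_mirnas = 748, seed = 1L) {
  cohort <- match.arg(cohort)
  sizes <- if (cohort == "sequencing") c(4L, 5L, 5L, 5L) else c(5L, 8L, 10L, 8L)
  ref <- rtqpcr_reference_folds()
  eff <- lapply(seq_len(nrow(ref)), function(i) {
    log2(unlist(ref[i, c("sham", "mTBI", "sTBI")]))
  })
  names(eff) <- paste0("rno-", ref$assay)
  eff[["rno-miR-153-3p"]] <- c(sham = 0.2, mTBI = 1.0, sTBI = 1.0)
  eff[["rno-miR-15a-3p"]] <- c(sham = 0.2, mTBI = 1.0, sTBI = 1.0)
  sim_design(
    group_names = c("naive", "sham", "mTBI", "sTBI"),
    group_sizes = sizes,
    n_mirnas = n_mirnas,
    effect_table = eff,
    seed = seed
  )
}

#' Default synthetic human cohort copy numbers
#'
#' Log-normal copies-per-well for control (n = 14), mTBI (n = 15) and sTBI
#' (n = 2) with geometric group means equal to the printed human ddPCR means,
#' an elevated mTBI subpopulation, and an S100B covariate (clinical cutoff
#' 0.1 ug/L). The mTBI group is a mixture: a baseline subgroup at the control
#' level and an elevated subgroup, reproducing the reported subpopulation
#' structure rather than a uniform group shift.
#'
#' @param assay `"miR-9-3p"` or `"miR-136-3p"`.
#' @param log_sd between-subject SD on the natural-log scale.
#' @param elevated_fraction fraction of mTBI subjects in the elevated
#'   subgroup.
#' @param seed integer seed.
#' @return A list with `copies` (named vector), `meta` (data frame with
#'   `sample_id`, `group`, `s100b`).
#' @export
default_human_cohort <- function(assay = c("miR-9-3p", "miR-136-3p"),
                                 log_sd = 0.8, elevated_fraction = 0.45,
                                 seed = 1L) {
  assay <- match.arg(assay)
  ref <- ddpcr_reference_means("human")
  m <- ref[ref$assay == assay, ]
  sizes <- c(control = 14L, mTBI = 15L, sTBI = 2L)
  set.seed(seed)
  ids <- sprintf("H%02d", seq_len(sum(sizes)))
  group <- rep(names(sizes), sizes)
  n_elev <- round(elevated_fraction * sizes[["mTBI"]])
  elevated <- group == "mTBI" & seq_along(group) %in%
    (sizes[["control"]] + seq_len(n_elev))
  # geometric means: controls at control level; elevated mTBI subgroup pulled
  # up so that the group structure matches the reported subpopulation
  gm <- numeric(length(group))
  gm[group == "control"] <- m$control
  gm[group == "mTBI"] <- ifelse(elevated[group == "mTBI"],
                                m$mTBI * 2.5, m$control)
  gm[group == "sTBI"] <- if (is.na(m$sTBI)) m$mTBI else m$sTBI
  copies <- rlnorm(length(gm), meanlog = log(gm), sdlog = log_sd)
  s100b <- round(ifelse(group == "mTBI",
                        rlnorm(length(group), log(0.15), 0.5),
                        rlnorm(length(group), log(0.07), 0.4)), 3)
  s100b[group != "mTBI"] <- NA  # reported for TBI patients only
  s100b[group == "sTBI"] <- round(rlnorm(2, log(0.5), 0.3), 3)
  list(copies = setNames(copies, ids),
       meta = data.frame(sample_id = ids, group = group, s100b = s100b,
                         elevated_truth = elevated))
}

#' Simulate a raw miRNA count matrix and sample metadata
#'
#' Counts are negative binomial with a shared size parameter: each miRNA gets
#' a log2-normal baseline abundance, group effects multiply the mean by
#' 2^effect, and per-sample library sizes (drawn uniformly over the design
#' range) scale all means relative to the midpoint of the range. Per-sample
#' miRNA-mapped totals are the realized column sums. The per-sample
#' hemolysis coefficient at 414 nm is drawn so that roughly a third of the
#' samples exceed the 0.25 threshold, as observed for pooled plasma.
#'
#' @param design a [sim_design].
#' @return A list with `counts` (a [count_matrix]) and `meta` (data frame
#'   with `sample_id`, `group`, `a414`).
#' @export
simulate_count_matrix <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n_samp <- sum(design$group_sizes)
  group <- rep(design$group_names, design$group_sizes)
  ids <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", group),
                 unlist(lapply(design$group_sizes, seq_len)))
  mirna_ids <- sprintf("rno-sim-%04d", seq_len(design$n_mirnas))
  eff_names <- names(design$effect_table)
  if (length(eff_names)) mirna_ids[seq_along(eff_names)] <- eff_names

  base_mu <- 2^rnorm(design$n_mirnas, design$baseline_log2_mean,
                     design$baseline_log2_sd)
  names(base_mu) <- mirna_ids
  # planted markers are anchored at the baseline abundance so that their
  # group effects are not confounded with the abundance lottery; the two
  # unvalidated candidates sit low, below a CPM of ~10 in typical libraries
  if (length(eff_names)) {
    anchored <- 2^design$baseline_log2_mean
    base_mu[seq_along(eff_names)] <- anchored
    low <- grepl("153|15a", eff_names)
    base_mu[seq_along(eff_names)][low] <- 4
  }

  lib <- round(runif(n_samp, design$library_size_range[1],
                     design$library_size_range[2]))
  lib_scale <- lib / mean(design$library_size_range)

  log2fc <- matrix(0, design$n_mirnas, n_samp,
                   dimnames = list(mirna_ids, ids))
  for (m in eff_names) {
    e <- design$effect_table[[m]]
    log2fc[m, ] <- ifelse(group %in% names(e), e[group], 0)
  }
  mu <- base_mu * 2^log2fc * rep(lib_scale, each = design$n_mirnas)
  counts <- matrix(
    rnbinom(length(mu), mu = mu, size = design$dispersion),
    nrow = design$n_mirnas, dimnames = list(mirna_ids, ids)
  )
  a414 <- round(pmax(runif(n_samp, 0.05, 0.45) +
                       0.05 * (runif(n_samp) < 0.1), 0), 3)
  list(counts = count_matrix(counts),
       meta = data.frame(sample_id = ids, group = group, a414 = a414))
}

#' Simulate an RT-qPCR Cq table
#'
#' Cq values follow `baseline - log2(relative abundance) + noise`: a planted
#' log2 effect of +e lowers the target's Cq by e cycles. The table always
#' carries the endogenous reference assay and the hemolysis indicator pair
#' miR-23a/miR-451; samples listed in `hemolyzed` get their pair difference
#' forced above the 5-cycle hemolysis threshold.
#'
#' @param meta data frame with `sample_id` and `group`.
#' @param assays character vector of assay names; must include
#'   `reference_assay` and both members of `hemolysis_pair`.
#' @param effects named list: assay -> named numeric vector of per-group log2
#'   effects (higher abundance = lower Cq).
#' @param noise_sd Gaussian Cq noise SD in cycles.
#' @param baseline_cq scalar or named-by-assay baseline Cq.
#' @param hemolyzed sample ids whose delta-Cq(miR-23a - miR-451) is forced
#'   above 5.
#' @param reference_assay endogenous normalizer assay name.
#' @param hemolysis_pair the two hemolysis indicator assays, in the order
#'   (miR-23a, miR-451).
#' @param seed integer seed.
#' @return A long data frame of class `cq_table` with columns `sample_id`,
#'   `assay`, `cq`; attributes record the reference assay, the hemolysis
#'   pair and which samples were planted as hemolyzed.
#' @export
simulate_cq_table <- function(meta, assays, effects = list(), noise_sd = 0.5,
                              baseline_cq = 30, hemolyzed = character(),
                              reference_assay = "miR-28-3p",
                              hemolysis_pair = c("miR-23a", "miR-451"),
                              seed = 1L) {
  if (!reference_assay %in% assays) {
    stop("assays must include the reference assay ", reference_assay)
  }
  if (!all(hemolysis_pair %in% assays)) {
    stop("assays must include the hemolysis pair ",
         paste(hemolysis_pair, collapse = ", "))
  }
  set.seed(seed)
  base <- if (is.null(names(baseline_cq))) {
    setNames(rep(baseline_cq[1], length(assays)), assays)
  } else baseline_cq[assays]
  # miR-451 is abundant in plasma; keep its baseline well below miR-23a so
  # that the non-hemolyzed delta-Cq sits in the normal (< 5) range
  if (is.null(names(baseline_cq))) {
    base[hemolysis_pair[2]] <- base[hemolysis_pair[2]] - 3
  }
  grid <- expand.grid(sample_id = meta$sample_id, assay = assays,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grp <- meta$group[match(grid$sample_id, meta$sample_id)]
  eff <- numeric(nrow(grid))
  for (a in names(effects)) {
    sel <- grid$assay == a
    e <- effects[[a]]
    eff[sel] <- ifelse(grp[sel] %in% names(e), e[grp[sel]], 0)
  }
  cq <- base[grid$assay] - eff + rnorm(nrow(grid), 0, noise_sd)
  out <- data.frame(grid, cq = as.numeric(cq))
  for (s in hemolyzed) {
    i23 <- out$sample_id == s & out$assay == hemolysis_pair[1]
    i451 <- out$sample_id == s & out$assay == hemolysis_pair[2]
    if (any(i23) && any(i451)) {
      out$cq[i451] <- out$cq[i23] - (5 + 0.5 + abs(rnorm(1, 0, 1)))
    }
  }
  structure(out, class = c("cq_table", "data.frame"),
            reference_assay = reference_assay,
            hemolysis_pair = hemolysis_pair,
            hemolyzed = hemolyzed)
}

#' Simulate droplet digital PCR wells
#'
#' Template molecules partition over droplets with Poisson occupancy: a well
#' loaded with `c` copies over `n` droplets has positive-droplet count
#' Binomial(n, 1 - exp(-c/n)). Positive and negative droplets get
#' fluorescence amplitudes from two Gaussian clusters separated by the
#' calling threshold (defaults 4000/14000 around a threshold of 10000);
#' cluster draws are clamped to their side of the threshold so that
#' amplitude-based calling reproduces the simulated occupancy exactly.
#'
#' @param copies_per_well named non-negative numeric: sample id -> true mean
#'   copies per well.
#' @param assay assay name recorded on each well.
#' @param n_droplets accepted droplets per well.
#' @param amplitude_params list with `neg_mean`, `pos_mean`, `neg_sd`,
#'   `pos_sd`, `threshold`.
#' @param replicates wells per sample (the study ran duplicates).
#' @param keep_amplitudes store per-droplet amplitudes (large); when `FALSE`
#'   only the positive/total counts are stored.
#' @param seed integer seed.
#' @return A list of [droplet_well] objects.
#' @export
simulate_ddpcr_wells <- function(copies_per_well, assay = "miR-9a-3p",
                                 n_droplets = 15000,
                                 amplitude_params = list(neg_mean = 4000,
                                                         pos_mean = 14000,
                                                         neg_sd = 700,
                                                         pos_sd = 900,
                                                         threshold = 10000),
                                 replicates = 2, keep_amplitudes = FALSE,
                                 seed = 1L) {
  if (any(copies_per_well < 0)) stop("copies per well must be non-negative")
  if (n_droplets < 1) stop("n_droplets must be >= 1")
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.null(names(copies_per_well))) {
    names(copies_per_well) <- sprintf("S%02d", seq_along(copies_per_well))
  }
  set.seed(seed)
  thr <- amplitude_params$threshold
  wells <- list()
  for (s in names(copies_per_well)) {
    lambda <- copies_per_well[[s]] / n_droplets
    for (r in seq_len(replicates)) {
      n_pos <- rbinom(1, n_droplets, 1 - exp(-lambda))
      amp <- NULL
      if (keep_amplitudes) {
        neg <- pmin(rnorm(n_droplets - n_pos, amplitude_params$neg_mean,
                          amplitude_params$neg_sd), thr - 1)
        pos <- pmax(rnorm(n_pos, amplitude_params$pos_mean,
                          amplitude_params$pos_sd), thr)
        amp <- sample(c(neg, pos))
      }
      wells[[length(wells) + 1L]] <- droplet_well(
        sample_id = s, assay = assay, replicate = r,
        n_positive = if (keep_amplitudes) NULL else n_pos,
        n_total = if (keep_amplitudes) NULL else n_droplets,
        amplitudes = amp, threshold = thr
      )
    }
  }
  wells
}

#' Simulate log-normal copy-number measurements at given geometric group means
#'
#' The between-animal distribution of ddPCR copies per well is modelled as
#' log-normal around the group geometric mean; the default log-scale SD of
#' 0.3 is a configurable free parameter (the study reports no
#' between-animal variance for copy numbers).
#'
#' @param group_means named numeric: group -> geometric mean copies/well.
#' @param group_sizes named integer: group -> number of subjects.
#' @param log_sd SD on the natural-log scale.
#' @param seed integer seed.
#' @return A list with `copies` (named vector) and `meta` (data frame with
#'   `sample_id` and `group`).
#' @export
simulate_copy_numbers <- function(group_means, group_sizes, log_sd = 0.3,
                                  seed = 1L) {
  stopifnot(!is.null(names(group_means)), !is.null(names(group_sizes)),
            all(names(group_sizes) %in% names(group_means)))
  set.seed(seed)
  group <- rep(names(group_sizes), group_sizes)
  ids <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", group),
                 unlist(lapply(group_sizes, seq_len)))
  copies <- rlnorm(length(group), log(group_means[group]), log_sd)
  list(copies = setNames(as.numeric(copies), ids),
       meta = data.frame(sample_id = ids, group = group))
}
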