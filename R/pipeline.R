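#' Default pipeline configuration
#'
#' All study thresholds appear as named defaults (hemolysis 0.25 / 5 cycles,
#' prevalence count >= 1 in 80% of samples, FDR 0.05, amplitude thresholds
#' 10000/6000, mean + 1 SD elevation, S100B 0.1 ug/L), so a default run is
#' the study's analysis profile on a synthetic cohort. Simulation sizes and
#' the machine-learning grid are kept moderate so a full run completes in a
#' few minutes on one core; every stage scales up via the config.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 7L) {
  list(
    seed = as.integer(seed),
    design = list(cohort = "sequencing", n_mirnas = 300L),
    thresholds = list(
      a414 = 0.25, dcq = 5,
      prevalence_min_count = 1, prevalence_min_fraction = 0.8,
      alpha = 0.05,
      amplitude = list("miR-9a-3p" = 10000, "miR-136-3p" = 6000,
                       "miR-434-3p" = 10000),
      k_sd = 1, covariate_cutoff = 0.1
    ),
    de_contrasts = list(c("mTBI", "naive")),
    ml = list(comparison = c("mTBI", "naive"),
              lambda = c(0.1, 1), n_features = c(2, 5, 10),
              method = "fscore", penalty = c("l1", "l2"),
              inner_folds = 3L, n_permutations = 19L, top_k = 5L),
    ddpcr = list(n_droplets = 15000L, replicates = 2L, log_sd = 0.3,
                 group_sizes = c(naive = 5L, sham = 8L, mTBI = 10L,
                                 sTBI = 8L)),
    human = list(assay = "miR-9-3p", log_sd = 0.8)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  .merge_config(default_config(), user)
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  path
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full discovery pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation, hemolysis/assay QC, normalization
#' and exploratory summaries, differential expression, nested-CV feature
#' selection with permutation test, ddPCR quantification with group fold
#' changes, and ROC/cutpoint plus elevated-subpopulation flagging. Every
#' stage writes its artifacts under `outdir` and the run manifest lists all
#' written files with md5 checksums; a rerun with an identical config
#' produces byte-identical numeric outputs.
#'
#' @param config configuration list from [default_config()] or
#'   [read_pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("mirtbi")),
                   seed = config$seed, config = config,
                   stages = list(), files = list(), status = "running")
  state <- new.env(parent = emptyenv())

  record <- function(name, outputs, summary) {
    manifest$stages[[name]] <<- list(outputs = basename(outputs),
                                     summary = summary)
  }
  fail <- function(name, err) {
    manifest$status <<- "failed"
    manifest$failed_stage <<- name
    .finish_manifest(manifest, outdir)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) fail(name, e))
  }

  run_stage("simulate", function() {
    design <- default_rat_design(config$design$cohort,
                                 n_mirnas = config$design$n_mirnas,
                                 seed = config$seed)
    sim <- simulate_count_matrix(design)
    assays <- c("miR-9a-3p", "miR-136-3p", "miR-434-3p", "miR-28-3p",
                "miR-23a", "miR-451")
    hemo_planted <- sim$meta$sample_id[sim$meta$a414 > config$thresholds$a414]
    cq <- simulate_cq_table(sim$meta, assays,
                            effects = design$effect_table[
                              intersect(paste0("rno-", assays),
                                        names(design$effect_table))],
                            hemolyzed = hemo_planted,
                            seed = config$seed + 1L)
    state$sim <- sim; state$cq <- cq
    fs <- c(write_count_matrix(sim$counts, file.path(outdir, "counts.tsv")),
            .write_tsv(sim$meta, file.path(outdir, "sample_meta.tsv")),
            .write_tsv(as.data.frame(cq), file.path(outdir, "cq_table.csv")))
    record("simulate", fs,
           list(n_mirnas = nrow(sim$counts$counts),
                n_samples = ncol(sim$counts$counts)))
  })

  run_stage("qc", function() {
    hemo <- assess_absorbance(state$sim$meta, config$thresholds$a414)
    dcq <- assess_dcq(state$cq, config$thresholds$dcq)
    ranges <- list("miR-28-3p" = c(24, 36), "miR-23a" = c(24, 36),
                   "miR-451" = c(20, 36))
    rep <- build_qc_report(hemo, state$cq, ranges)
    f <- qc_report_json(rep, file.path(outdir, "qc_report.json"))
    state$qc <- rep
    record("qc", f, list(fraction_hemolyzed_percent = hemo$fraction_percent,
                         n_dcq_flagged = sum(dcq$hemolyzed_by_dcq,
                                             na.rm = TRUE),
                         n_pass = rep$n_pass))
  })

  run_stage("normalize", function() {
    cpmm <- cpm(state$sim$counts)
    filt <- prevalence_filter(state$sim$counts,
                              config$thresholds$prevalence_min_count,
                              config$thresholds$prevalence_min_fraction)
    eda <- eda_summary(cpmm, state$sim$meta$group)
    state$cpm <- cpmm; state$filtered <- filt; state$eda <- eda
    fs <- c(.write_tsv(data.frame(mirna_id = rownames(cpmm), cpmm,
                                  check.names = FALSE),
                       file.path(outdir, "cpm.tsv")),
            .write_json(list(explained_variance = eda$explained_variance,
                             venn = eda$venn[c("per_group", "n_detected",
                                               "n_shared_all",
                                               "shared_percent")]),
                        file.path(outdir, "eda_summary.json")))
    record("normalize", fs,
           list(n_retained = nrow(filt$counts),
                shared_percent = eda$venn$shared_percent))
  })

  run_stage("de", function() {
    res <- lapply(config$de_contrasts, function(ct) {
      nb_wald_test(state$sim$counts, state$sim$meta, ct,
                   alpha = config$thresholds$alpha)
    })
    names(res) <- vapply(config$de_contrasts, paste, character(1),
                         collapse = "_vs_")
    state$de <- res
    tab <- do.call(rbind, lapply(names(res), function(nm) {
      cbind(contrast = nm, as.data.frame(res[[nm]]))
    }))
    f <- .write_tsv(tab, file.path(outdir, "de_results.tsv"))
    record("de", f, list(n_significant = vapply(res, function(r)
      sum(r$significant), numeric(1))))
  })

  run_stage("select", function() {
    ml <- config$ml
    keep <- state$sim$meta$group %in% ml$comparison
    X <- t(state$filtered$counts[, keep, drop = FALSE])
    labels <- factor(state$sim$meta$group[keep], levels = rev(ml$comparison))
    grid <- hyper_grid(lambda = ml$lambda, n_features = ml$n_features,
                       method = ml$method, penalty = ml$penalty)
    pt <- permutation_test(X, labels, grid,
                           n_permutations = ml$n_permutations,
                           inner_folds = ml$inner_folds,
                           seed = config$seed + 2L,
                           positive = ml$comparison[1])
    de_key <- paste(ml$comparison, collapse = "_vs_")
    de_res <- state$de[[de_key]]
    if (is.null(de_res)) {
      de_res <- nb_wald_test(state$sim$counts, state$sim$meta, ml$comparison,
                             alpha = config$thresholds$alpha)
    }
    cand <- select_candidates(pt$observed, de_res, ml$top_k)
    state$candidates <- cand
    fs <- c(nested_cv_json(pt$observed, file.path(outdir, "nested_cv.json")),
            .write_tsv(as.data.frame(cand),
                       file.path(outdir, "candidates.tsv")))
    record("select", fs,
           list(cv_auc = pt$observed$cv_auc, permutation_p = pt$p_value,
                candidates = cand$feature))
  })

  run_stage("quantify", function() {
    ref <- ddpcr_reference_means("rat")
    sizes <- config$ddpcr$group_sizes
    all_cn <- list(); folds <- list()
    for (i in seq_len(nrow(ref))) {
      assay <- ref$assay[i]
      means <- unlist(ref[i, names(sizes)])
      simc <- simulate_copy_numbers(means, sizes,
                                    log_sd = config$ddpcr$log_sd,
                                    seed = config$seed + 10L + i)
      wells <- simulate_ddpcr_wells(
        simc$copies, assay = assay,
        n_droplets = config$ddpcr$n_droplets,
        amplitude_params = list(neg_mean = 4000, pos_mean = 14000,
                                neg_sd = 700, pos_sd = 900,
                                threshold = config$thresholds$amplitude[[assay]]),
        replicates = config$ddpcr$replicates, seed = config$seed + 20L + i)
      cn <- quantify_cohort(wells)
      all_cn[[assay]] <- cn
      state$quant_meta[[assay]] <- simc$meta
      for (ct in list(c("mTBI", "naive"), c("mTBI", "sham"),
                      c("sTBI", "mTBI"), c("sTBI", "naive"))) {
        fc <- group_fold_change(cn, simc$meta, ct)
        folds[[length(folds) + 1L]] <- data.frame(
          assay = assay, contrast = paste(ct, collapse = "/"),
          fold_change = as.numeric(fc))
      }
    }
    state$copy_numbers <- all_cn
    fs <- c(.write_tsv(do.call(rbind, all_cn),
                       file.path(outdir, "copy_numbers.tsv")),
            .write_tsv(do.call(rbind, folds),
                       file.path(outdir, "fold_changes.tsv")))
    record("quantify", fs, list(fold_changes = do.call(rbind, folds)))
  })

  run_stage("roc", function() {
    cuts <- lapply(names(state$copy_numbers), function(assay) {
      cn <- state$copy_numbers[[assay]]
      m <- state$quant_meta[[assay]]
      v <- setNames(cn$copies_per_well, cn$sample_id)
      cp <- optimal_cutpoint(v[m$sample_id[m$group == "mTBI"]],
                             v[m$sample_id[m$group == "naive"]],
                             comparison = c("mTBI", "naive"))
      list(assay = assay, auc = cp$auc, auc_p = cp$auc_p,
           cutoff = cp$cutoff, sensitivity = cp$sensitivity,
           specificity = cp$specificity)
    })
    human <- default_human_cohort(config$human$assay,
                                  log_sd = config$human$log_sd,
                                  seed = config$seed + 30L)
    flags <- flag_elevated(human$copies, human$meta,
                           reference_group = "control",
                           k_sd = config$thresholds$k_sd,
                           covariate = setNames(human$meta$s100b,
                                                human$meta$sample_id),
                           covariate_cutoff = config$thresholds$covariate_cutoff)
    fs <- c(.write_json(cuts, file.path(outdir, "cutpoints.json")),
            .write_json(list(threshold = flags$threshold,
                             n_elevated = as.list(flags$n_elevated),
                             crosstab = as.data.frame(flags$crosstab),
                             n_covariate_unknown = flags$n_covariate_unknown),
                        file.path(outdir, "elevated_flags.json")))
    record("roc", fs,
           list(mTBI_vs_naive = lapply(cuts, function(x)
             x[c("assay", "auc", "sensitivity", "specificity")]),
             n_human_mTBI_elevated = unname(flags$n_elevated["mTBI"])))
  })

  manifest$status <- "complete"
  manifest <- .finish_manifest(manifest, outdir)
  invisible(manifest)
}

.finish_manifest <- function(manifest, outdir) {
  fls <- setdiff(list.files(outdir, full.names = TRUE),
                 file.path(outdir, "manifest.json"))
  manifest$files <- lapply(fls, function(f) {
    list(name = basename(f), md5 = unname(tools::md5sum(f)),
         bytes = file.size(f))
  })
  .write_json(manifest, file.path(outdir, "manifest.json"))
  manifest
}
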