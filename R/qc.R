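#' Hemolysis assessment from the 414-nm absorbance coefficient
#'
#' A plasma sample is called hemolyzed when its hemolysis coefficient
#' measured at 414 nm exceeds the threshold (default 0.25, strict
#' inequality: a coefficient exactly at the threshold passes).
#'
#' @param records data frame with columns `sample_id` and `a414`
#'   (non-negative absorbance-derived hemolysis coefficient).
#' @param threshold flagging threshold.
#' @return An object of class `hemolysis_assessment`: a list with `records`
#'   (per-sample flags), `n`, `n_hemolyzed` and `fraction_percent`.
#' @export
assess_absorbance <- function(records, threshold = 0.25) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "a414") %in% names(records)))
  if (any(records$a414 < 0)) stop("a414 coefficients must be non-negative")
  flagged <- records$a414 > threshold
  out <- data.frame(sample_id = records$sample_id,
                    a414_coefficient = records$a414,
                    hemolyzed_by_absorbance = flagged)
  structure(list(records = out,
                 threshold = threshold,
                 n = nrow(out),
                 n_hemolyzed = sum(flagged),
                 fraction_percent = 100 * sum(flagged) / nrow(out)),
            class = "hemolysis_assessment")
}

#' @export
print.hemolysis_assessment <- function(x, ...) {
  cat(sprintf("hemolysis (a414 > %.2f): %d/%d samples (%.0f%%)\n",
              x$threshold, x$n_hemolyzed, x$n, x$fraction_percent))
  invisible(x)
}

#' Hemolysis assessment from the delta-Cq (miR-23a - miR-451) indicator
#'
#' Red-blood-cell miR-451 is strongly enriched by hemolysis, lowering its Cq
#' relative to miR-23a; a difference Cq(miR-23a) - Cq(miR-451) above 5
#' cycles (strict) indicates hemolysis. Samples missing either pair member
#' are marked unassessable (`NA` flag), not flagged.
#'
#' @param cq a `cq_table` (long data frame `sample_id`, `assay`, `cq`).
#' @param threshold delta-Cq threshold in cycles.
#' @param pair the indicator assays, in the order (miR-23a, miR-451).
#' @return Data frame with `sample_id`, `delta_cq`, `hemolyzed_by_dcq`.
#' @export
assess_dcq <- function(cq, threshold = 5, pair = c("miR-23a", "miR-451")) {
  stopifnot(is.data.frame(cq), all(c("sample_id", "assay", "cq") %in% names(cq)))
  samples <- unique(cq$sample_id)
  d <- vapply(samples, function(s) {
    c23 <- cq$cq[cq$sample_id == s & cq$assay == pair[1]]
    c451 <- cq$cq[cq$sample_id == s & cq$assay == pair[2]]
    if (length(c23) != 1 || length(c451) != 1) NA_real_ else c23 - c451
  }, numeric(1))
  data.frame(sample_id = samples,
             delta_cq = as.numeric(d),
             hemolyzed_by_dcq = d > threshold)
}

#' Sample-level QC report
#'
#' Combines hemolysis flags with per-assay Cq range checks (endogenous
#' control panel and spike-ins): a sample passes an assay when its Cq lies
#' inside the expected `[lo, hi]` window, and passes overall when it passes
#' every checked assay.
#'
#' @param hemo a [assess_absorbance] result, an [assess_dcq] data frame, or a
#'   data frame carrying per-sample hemolysis flags.
#' @param cq a `cq_table`.
#' @param expected_ranges named list: assay -> `c(lo, hi)` expected Cq range.
#' @return An object of class `qc_report`: per-sample per-assay pass flags,
#'   failing assay names, hemolysis flags and overall pass. Serializable
#'   with [qc_report_json()].
#' @export
build_qc_report <- function(hemo, cq, expected_ranges) {
  if (inherits(hemo, "hemolysis_assessment")) hemo <- hemo$records
  if (is.null(hemo) || nrow(hemo) == 0 || is.null(cq) || nrow(cq) == 0 ||
      length(expected_ranges) == 0) {
    stop("build_qc_report requires non-empty hemolysis records, Cq table and expected ranges")
  }
  if (is.null(names(expected_ranges))) stop("expected_ranges must be keyed by assay")
  samples <- unique(cq$sample_id)
  checks <- lapply(samples, function(s) {
    per_assay <- vapply(names(expected_ranges), function(a) {
      v <- cq$cq[cq$sample_id == s & cq$assay == a]
      length(v) == 1 && v >= expected_ranges[[a]][1] && v <= expected_ranges[[a]][2]
    }, logical(1))
    list(sample_id = s, assay_pass = per_assay,
         failed_assays = names(per_assay)[!per_assay],
         overall_pass = all(per_assay))
  })
  names(checks) <- samples
  structure(list(samples = checks,
                 hemolysis = hemo,
                 expected_ranges = expected_ranges,
                 n_pass = sum(vapply(checks, `[[`, logical(1), "overall_pass")),
                 n = length(checks)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d/%d samples pass all assay range checks\n",
              x$n_pass, x$n))
  fails <- Filter(function(s) !s$overall_pass, x$samples)
  for (s in fails) {
    cat(sprintf("  %s fails: %s\n", s$sample_id,
                paste(s$failed_assays, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname build_qc_report
#' @param report a `qc_report`.
#' @param path optional file path; when given, the JSON is written there.
#' @export
qc_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "qc_report"))
  obj <- list(
    n = report$n, n_pass = report$n_pass,
    expected_ranges = report$expected_ranges,
    hemolysis = report$hemolysis,
    samples = lapply(report$samples, function(s) {
      list(sample_id = s$sample_id, overall_pass = s$overall_pass,
           failed_assays = s$failed_assays)
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(path)
  } else js
}
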