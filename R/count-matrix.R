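#' Raw miRNA count matrix with per-sample miRNA-mapped totals
#'
#' The substrate of the whole pipeline: an integer matrix of raw read counts
#' (miRNAs in rows, samples in columns) together with the per-sample total
#' number of reads mapped to miRNAs. The totals are the denominator of the
#' counts-per-million transform and may exceed the column sums, because the
#' matrix may hold only a filtered subset of the miRNAs that contributed to
#' the mapped total.
#'
#' @param counts integer matrix, miRNAs x samples, with row and column names.
#' @param mirna_mapped_total positive numeric vector, one entry per sample.
#'   Defaults to the column sums of `counts`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `mirna_mapped_total`.
#' @export
count_matrix <- function(counts, mirna_mapped_total = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("miR-%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("miRNA and sample identifiers must be unique")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (length(mirna_mapped_total) != ncol(counts)) {
    stop("one miRNA-mapped total is required per sample")
  }
  if (any(mirna_mapped_total <= 0)) {
    stop("miRNA-mapped totals must be positive")
  }
  structure(
    list(counts = counts,
         mirna_mapped_total = setNames(as.numeric(mirna_mapped_total),
                                       colnames(counts))),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("miRNA-mapped totals: %s ... \n",
              paste(format(head(x$mirna_mapped_total, 4)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read a count matrix as TSV
#'
#' Plain-text interchange format: miRNAs in rows, samples in columns, first
#' column `mirna_id`. The miRNA-mapped totals are stored as a final row
#' labelled `__mirna_mapped_total__`.
#'
#' @param cm a [count_matrix].
#' @param path file path.
#' @return `write_count_matrix` returns `path` invisibly; `read_count_matrix`
#'   returns a [count_matrix].
#' @export
write_count_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(mirna_id = c(rownames(cm$counts), "__mirna_mapped_total__"),
                   rbind(cm$counts, cm$mirna_mapped_total),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- ids
  tot_row <- ids == "__mirna_mapped_total__"
  if (any(tot_row)) {
    totals <- mat[which(tot_row)[1], ]
    mat <- mat[!tot_row, , drop = FALSE]
    count_matrix(mat, totals)
  } else {
    count_matrix(mat)
  }
}
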