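#' Construct a feature table
#'
#' Container for LC-HRMS metabolic features: per-feature metadata
#' (feature id, analytical mode, m/z, retention time in seconds) plus a
#' features x subjects intensity matrix and a features x replicates
#' pooled-QC matrix. Intensities start on the raw scale; preprocessing
#' moves them to log2 (`is_log2` tracks which).
#'
#' @param meta data.frame with at least `feature_id`, `mode`, `mz`, `rt`.
#' @param intensity Numeric matrix, rows = features (named by
#'   `feature_id`), columns = subjects.
#' @param qc Numeric matrix of pooled-QC replicate intensities, or NULL.
#' @param is_log2 Logical: are intensities on the log2 scale?
#' @return An object of class `feature_table`.
#' @export
new_feature_table <- function(meta, intensity, qc = NULL,
                              is_log2 = FALSE) {
  stopifnot(is.data.frame(meta),
            all(c("feature_id", "mode", "mz", "rt") %in% names(meta)),
            is.matrix(intensity),
            nrow(intensity) == nrow(meta))
  if (is.null(rownames(intensity))) rownames(intensity) <- meta$feature_id
  stopifnot(identical(rownames(intensity), meta$feature_id))
  structure(list(meta = meta, intensity = intensity, qc = qc,
                 is_log2 = is_log2),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$meta), "features x",
      ncol(x$intensity), "subjects",
      if (x$is_log2) "(log2)" else "(raw)", "\n")
  tab <- table(x$meta$mode)
  cat("  modes:", paste(sprintf("%s=%d", names(tab), tab),
                        collapse = ", "), "\n")
  cat("  QC replicates:", if (is.null(x$qc)) 0 else ncol(x$qc), "\n")
  invisible(x)
}

#' Number of features
#' @param table A `feature_table`.
#' @return Integer count of features.
#' @export
n_features <- function(table) nrow(table$meta)

#' Subset a feature table by feature id
#' @param table A `feature_table`.
#' @param ids Feature ids to keep (order taken from the table).
#' @return A `feature_table` restricted to `ids`.
#' @export
subset_features <- function(table, ids) {
  keep <- table$meta$feature_id %in% ids
  new_feature_table(table$meta[keep, , drop = FALSE],
                    table$intensity[keep, , drop = FALSE],
                    if (!is.null(table$qc)) table$qc[keep, , drop = FALSE],
                    table$is_log2)
}
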