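mode_slug <- function(m) gsub("\\+", "pos", gsub("-", "neg", m))

#' Write a synthetic study to plain-text files
#'
#' Lays a study out as the CSV/TSV interchange the pipeline reads:
#' `exposures.csv` (concentrations with per-cell censoring flags in
#' `censored.csv` and per-chemical LODs in `chemicals.csv`),
#' `covariates.csv`, `bp.csv`, one `features_<mode>.tsv` per analytical
#' mode (feature metadata plus subject and QC intensity columns),
#' `truth.json`, `annotation_library.tsv` and `pathways.tsv`.
#'
#' @param study A study list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f, sep = ",") {
    utils::write.table(d, file.path(dir, f), sep = sep,
                       row.names = FALSE, quote = TRUE)
  }
  ex <- study$exposures
  w(data.frame(subject_id = subject_ids(ex), ex$concentrations,
               check.names = FALSE), "exposures.csv")
  w(data.frame(subject_id = subject_ids(ex), ex$censored,
               check.names = FALSE), "censored.csv")
  w(data.frame(chemical = names(ex$lod), lod = unname(ex$lod),
               class = unname(ex$chem_class)), "chemicals.csv")
  w(study$covariates, "covariates.csv")
  w(as.data.frame(study$bp), "bp.csv")
  ft <- study$features
  for (m in unique(ft$meta$mode)) {
    keep <- ft$meta$mode == m
    d <- cbind(ft$meta[keep, c("feature_id", "mode", "mz", "rt")],
               ft$intensity[keep, , drop = FALSE],
               ft$qc[keep, , drop = FALSE])
    w(d, sprintf("features_%s.tsv", mode_slug(m)), sep = "\t")
  }
  w(study$annotation, "annotation_library.tsv", sep = "\t")
  w(study$pathways, "pathways.tsv", sep = "\t")
  truth <- study$truth
  jsonlite::write_json(
    list(signal_feature_ids = truth$signal_feature_ids,
         mediator_feature_ids = truth$mediator_feature_ids,
         true_psi_sbp = truth$true_psi_sbp,
         true_psi_per_feature = as.list(truth$true_psi_per_feature)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing the study files.
#' @return A study list (`exposures`, `covariates`, `features`, `bp`,
#'   `truth` if present, `annotation`, `pathways`).
#' @export
read_study <- function(dir) {
  r <- function(f, sep = ",") {
    utils::read.table(file.path(dir, f), sep = sep, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  exd <- r("exposures.csv")
  cend <- r("censored.csv")
  chem <- r("chemicals.csv")
  X <- as.matrix(exd[, -1, drop = FALSE])
  rownames(X) <- exd$subject_id
  cen <- as.matrix(cend[, -1, drop = FALSE]) == "TRUE" |
    as.matrix(cend[, -1, drop = FALSE]) == TRUE
  rownames(cen) <- cend$subject_id
  exposures <- new_exposure_panel(
    X, stats::setNames(chem$lod, chem$chemical), cen,
    stats::setNames(chem$class, chem$chemical))
  feat_files <- list.files(dir, pattern = "^features_.*\\.tsv$")
  parts <- lapply(feat_files, function(f) r(f, sep = "\t"))
  meta <- do.call(rbind, lapply(parts, function(p)
    p[, c("feature_id", "mode", "mz", "rt")]))
  qc_cols <- grep("^QC", names(parts[[1]]), value = TRUE)
  subj_cols <- setdiff(names(parts[[1]]),
                       c("feature_id", "mode", "mz", "rt", qc_cols))
  intensity <- do.call(rbind, lapply(parts, function(p)
    as.matrix(p[, subj_cols, drop = FALSE])))
  qc <- do.call(rbind, lapply(parts, function(p)
    as.matrix(p[, qc_cols, drop = FALSE])))
  rownames(intensity) <- rownames(qc) <- meta$feature_id
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tl <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- structure(list(
      signal_feature_ids = tl$signal_feature_ids,
      mediator_feature_ids = tl$mediator_feature_ids,
      true_psi_sbp = tl$true_psi_sbp,
      true_psi_per_feature = unlist(tl$true_psi_per_feature)),
      class = "ground_truth")
  }
  bp <- r("bp.csv")
  class(bp) <- c("bp_panel", "data.frame")
  list(exposures = exposures, covariates = r("covariates.csv"),
       features = new_feature_table(meta, intensity, qc),
       bp = bp, truth = truth,
       annotation = r("annotation_library.tsv", sep = "\t"),
       pathways = r("pathways.tsv", sep = "\t"))
}
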