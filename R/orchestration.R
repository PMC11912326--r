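#' Configuration for an end-to-end pipeline run
#'
#' @param sim A [sim_config()] describing a synthetic study, or NULL
#'   when `data_dir` is given.
#' @param data_dir Directory with study files from [write_study()], or
#'   NULL to simulate.
#' @param q Number of exposure quantiles (default 4, quartiles).
#' @param raw_alpha Raw significance tier for the MWAS scans (0.01).
#' @param alpha_family Family-wise alpha for the PCA-adjusted tier.
#' @param tier Tier used for the meet-in-the-middle overlap
#'   (`"raw"` or `"adjusted"`).
#' @param enrichment_alpha Raw p-value tier feeding pathway enrichment
#'   (0.05, looser so enough features enter the test).
#' @param ppm_tol,rt_tol_s Annotation tolerances (ppm, seconds).
#' @param include_site Adjust all models for study site?
#' @param meff_by_mode Compute the metabolome Meff per mode and sum?
#' @param selected_outcome Outcome label (e.g. `"sbp_pct_year5"`) for
#'   the second MWAS; NULL selects programmatically as the outcome whose
#'   mixture-fit CI excludes zero (smallest p among those, falling back
#'   to smallest p overall).
#' @param do_submixtures Fit OCP/PCB class submixtures on the selected
#'   outcome?
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), data_dir = NULL, q = 4L,
                       raw_alpha = 0.01, alpha_family = 0.05,
                       tier = c("raw", "adjusted"),
                       enrichment_alpha = 0.05,
                       ppm_tol = 10, rt_tol_s = 10,
                       include_site = FALSE, meff_by_mode = TRUE,
                       selected_outcome = NULL,
                       do_submixtures = TRUE) {
  tier <- match.arg(tier)
  if (is.null(data_dir)) stopifnot(inherits(sim, "sim_config"))
  structure(list(sim = sim, data_dir = data_dir, q = as.integer(q),
                 raw_alpha = raw_alpha, alpha_family = alpha_family,
                 tier = tier, enrichment_alpha = enrichment_alpha,
                 ppm_tol = ppm_tol, rt_tol_s = rt_tol_s,
                 include_site = include_site,
                 meff_by_mode = meff_by_mode,
                 selected_outcome = selected_outcome,
                 do_submixtures = do_submixtures),
            class = "run_config")
}

# md5 of a serialized R object (used to stamp reports with their config)
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full mixture-metabolome-blood-pressure pipeline
#'
#' Simulates (or ingests) a study, preprocesses exposures and features,
#' fits quantile g-computation for every blood-pressure measure and
#' follow-up visit, selects the outcome for the second scan, runs both
#' MWAS directions with raw and Kaiser-Guttman-adjusted significance
#' tiers, annotates features, intersects the two significant sets
#' (meet-in-the-middle) and runs hypergeometric pathway
#' overrepresentation on each side.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `mixture_fits` (all eight), a
#'   `mixture_table` analogue, `submixture_fits`, `selected_outcome`,
#'   `scan_exposure`, `scan_outcome`, `meff` (exposure/metabolome counts
#'   and adjusted alphas), `summary_exposure`, `summary_outcome`,
#'   `annotation`, `identified_exposure`, `identified_outcome`,
#'   `overlap`, `enrichment_exposure`, `enrichment_outcome`,
#'   `overlapped_pathways`, plus `config_hash` and `seed` stamps.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  study <- run_stage("input", {
    if (is.null(config$data_dir)) simulate_study(config$sim)
    else read_study(config$data_dir)
  })

  exposures <- run_stage("preprocess_exposures", {
    log2_transform(substitute_below_lod(study$exposures))
  })
  descriptives <- describe_exposures(exposures)

  features <- run_stage("preprocess_features", {
    log2_transform(impute_half_min(filter_features(study$features)))
  })

  outcomes <- run_stage("outcomes", bp_outcomes(study$bp))
  design <- run_stage("quantize",
                      quantize_exposures(exposures, q = config$q))

  outcome_labels <- setdiff(names(outcomes), "subject_id")
  fits <- run_stage("mixture_fits", {
    lapply(stats::setNames(outcome_labels, outcome_labels), function(o)
      fit_qgcomp(design, outcomes[[o]], study$covariates,
                 include_site = config$include_site,
                 outcome_label = o))
  })
  mixture_table <- data.frame(
    outcome = outcome_labels,
    psi = vapply(fits, `[[`, numeric(1), "psi"),
    ci_low = vapply(fits, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(fits, `[[`, numeric(1), "ci_high"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    row.names = NULL, stringsAsFactors = FALSE)

  selected <- config$selected_outcome
  if (is.null(selected)) {
    excl0 <- mixture_table$ci_low > 0 | mixture_table$ci_high < 0
    pool <- if (any(excl0)) mixture_table[excl0, ] else mixture_table
    selected <- pool$outcome[which.min(pool$p_value)]
  }
  y_sel <- stats::setNames(outcomes[[selected]], outcomes$subject_id)

  submixture_fits <- NULL
  if (config$do_submixtures) {
    cls <- exposures$chem_class
    submixture_fits <- run_stage("submixtures", {
      lapply(stats::setNames(nm = intersect(c("OCP", "PCB"), cls)),
             function(cl)
               fit_submixture(design, outcomes[[selected]],
                              study$covariates,
                              subset = names(cls)[cls == cl],
                              include_site = config$include_site,
                              outcome_label = paste0(selected, " (",
                                                     cl, ")")))
    })
  }

  meff_exposure <- run_stage("meff", compute_meff(exposures$log2))
  meff_features <- compute_meff(features, by_mode = config$meff_by_mode)
  alpha_exposure_scan <- adjusted_alpha(as.integer(meff_exposure),
                                        as.integer(meff_features),
                                        config$alpha_family)
  alpha_outcome_scan <- adjusted_alpha(as.integer(meff_features), 1L,
                                       config$alpha_family)

  scan1 <- run_stage("mwas_exposure", {
    flag_significance(
      mwas_mixture_on_metabolome(design, features, study$covariates,
                                 config$include_site),
      config$raw_alpha, alpha_exposure_scan)
  })
  scan2 <- run_stage("mwas_outcome", {
    flag_significance(
      mwas_metabolome_on_outcome(features, y_sel, study$covariates,
                                 config$include_site),
      config$raw_alpha, alpha_outcome_scan)
  })

  annotation <- run_stage("annotate", {
    annotate_features(features, study$annotation,
                      ppm_tol = config$ppm_tol,
                      rt_tol_s = config$rt_tol_s)
  })

  identified <- function(scan) {
    col <- paste0("significant_", config$tier)
    sig <- scan[scan[[col]], , drop = FALSE]
    ann <- annotation[annotation$confidence == "1", , drop = FALSE]
    merge(sig, ann[, c("feature_id", "metabolite", "ppm")],
          by = "feature_id")
  }

  overlap <- run_stage("overlap",
                       find_overlap(scan1, scan2, config$tier,
                                    annotation))

  enrich <- run_stage("enrichment", {
    background <- unique(annotation$feature_id)
    sig_ids <- function(scan)
      intersect(scan$feature_id[!is.na(scan$p_value) &
                                  scan$p_value < config$enrichment_alpha],
                background)
    list(
      exposure = pathway_ora(sig_ids(scan1), background,
                             study$pathways, annotation),
      outcome = pathway_ora(sig_ids(scan2), background,
                            study$pathways, annotation))
  })

  structure(list(
    descriptives = descriptives,
    mixture_fits = fits,
    mixture_table = mixture_table,
    submixture_fits = submixture_fits,
    selected_outcome = selected,
    scan_exposure = scan1,
    scan_outcome = scan2,
    meff = list(exposure = as.integer(meff_exposure),
                metabolome = as.integer(meff_features),
                alpha_exposure_scan = alpha_exposure_scan,
                alpha_outcome_scan = alpha_outcome_scan),
    summary_exposure = significance_summary(scan1, config$raw_alpha,
                                            alpha_exposure_scan),
    summary_outcome = significance_summary(scan2, config$raw_alpha,
                                           alpha_outcome_scan),
    annotation = annotation,
    identified_exposure = identified(scan1),
    identified_outcome = identified(scan2),
    overlap = overlap,
    enrichment_exposure = enrich$exposure,
    enrichment_outcome = enrich$outcome,
    overlapped_pathways = overlapped_pathways(enrich$exposure,
                                              enrich$outcome),
    truth = study$truth,
    config_hash = object_hash(config),
    seed = if (!is.null(config$sim)) config$sim$seed else NA_integer_
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline report (config ", substr(x$config_hash, 1, 8),
      ", seed ", x$seed, ")\n", sep = "")
  cat("Selected outcome:", x$selected_outcome, "\n")
  cat("Mixture effects:\n")
  print(transform(x$mixture_table, psi = round(psi, 2),
                  ci_low = round(ci_low, 2),
                  ci_high = round(ci_high, 2),
                  p_value = signif(p_value, 2)))
  cat("Meff: exposures =", x$meff$exposure,
      "| metabolome =", x$meff$metabolome,
      "| adjusted alpha =",
      signif(x$meff$alpha_exposure_scan, 2), "/",
      signif(x$meff$alpha_outcome_scan, 2), "\n")
  cat("Overlap features:", nrow(x$overlap),
      "| overlapped pathways:",
      length(x$overlapped_pathways), "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' TSV tables plus a `report.json` summary, each stamped with the config
#' hash and seed. On failure everything written so far is removed.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stamp <- sprintf("# config_hash=%s seed=%s", report$config_hash,
                   report$seed)
  tryCatch({
    wtsv <- function(d, f) {
      path <- file.path(dir, f)
      con <- file(path, "w")
      writeLines(stamp, con)
      utils::write.table(d, con, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      close(con)
      written <<- c(written, path)
    }
    wtsv(report$descriptives, "exposure_descriptives.tsv")
    wtsv(report$mixture_table, "mixture_effects.tsv")
    wtsv(report$summary_exposure, "mwas_summary_exposure.tsv")
    wtsv(report$summary_outcome, "mwas_summary_outcome.tsv")
    wtsv(report$identified_exposure, "identified_exposure.tsv")
    wtsv(report$identified_outcome, "identified_outcome.tsv")
    wtsv(as.data.frame(report$overlap), "overlap.tsv")
    wtsv(as.data.frame(report$enrichment_exposure),
         "enrichment_exposure.tsv")
    wtsv(as.data.frame(report$enrichment_outcome),
         "enrichment_outcome.tsv")
    for (side in c("exposure", "outcome")) {
      path <- file.path(dir, sprintf("bubble_%s.svg", side))
      write_bubble_svg(report[[paste0("enrichment_", side)]], path)
      written <- c(written, path)
    }
    js <- file.path(dir, "report.json")
    jsonlite::write_json(list(
      config_hash = report$config_hash, seed = report$seed,
      selected_outcome = report$selected_outcome,
      mixture_table = report$mixture_table,
      meff = report$meff,
      overlap = as.data.frame(report$overlap),
      overlapped_pathways = report$overlapped_pathways
    ), js, auto_unbox = TRUE, digits = NA)
    written <- c(written, js)
  }, error = function(e) {
    unlink(written)
    stop("write_report failed (partial outputs removed): ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(dir)
}
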