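#' Generate correlated log-normal POP exposures with LOD censoring
#'
#' Draws subjects x chemicals concentrations from log-normal marginals at
#' the configured geometric mean/GSD, coupled through a Gaussian copula.
#' The copula's Pearson correlation is obtained from the target Spearman
#' matrix by rho = 2 sin(pi rho_s / 6), so realized rank correlations
#' approach `spearman_target` as n grows. Values below a chemical's LOD
#' are flagged censored (the latent value is kept; substitution is a
#' preprocessing step, see [substitute_below_lod()]).
#'
#' @param config A [sim_config()].
#' @param n Optional subject-count override (defaults to
#'   `config$n_subjects`).
#' @return An `exposure_panel`: list with `concentrations` (n x k matrix,
#'   ng/g), `lod` (named vector), `censored` (logical matrix),
#'   `chem_class` (named vector), `log2` (NULL until transformed).
#' @export
generate_exposures <- function(config, n = config$n_subjects) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config, "exposures"))
  chem <- config$chemicals
  k <- nrow(chem)
  R <- 2 * sin(pi * config$spearman_target / 6)
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("spearman_target maps to a non-positive-semidefinite copula ",
         "correlation; adjust the target matrix")
  }
  if (min(ev) < 1e-10) {
    # PSD but singular: tiny ridge keeps the Cholesky factor defined
    R <- R + diag(1e-8, k)
  }
  U <- chol(R)
  Z <- matrix(stats::rnorm(n * k), n, k) %*% U
  X <- vapply(seq_len(k), function(j) {
    stats::qlnorm(stats::pnorm(Z[, j]),
                  meanlog = log(chem$gm[j]), sdlog = log(chem$gsd[j]))
  }, numeric(n))
  dimnames(X) <- list(sprintf("S%03d", seq_len(n)), chem$name)
  lod <- stats::setNames(chem$lod, chem$name)
  censored <- sweep(X, 2, lod, `<`)
  new_exposure_panel(X, lod, censored,
                     stats::setNames(chem$class, chem$name))
}

new_exposure_panel <- function(concentrations, lod, censored, chem_class,
                               log2 = NULL) {
  structure(list(concentrations = concentrations, lod = lod,
                 censored = censored, chem_class = chem_class,
                 log2 = log2),
            class = "exposure_panel")
}

#' @export
print.exposure_panel <- function(x, ...) {
  cat("Exposure panel:", nrow(x$concentrations), "subjects x",
      ncol(x$concentrations), "chemicals\n")
  cat("  censored cells:", sum(x$censored),
      if (is.null(x$log2)) "(raw scale)" else "(log2 available)", "\n")
  invisible(x)
}

#' Subject ids of an exposure panel
#' @param panel An `exposure_panel`.
#' @return Character vector of subject ids.
#' @export
subject_ids <- function(panel) rownames(panel$concentrations)

#' Generate subject covariates
#'
#' Sex (male/female), race/ethnicity (non-Hispanic white vs others),
#' parents' income in four categories (including "unknown"), age in
#' months and baseline BMI, drawn from configurable category frequencies
#' and normal distributions matching the cohort's descriptive profile
#' (72% female, 63% non-Hispanic white, age 203 (18) months,
#' BMI 54 (10) kg/m2). An optional two-level study site is included for
#' sensitivity analyses.
#'
#' @param config A [sim_config()].
#' @param n Subject count override; `n = 0` returns an empty table with
#'   the full schema.
#' @param freqs Optional list overriding category frequencies: elements
#'   `sex`, `race`, `income` (named numeric vectors) and `age_mean`,
#'   `age_sd`, `bmi_mean`, `bmi_sd`.
#' @return A data.frame with `subject_id`, `sex`, `race`, `age_months`,
#'   `income`, `bmi`, `site`.
#' @export
generate_covariates <- function(config, n = config$n_subjects,
                                freqs = list()) {
  set.seed(stage_seed(config, "covariates"))
  f <- utils::modifyList(list(
    sex = c(male = 0.28, female = 0.72),
    race = c("Non-Hispanic white" = 0.63, "Others" = 0.37),
    income = c("<$25,000" = 0.44, "$25,000-$74,999" = 0.39,
               ">=$75,000" = 0.12, "unknown" = 0.053),
    site = c(A = 0.6, B = 0.4),
    age_mean = 203, age_sd = 18, bmi_mean = 54, bmi_sd = 10
  ), freqs)
  draw <- function(levels_probs, n) {
    if (n == 0) return(character(0))
    sample(names(levels_probs), n, replace = TRUE,
           prob = levels_probs / sum(levels_probs))
  }
  data.frame(
    subject_id = if (n == 0) character(0) else sprintf("S%03d", seq_len(n)),
    sex = draw(f$sex, n),
    race = draw(f$race, n),
    age_months = stats::rnorm(n, f$age_mean, f$age_sd),
    income = draw(f$income, n),
    bmi = stats::rnorm(n, f$bmi_mean, f$bmi_sd),
    site = draw(f$site, n),
    stringsAsFactors = FALSE
  )
}

# Mean quartile index per subject: the "simultaneous quantile" score the
# planted effects act through (one-unit increase = one-quartile increase
# in every chemical).
exposure_quartile_score <- function(panel, q = 4L) {
  idx <- quantile_indices(panel$concentrations, q)
  rowMeans(idx)
}

#' Generate the synthetic adipose metabolome
#'
#' Builds a feature table per analytical mode. Null features are
#' independent log-normal noise; signal features add
#' `psi_exposure_to_feature x (mean chemical quartile index)` to log2
#' intensity, so the quantile-g-computation estimand for such a feature
#' equals the planted psi. Features matching annotation-library entries
#' receive the library m/z, retention time and mode so downstream
#' annotation recovers them; planted metabolites are drawn from the
#' library so meet-in-the-middle logic is exercised end to end. Pooled-QC
#' replicate columns carry multiplicative noise at the configured CV;
#' missingness is injected at `missing_rate`, with small designated
#' fractions of junk features violating the detection-rate and QC-CV
#' filters.
#'
#' @param config A [sim_config()].
#' @param exposures The `exposure_panel` from [generate_exposures()].
#' @return A list with elements `features` (a `feature_table`) and
#'   `truth` (a `ground_truth`: `signal_feature_ids`,
#'   `mediator_feature_ids`, `true_psi_sbp`, `true_psi_per_feature`).
#' @export
generate_metabolome <- function(config, exposures) {
  stopifnot(inherits(config, "sim_config"),
            inherits(exposures, "exposure_panel"))
  set.seed(stage_seed(config, "metabolome"))
  n <- nrow(exposures$concentrations)
  subj <- subject_ids(exposures)
  s <- exposure_quartile_score(exposures)
  lib <- annotation_library()
  mode_labels <- names(config$modes)
  slug <- function(m) gsub("\\+", "pos", gsub("-", "neg", m))

  meta_list <- list(); int_list <- list(); qc_list <- list()
  latent_list <- list()
  signal_ids <- character(0); mediator_ids <- character(0)
  psi_map <- numeric(0)

  for (m in mode_labels) {
    p <- config$modes[[m]]
    lib_m <- lib[lib$mode == m, , drop = FALSE]
    n_ann <- min(nrow(lib_m), p)
    ids <- sprintf("%s_F%05d", slug(m), seq_len(p))
    mz <- stats::runif(p, 85, 800)
    rt <- stats::runif(p, 10, 600)
    metab <- rep(NA_character_, p)
    if (n_ann > 0) {
      mz[seq_len(n_ann)] <- lib_m$mz[seq_len(n_ann)]
      rt[seq_len(n_ann)] <- lib_m$rt[seq_len(n_ann)]
      metab[seq_len(n_ann)] <- lib_m$metabolite[seq_len(n_ann)]
    }
    if (config$n_signal_features > p) {
      stop("n_signal_features exceeds the number of features in mode ", m)
    }
    planted_here <- which(metab %in% config$planted_metabolites)
    extra_needed <- max(0L, config$n_signal_features - length(planted_here))
    pool <- setdiff(seq_len(p), planted_here)
    sig <- c(planted_here,
             if (extra_needed > 0) sample(pool, min(extra_needed,
                                                    length(pool))))
    med <- which(metab %in% config$mediator_metabolites)

    mu <- stats::runif(p, 12, 24)
    eps <- matrix(stats::rnorm(p * n, 0, config$feature_sd), p, n)
    log2i <- mu + eps
    log2i[sig, ] <- log2i[sig, ] +
      config$psi_exposure_to_feature * matrix(s, length(sig), n,
                                              byrow = TRUE)
    dimnames(log2i) <- list(ids, subj)
    raw <- 2^log2i

    # pooled-QC replicates: repeated injections of the pooled mean with
    # multiplicative noise at the feature's CV
    cv <- stats::runif(p, config$qc_cv_range[1], config$qc_cv_range[2])
    junk_pool <- setdiff(seq_len(p), sig)
    n_hicv <- round(config$frac_high_cv * p)
    hicv <- if (n_hicv > 0) sample(junk_pool, min(n_hicv,
                                                  length(junk_pool)))
            else integer(0)
    cv[hicv] <- stats::runif(length(hicv), 0.35, 0.60)
    pooled <- rowMeans(raw)
    qc <- pooled * exp(matrix(stats::rnorm(p * config$n_qc), p) *
                         log(1 + cv))
    colnames(qc) <- sprintf("QC%d", seq_len(config$n_qc))
    rownames(qc) <- ids

    # missingness: baseline rate everywhere, near-total for designated
    # low-detection junk features (never signal features)
    miss <- matrix(stats::runif(p * n) < config$missing_rate, p, n)
    n_lo <- round(config$frac_low_detect * p)
    lo_pool <- setdiff(junk_pool, hicv)
    lo <- if (n_lo > 0) sample(lo_pool, min(n_lo, length(lo_pool)))
          else integer(0)
    miss[lo, ] <- matrix(stats::runif(length(lo) * n) <
                           stats::runif(length(lo), 0.85, 0.95),
                         length(lo), n)
    # keep at least one observation per feature so half-min is defined
    all_gone <- rowSums(!miss) == 0
    miss[all_gone, 1] <- FALSE
    raw_obs <- raw
    raw_obs[miss] <- NA_real_

    meta_list[[m]] <- data.frame(
      feature_id = ids, mode = m, mz = mz, rt = rt,
      metabolite_truth = metab, stringsAsFactors = FALSE)
    int_list[[m]] <- raw_obs
    qc_list[[m]] <- qc
    latent_list[[m]] <- log2i[med, , drop = FALSE]
    signal_ids <- c(signal_ids, ids[sig])
    mediator_ids <- c(mediator_ids, ids[med])
    psi_map <- c(psi_map, stats::setNames(
      rep(config$psi_exposure_to_feature, length(sig)), ids[sig]))
  }

  features <- new_feature_table(
    meta = do.call(rbind, c(meta_list, list(make.row.names = FALSE))),
    intensity = do.call(rbind, int_list),
    qc = do.call(rbind, qc_list))
  mediator_latent <- do.call(rbind, latent_list)
  truth <- structure(list(
    signal_feature_ids = signal_ids,
    mediator_feature_ids = mediator_ids,
    true_psi_sbp = config$psi_exposure_to_sbp,
    true_psi_per_feature = psi_map
  ), class = "ground_truth")
  # latent complete mediator intensities (log2) and their base means,
  # carried so blood-pressure generation is independent of missingness
  attr(truth, "mediator_log2") <- mediator_latent
  attr(truth, "mediator_mu") <- rowMeans(mediator_latent) -
    config$psi_exposure_to_feature * mean(s)
  list(features = features, truth = truth)
}

#' Generate longitudinal blood pressure
#'
#' Baseline SBP/DBP are normal at the configured means/SDs. Six-month and
#' five-year values are built from percent-change models: the 5-year SBP
#' percent change carries the planted total mixture effect
#' `psi_exposure_to_sbp` per simultaneous one-quartile increase plus
#' `beta_feature_to_sbp` per doubling of each mediator feature (the
#' direct path is reduced by the mediated part so the marginal estimand
#' equals `true_psi_sbp`), plus noise; all other measure/visit changes
#' are noise around modest post-surgery declines.
#'
#' @param config A [sim_config()].
#' @param exposures The `exposure_panel`.
#' @param features The `feature_table` from [generate_metabolome()].
#' @param truth The matching `ground_truth`.
#' @return A data.frame (class `bp_panel`) with one row per subject:
#'   `sbp_baseline`, `dbp_baseline`, `sbp_month6`, `dbp_month6`,
#'   `sbp_year5`, `dbp_year5` (mmHg).
#' @export
generate_blood_pressure <- function(config, exposures, features, truth) {
  stopifnot(inherits(config, "sim_config"),
            inherits(truth, "ground_truth"))
  set.seed(stage_seed(config, "bp"))
  n <- nrow(exposures$concentrations)
  subj <- subject_ids(exposures)
  if (!all(truth$mediator_feature_ids %in% features$meta$feature_id)) {
    missing_ids <- setdiff(truth$mediator_feature_ids,
                           features$meta$feature_id)
    stop("mediator features absent from the feature table: ",
         paste(missing_ids, collapse = ", "))
  }
  s <- exposure_quartile_score(exposures)
  med_log2 <- attr(truth, "mediator_log2")
  med_mu <- attr(truth, "mediator_mu")
  beta <- config$beta_feature_to_sbp
  psi_f <- config$psi_exposure_to_feature
  n_med <- length(truth$mediator_feature_ids)
  mediated <- if (n_med > 0) {
    colSums(beta * (med_log2 - med_mu))
  } else rep(0, n)
  direct <- truth$true_psi_sbp - n_med * beta * psi_f

  b <- config$bp_baseline
  sbp0 <- stats::rnorm(n, b[["sbp_mean"]], b[["sbp_sd"]])
  dbp0 <- pmin(stats::rnorm(n, b[["dbp_mean"]], b[["dbp_sd"]]), sbp0 - 5)
  noise <- function(mu) stats::rnorm(n, mu, config$bp_noise_sd)

  pct_sbp_5y <- -8 + direct * s + mediated + noise(0)
  pct_dbp_5y <- noise(-4)
  pct_sbp_6m <- noise(-6)
  pct_dbp_6m <- noise(-5)

  sbp_6m <- sbp0 * (1 + pct_sbp_6m / 100)
  sbp_5y <- sbp0 * (1 + pct_sbp_5y / 100)
  out <- data.frame(
    subject_id = subj,
    sbp_baseline = sbp0, dbp_baseline = dbp0,
    sbp_month6 = sbp_6m,
    dbp_month6 = pmin(dbp0 * (1 + pct_dbp_6m / 100), sbp_6m - 5),
    sbp_year5 = sbp_5y,
    dbp_year5 = pmin(dbp0 * (1 + pct_dbp_5y / 100), sbp_5y - 5),
    stringsAsFactors = FALSE
  )
  class(out) <- c("bp_panel", "data.frame")
  out
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running all four generators under one config.
#'
#' @param config A [sim_config()].
#' @return A list with `config`, `exposures`, `covariates`, `features`,
#'   `bp`, `truth`, `annotation` (library) and `pathways`.
#' @export
simulate_study <- function(config = sim_config()) {
  exposures <- generate_exposures(config)
  covariates <- generate_covariates(config)
  met <- generate_metabolome(config, exposures)
  bp <- generate_blood_pressure(config, exposures, met$features,
                                met$truth)
  list(config = config, exposures = exposures, covariates = covariates,
       features = met$features, bp = bp, truth = met$truth,
       annotation = annotation_library(), pathways = pathway_library())
}
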