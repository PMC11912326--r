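#' Default chemical panel for the synthetic study
#'
#' Six lipophilic POPs routinely quantified in visceral adipose tissue:
#' three organochlorine pesticides (p,p'-DDE, p,p'-DDT, HCB), two
#' polychlorinated biphenyls (PCB118, PCB153) and one polybrominated
#' diphenyl ether (PBDE47). Geometric means are cohort-scale values in
#' ng/g; geometric SDs are back-solved from geometric-mean confidence
#' intervals at n = 57. LODs are chosen so the LOD/sqrt(2) substitution
#' yields the conventional 0.0707 ng/g floor where censoring occurs.
#'
#' @return A data.frame with columns `name`, `class` (OCP/PCB/PBDE),
#'   `gm` (geometric mean, ng/g), `gsd` (geometric SD, unitless) and
#'   `lod` (limit of detection, ng/g).
#' @export
default_chemicals <- function() {
  data.frame(
    name  = c("pp_DDE", "pp_DDT", "HCB", "PCB118", "PCB153", "PBDE47"),
    class = c("OCP", "OCP", "OCP", "PCB", "PCB", "PBDE"),
    gm    = c(16.1, 0.745, 8.34, 0.683, 0.628, 19.9),
    gsd   = c(1.73, 1.97, 1.16, 1.63, 2.00, 3.33),
    lod   = c(0.1, 0.05, 0.5, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE
  )
}

#' Default rank-correlation target for the exposure copula
#'
#' Two-block Spearman structure: the OCPs correlate 0.5 among themselves,
#' the PCB/PBDE block 0.6, and the blocks 0.15 with each other —
#' consistent with pairwise POP rank correlations spanning roughly
#' -0.2 to 0.9 in adipose-tissue panels. This is an assumption of the
#' generator, not an estimate.
#'
#' @param chemicals A chemical panel as returned by [default_chemicals()].
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @export
default_spearman <- function(chemicals = default_chemicals()) {
  k <- nrow(chemicals)
  cls <- chemicals$class
  block <- ifelse(cls == "OCP", 1L, 2L)
  S <- matrix(0.15, k, k)
  for (b in 1:2) {
    within <- which(block == b)
    S[within, within] <- if (b == 1) 0.5 else 0.6
  }
  diag(S) <- 1
  dimnames(S) <- list(chemicals$name, chemicals$name)
  S
}

# Metabolites identified at level-1 confidence in the cohort analyses:
# mixture-associated (the twelve) plus SBP-change-associated entries.
identified_metabolites <- function() {
  data.frame(
    metabolite = c(
      "palmitoleate", "stearidonic acid", "11-octadecen-9-ynoic acid",
      "arachidonic acid", "histidine", "acetoacetate",
      "3-hydroxyanthranilate", "asparagine", "indole-3-acetate",
      "hypoxanthine", "inosine", "N,N-dimethylarginine",
      "hippuric acid", "N-acetylglutamate", "choline"
    ),
    mz = c(253.2173, 275.2017, 277.2173, 303.2329, 154.0623, 101.0242,
           152.0351, 133.0608, 176.0706, 137.0458, 269.0882, 203.1503,
           178.0509, 188.0563, 139.0765),
    rt = c(335.12, 304.52, 323.27, 340.71, 18.53, 173.66,
           126.77, 294.41, 74.06, 148.33, 183.31, 367.35,
           23.40, 303.47, 43.83),
    mode = c("C18-", "C18-", "C18-", "C18-", "C18-", "HILIC-",
             "HILIC-", "HILIC+", "HILIC+", "HILIC+", "HILIC+", "HILIC+",
             "C18-", "HILIC-", "C18-"),
    confidence = "1",
    stringsAsFactors = FALSE
  )
}

#' Built-in metabolite annotation library
#'
#' Reference entries (name, m/z, retention time in seconds, analytical
#' mode, confidence tier) against which LC-HRMS features are annotated.
#' Level-1 entries are authentic-standard identities; entries named
#' `synthetic-met-###` (and the prostaglandin/linoleate additions marked
#' confidence "annotated") are synthetic fillers generated
#' deterministically so pathway enrichment has a realistic background.
#'
#' @return A data.frame with columns `metabolite`, `mz`, `rt`, `mode`,
#'   `confidence`. Names are unique within a mode.
#' @export
annotation_library <- function() {
  lvl1 <- identified_metabolites()
  extra <- data.frame(
    metabolite = c("linoleate", "prostaglandin E2", "prostaglandin G2",
                   "prostaglandin H2"),
    mz = c(279.2330, 351.2177, 367.2126, 351.2177),
    rt = c(330.50, 310.20, 295.80, 321.40),
    mode = "C18-",
    confidence = "annotated",
    stringsAsFactors = FALSE
  )
  n_syn <- 88L
  i <- seq_len(n_syn)
  modes <- c("C18-", "C18+", "HILIC-", "HILIC+")
  syn <- data.frame(
    metabolite = sprintf("synthetic-met-%03d", i),
    # deterministic low-discrepancy placement over plausible m/z, RT space
    mz = round(85 + (i * 61.8034) %% 700 + (i * 0.0137) %% 1, 4),
    rt = round(15 + (i * 97.11) %% 580, 2),
    mode = modes[(i - 1L) %% 4L + 1L],
    confidence = "annotated",
    stringsAsFactors = FALSE
  )
  # first five synthetic entries sit in C18+ (tryptophan-pathway fillers)
  syn$mode[1:5] <- "C18+"
  rbind(lvl1, extra, syn)
}

#' Built-in pathway definitions
#'
#' Maps pathways to member metabolite names in the annotation library.
#' Membership of the level-1 metabolites follows standard biochemistry
#' (tryptophan, purine, amino-acid and eicosanoid pathways); synthetic
#' entries pad each pathway to a realistic size.
#'
#' @return A data.frame with columns `pathway`, `metabolite`.
#' @export
pathway_library <- function() {
  p <- list(
    "tryptophan metabolism" = c(
      "indole-3-acetate", "3-hydroxyanthranilate", "hippuric acid",
      sprintf("synthetic-met-%03d", 1:5)),
    "arachidonic acid metabolism" = c(
      "arachidonic acid", "prostaglandin E2", "prostaglandin G2",
      "prostaglandin H2", sprintf("synthetic-met-%03d", 6:9)),
    "linoleate metabolism" = c(
      "linoleate", "stearidonic acid", "11-octadecen-9-ynoic acid",
      "arachidonic acid", sprintf("synthetic-met-%03d", 10:12)),
    "histidine metabolism" = c(
      "histidine", sprintf("synthetic-met-%03d", 13:18)),
    "purine metabolism" = c(
      "hypoxanthine", "inosine", sprintf("synthetic-met-%03d", 19:25)),
    "alanine, aspartate and asparagine metabolism" = c(
      "asparagine", "N-acetylglutamate", sprintf("synthetic-met-%03d", 26:31)),
    "ketone body metabolism" = c(
      "acetoacetate", sprintf("synthetic-met-%03d", 32:36)),
    "arginine and proline metabolism" = c(
      "N,N-dimethylarginine", sprintf("synthetic-met-%03d", 37:43)),
    "de novo fatty acid biosynthesis" = c(
      "palmitoleate", sprintf("synthetic-met-%03d", 44:49)),
    "glycine and serine metabolism" = c(
      "hippuric acid", "choline", sprintf("synthetic-met-%03d", 50:55)),
    "synthetic pathway A" = sprintf("synthetic-met-%03d", 56:66),
    "synthetic pathway B" = sprintf("synthetic-met-%03d", 67:78),
    "synthetic pathway C" = sprintf("synthetic-met-%03d", 79:88)
  )
  data.frame(
    pathway = rep(names(p), lengths(p)),
    metabolite = unlist(p, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# Default set of metabolites carrying a planted exposure->feature effect:
# the twelve mixture-associated level-1 identities plus the mediators.
default_planted_metabolites <- function(mediators) {
  twelve <- identified_metabolites()$metabolite[1:12]
  unique(c(twelve, mediators))
}

#' Configuration for a synthetic POP-metabolome-blood-pressure study
#'
#' Bundles every knob of the synthetic-data generator, validated once.
#' Defaults reproduce the study conditions the package targets: 57
#' subjects, six correlated log-normal POPs on the Table-2 concentration
#' scale with LOD censoring, four LC-HRMS analytical modes, baseline
#' blood pressure 127(15)/76(11) mmHg, a planted +6.4% total mixture
#' effect on 5-year SBP percent change partially carried by designated
#' mediator features (exposure->feature -0.729 log2 units per quartile;
#' feature->SBP -3.49% per doubling).
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param chemicals Chemical panel data.frame, see [default_chemicals()].
#' @param spearman_target Target Spearman correlation matrix among
#'   chemicals (symmetric, unit diagonal, positive semidefinite).
#' @param modes Named integer vector: features per analytical mode.
#' @param full_scale If TRUE, use the full cohort-scale feature counts
#'   (3619, 4824, 7615, 5292) instead of `modes`.
#' @param n_signal_features Features per mode carrying the planted
#'   exposure effect (annotated planted metabolites are included first).
#' @param psi_exposure_to_feature Planted effect on log2 feature
#'   intensity per simultaneous one-quartile increase in all chemicals.
#' @param psi_exposure_to_sbp Planted TOTAL effect on 5-year SBP percent
#'   change (percentage points) per simultaneous one-quartile increase.
#' @param beta_feature_to_sbp Percent-change in 5-year SBP per doubling
#'   of a mediator feature's intensity.
#' @param mediator_metabolites Names of annotation-library metabolites
#'   whose matched features mediate part of the exposure effect.
#' @param planted_metabolites Names of library metabolites whose matched
#'   features receive the exposure effect; defaults to the twelve
#'   mixture-associated identities plus the mediators.
#' @param feature_sd Residual SD of log2 feature intensities.
#' @param bp_noise_sd Residual SD of percent-change outcomes (points).
#' @param bp_baseline Named vector `sbp_mean`, `sbp_sd`, `dbp_mean`,
#'   `dbp_sd` (mmHg).
#' @param qc_cv_range Range of fractional QC coefficients of variation
#'   for well-behaved features, within (0, 1).
#' @param n_qc Number of pooled-QC replicate injections.
#' @param missing_rate Fraction of subject cells set missing at random.
#' @param frac_low_detect Fraction of (non-signal) features made nearly
#'   undetectable so the detection-rate filter has work to do.
#' @param frac_high_cv Fraction of (non-signal) features given QC CV
#'   above 30% so the QC filter has work to do.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 57L,
                       chemicals = default_chemicals(),
                       spearman_target = default_spearman(chemicals),
                       modes = c("C18-" = 500L, "C18+" = 500L,
                                 "HILIC-" = 500L, "HILIC+" = 500L),
                       full_scale = FALSE,
                       n_signal_features = 15L,
                       psi_exposure_to_feature = -0.729,
                       psi_exposure_to_sbp = 6.4,
                       beta_feature_to_sbp = -3.49,
                       mediator_metabolites = c("indole-3-acetate",
                                                "hippuric acid",
                                                "3-hydroxyanthranilate",
                                                "synthetic-met-001",
                                                "synthetic-met-002"),
                       planted_metabolites = NULL,
                       feature_sd = 1.0,
                       bp_noise_sd = 12,
                       bp_baseline = c(sbp_mean = 127, sbp_sd = 15,
                                       dbp_mean = 76, dbp_sd = 11),
                       qc_cv_range = c(0.05, 0.20),
                       n_qc = 6L,
                       missing_rate = 0.05,
                       frac_low_detect = 0.03,
                       frac_high_cv = 0.03,
                       seed = 1L) {
  if (full_scale) {
    modes <- c("C18-" = 3619L, "C18+" = 4824L,
               "HILIC-" = 7615L, "HILIC+" = 5292L)
  }
  if (is.null(planted_metabolites)) {
    planted_metabolites <- default_planted_metabolites(mediator_metabolites)
  }
  stopifnot(
    is.data.frame(chemicals),
    all(c("name", "gm", "gsd", "lod") %in% names(chemicals))
  )
  if (n_subjects < 10) {
    stop("n_subjects must be at least 10")
  }
  if (any(chemicals$lod <= 0)) stop("all LODs must be positive")
  if (any(chemicals$gsd <= 1)) stop("geometric SDs must exceed 1")
  validate_spearman_target(spearman_target, nrow(chemicals))
  if (length(qc_cv_range) != 2 || any(qc_cv_range <= 0) ||
      any(qc_cv_range >= 1) || diff(qc_cv_range) < 0) {
    stop("qc_cv_range must be an increasing pair within (0, 1)")
  }
  if (any(modes < 1)) stop("each mode needs at least one feature")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  if (!all(mediator_metabolites %in% planted_metabolites)) {
    stop("mediator_metabolites must be a subset of planted_metabolites")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    chemicals = chemicals,
    spearman_target = spearman_target,
    modes = modes,
    n_signal_features = as.integer(n_signal_features),
    psi_exposure_to_feature = psi_exposure_to_feature,
    psi_exposure_to_sbp = psi_exposure_to_sbp,
    beta_feature_to_sbp = beta_feature_to_sbp,
    mediator_metabolites = mediator_metabolites,
    planted_metabolites = planted_metabolites,
    feature_sd = feature_sd,
    bp_noise_sd = bp_noise_sd,
    bp_baseline = bp_baseline,
    qc_cv_range = qc_cv_range,
    n_qc = as.integer(n_qc),
    missing_rate = missing_rate,
    frac_low_detect = frac_low_detect,
    frac_high_cv = frac_high_cv,
    seed = as.integer(seed)
  ), class = "sim_config")
}

validate_spearman_target <- function(S, k) {
  if (!is.matrix(S) || nrow(S) != k || ncol(S) != k) {
    stop("spearman_target must be a ", k, "x", k, " matrix")
  }
  if (max(abs(S - t(S))) > 1e-10) {
    stop("spearman_target is not symmetric")
  }
  if (max(abs(diag(S) - 1)) > 1e-10) {
    stop("spearman_target must have unit diagonal")
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("spearman_target is not positive semidefinite ",
         "(smallest eigenvalue ", format(min(ev), digits = 4), ")")
  }
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat("  subjects:   ", x$n_subjects, "\n")
  cat("  chemicals:  ", paste(x$chemicals$name, collapse = ", "), "\n")
  cat("  features:   ", paste(sprintf("%s=%d", names(x$modes), x$modes),
                              collapse = ", "), "\n")
  cat("  planted psi(SBP 5y): ", x$psi_exposure_to_sbp,
      " | psi(feature): ", x$psi_exposure_to_feature,
      " | beta(mediator): ", x$beta_feature_to_sbp, "\n", sep = "")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}

# Derived per-stage seeds so each generator is reproducible on its own
# and insensitive to the order in which stages are called.
stage_seed <- function(config, stage) {
  offset <- c(exposures = 101L, covariates = 211L,
              metabolome = 307L, bp = 401L)[[stage]]
  (config$seed %% 100000L) * 10000L + offset
}
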