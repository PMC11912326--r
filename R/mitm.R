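#' Annotate features against a metabolite library
#'
#' A feature matches a same-mode library entry when the m/z agree within
#' `ppm_tol` parts per million (|mz_obs - mz_ref| / mz_ref * 1e6) and
#' the retention times within `rt_tol_s` seconds. All matches are
#' returned, nearest-ppm first within each feature; matching is monotone
#' in both tolerances (widening either never removes a match).
#'
#' @param features A `feature_table` (or its `meta` data.frame).
#' @param library Annotation library data.frame: `metabolite`, `mz`,
#'   `rt`, `mode`, `confidence`.
#' @param ppm_tol m/z tolerance in ppm (default 10).
#' @param rt_tol_s Retention-time tolerance in seconds (default 10).
#' @return data.frame with `feature_id`, `mode`, `metabolite`,
#'   `confidence`, `mz_obs`, `mz_ref`, `ppm`, `rt_obs`, `rt_ref`,
#'   `rt_diff`.
#' @export
annotate_features <- function(features, library, ppm_tol = 10,
                              rt_tol_s = 10) {
  meta <- if (inherits(features, "feature_table")) features$meta
          else features
  empty <- data.frame(feature_id = character(0), mode = character(0),
                      metabolite = character(0),
                      confidence = character(0),
                      mz_obs = numeric(0), mz_ref = numeric(0),
                      ppm = numeric(0), rt_obs = numeric(0),
                      rt_ref = numeric(0), rt_diff = numeric(0),
                      stringsAsFactors = FALSE)
  if (is.null(library) || nrow(library) == 0) {
    warning("empty annotation library; no features annotated")
    return(empty)
  }
  out <- lapply(unique(meta$mode), function(m) {
    f <- meta[meta$mode == m, , drop = FALSE]
    l <- library[library$mode == m, , drop = FALSE]
    if (nrow(f) == 0 || nrow(l) == 0) return(NULL)
    ppm <- abs(outer(f$mz, l$mz, `-`)) / rep(l$mz, each = nrow(f)) * 1e6
    rtd <- abs(outer(f$rt, l$rt, `-`))
    hit <- which(ppm <= ppm_tol & rtd <= rt_tol_s, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    data.frame(
      feature_id = f$feature_id[hit[, 1]], mode = m,
      metabolite = l$metabolite[hit[, 2]],
      confidence = l$confidence[hit[, 2]],
      mz_obs = f$mz[hit[, 1]], mz_ref = l$mz[hit[, 2]],
      ppm = ppm[hit], rt_obs = f$rt[hit[, 1]],
      rt_ref = l$rt[hit[, 2]], rt_diff = rtd[hit],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out[order(match(out$feature_id, meta$feature_id), out$ppm), ,
      drop = FALSE]
}

#' Meet-in-the-middle overlap of the two MWAS scans
#'
#' Intersects the features significant in the exposure->feature scan and
#' the feature->outcome scan at the chosen tier, carrying both effect
#' estimates and any annotations.
#'
#' @param scan1 `mwas_result` for the mixture-on-metabolome direction,
#'   with significance flags (see [flag_significance()]).
#' @param scan2 `mwas_result` for the metabolome-on-outcome direction,
#'   with significance flags.
#' @param tier `"raw"` or `"adjusted"`.
#' @param annotation Optional annotation data.frame from
#'   [annotate_features()].
#' @return data.frame of class `overlap_report`: `feature_id`, `mode`,
#'   `mz`, `rt`, `psi`, `p_exposure`, `beta`, `p_outcome`, `metabolite`,
#'   `confidence`; attribute `tier`.
#' @export
find_overlap <- function(scan1, scan2, tier = c("raw", "adjusted"),
                         annotation = NULL) {
  tier <- match.arg(tier)
  stopifnot(inherits(scan1, "mwas_result"),
            inherits(scan2, "mwas_result"))
  if (length(intersect(scan1$feature_id, scan2$feature_id)) == 0) {
    stop("the two scans share no feature ids")
  }
  col <- paste0("significant_", tier)
  if (is.null(scan1[[col]]) || is.null(scan2[[col]]) ||
      anyNA(scan1[[col]]) || anyNA(scan2[[col]])) {
    stop("significance flags for tier '", tier,
         "' are missing; run flag_significance() first")
  }
  ids <- intersect(scan1$feature_id[scan1[[col]]],
                   scan2$feature_id[scan2[[col]]])
  s1 <- scan1[match(ids, scan1$feature_id), , drop = FALSE]
  s2 <- scan2[match(ids, scan2$feature_id), , drop = FALSE]
  out <- data.frame(
    feature_id = ids, mode = s1$mode, mz = s1$mz, rt = s1$rt,
    psi = s1$estimate, p_exposure = s1$p_value,
    beta = s2$estimate, p_outcome = s2$p_value,
    metabolite = rep(NA_character_, length(ids)),
    confidence = rep(NA_character_, length(ids)),
    stringsAsFactors = FALSE)
  if (!is.null(annotation) && nrow(annotation) > 0) {
    best <- annotation[!duplicated(annotation$feature_id), ,
                       drop = FALSE]
    j <- match(out$feature_id, best$feature_id)
    out$metabolite <- best$metabolite[j]
    out$confidence <- best$confidence[j]
  }
  structure(out, tier = tier,
            class = c("overlap_report", "data.frame"))
}

#' Pathway overrepresentation analysis (one-sided hypergeometric)
#'
#' For each pathway, tests whether significant features are
#' overrepresented among its members, where membership is established by
#' annotation matching of pathway metabolites to feature ids. A pathway
#' is `displayed` (bubble-plot rule) when p < 0.05 and it has at least
#' three significant member features. This is a declared simplification:
#' a Fisher/hypergeometric test over explicit annotations rather than a
#' network-based tentative-annotation algorithm.
#'
#' @param significant_ids Feature ids significant in a scan.
#' @param background_ids All feature ids eligible for the scan
#'   (must contain `significant_ids`).
#' @param pathways data.frame `pathway`, `metabolite`.
#' @param annotation Annotation data.frame mapping features to
#'   metabolites (see [annotate_features()]).
#' @param p_display Display threshold (default 0.05).
#' @param min_hits Minimum significant members to display (default 3).
#' @return data.frame of class `enrichment_result`: `pathway`,
#'   `n_members`, `n_significant`, `p_value`, `displayed`.
#' @export
pathway_ora <- function(significant_ids, background_ids, pathways,
                        annotation, p_display = 0.05, min_hits = 3L) {
  if (!all(significant_ids %in% background_ids)) {
    stop("significant features must be a subset of the background")
  }
  ann <- annotation[annotation$feature_id %in% background_ids, ,
                    drop = FALSE]
  N <- length(unique(background_ids))
  n_sig <- length(unique(significant_ids))
  rows <- lapply(unique(pathways$pathway), function(pw) {
    members <- pathways$metabolite[pathways$pathway == pw]
    member_ids <- unique(ann$feature_id[ann$metabolite %in% members])
    if (length(member_ids) == 0) {
      message("pathway '", pw, "' has no background members; skipped")
      return(NULL)
    }
    K <- length(member_ids)
    k <- length(intersect(member_ids, significant_ids))
    p <- stats::phyper(k - 1, K, N - K, n_sig, lower.tail = FALSE)
    data.frame(pathway = pw, n_members = K, n_significant = k,
               p_value = p,
               displayed = p < p_display & k >= min_hits,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(pathway = character(0), n_members = integer(0),
                      n_significant = integer(0), p_value = numeric(0),
                      displayed = logical(0))
  }
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' Pathways enriched on both sides of the meet-in-the-middle
#'
#' @param enrich1 `enrichment_result` for the exposure side.
#' @param enrich2 `enrichment_result` for the outcome side.
#' @return Character vector of pathways displayed in both runs.
#' @export
overlapped_pathways <- function(enrich1, enrich2) {
  intersect(enrich1$pathway[enrich1$displayed],
            enrich2$pathway[enrich2$displayed])
}

#' Bubble-plot data for enriched pathways
#'
#' Tabular form of the enrichment bubble plot: pathway, -log10 p and the
#' significant-hit count, restricted to displayed pathways.
#'
#' @param enrich An `enrichment_result`.
#' @return data.frame `pathway`, `neg_log10_p`, `hits`.
#' @export
bubble_plot_data <- function(enrich) {
  d <- enrich[enrich$displayed, , drop = FALSE]
  data.frame(pathway = d$pathway,
             neg_log10_p = -log10(d$p_value),
             hits = d$n_significant,
             stringsAsFactors = FALSE)
}

#' Write a minimal SVG bubble plot of enriched pathways
#'
#' @param enrich An `enrichment_result`.
#' @param path Output file path (.svg).
#' @return Invisibly, the path.
#' @export
write_bubble_svg <- function(enrich, path) {
  d <- bubble_plot_data(enrich)
  w <- 640; h <- 40 + 30 * max(1, nrow(d))
  xmax <- max(3, d$neg_log10_p)
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    w, h),
    '<text x="320" y="16" text-anchor="middle" font-size="13">pathway enrichment (-log10 p)</text>')
  if (nrow(d) > 0) {
    for (i in seq_len(nrow(d))) {
      cx <- 220 + 380 * d$neg_log10_p[i] / xmax
      cy <- 30 * i + 20
      r <- 4 + 2 * sqrt(d$hits[i])
      lines <- c(lines,
        sprintf('<circle cx="%.1f" cy="%d" r="%.1f" fill="steelblue" fill-opacity="0.6"/>', cx, cy, r),
        sprintf('<text x="210" y="%d" text-anchor="end" font-size="11">%s</text>',
                cy + 4, d$pathway[i]))
    }
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}
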