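tiny_library <- function() {
  data.frame(
    metabolite = c("indole-3-acetate", "histidine", "decoy"),
    mz = c(176.0706, 154.0623, 176.0706),
    rt = c(74.06, 18.53, 74.06),
    mode = c("HILIC+", "C18-", "C18-"),
    confidence = c("1", "1", "annotated"),
    stringsAsFactors = FALSE)
}

feat_meta <- function(mz, rt, mode, ids = NULL) {
  data.frame(
    feature_id = ids %||% sprintf("F%02d", seq_along(mz)),
    mode = mode, mz = mz, rt = rt, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("annotation matches within ppm and RT tolerance, same mode only", {
  meta <- feat_meta(
    mz = c(176.0706,                 # exact -> 0 ppm match
           176.0706 * (1 + 20e-6),   # 20 ppm off -> no match
           176.0706,                 # RT off by 11 s -> no match
           176.0706),                # right m/z, wrong mode for indole
    rt = c(74.06, 74.06, 85.06, 74.06),
    mode = c("HILIC+", "HILIC+", "HILIC+", "C18-"))
  ann <- annotate_features(meta, tiny_library())
  indole <- ann[ann$metabolite == "indole-3-acetate", ]
  expect_equal(indole$feature_id, "F01")
  expect_equal(indole$ppm, 0)
  # the C18- feature matches the decoy entry of its own mode instead
  expect_equal(ann$metabolite[ann$feature_id == "F04"], "decoy")
  expect_false("F02" %in% ann$feature_id)
  expect_false("F03" %in% ann$feature_id)
})

test_that("annotation is monotone in both tolerances", {
  set.seed(71)
  meta <- feat_meta(mz = runif(60, 150, 200), rt = runif(60, 10, 120),
                    mode = sample(c("HILIC+", "C18-"), 60, TRUE))
  lib <- tiny_library()
  key <- function(a) paste(a$feature_id, a$metabolite)
  for (i in 1:8) {
    ppm1 <- runif(1, 0, 2e4); ppm2 <- ppm1 * runif(1, 1, 3)
    rt1 <- runif(1, 0, 40); rt2 <- rt1 * runif(1, 1, 3)
    narrow <- annotate_features(meta, lib, ppm1, rt1)
    wide_ppm <- annotate_features(meta, lib, ppm2, rt1)
    wide_rt <- annotate_features(meta, lib, ppm1, rt2)
    expect_true(all(key(narrow) %in% key(wide_ppm)))
    expect_true(all(key(narrow) %in% key(wide_rt)))
  }
  expect_warning(out <- annotate_features(meta, lib[0, ]), "empty")
  expect_equal(nrow(out), 0)
})

test_that("multiple matches are all reported, nearest ppm first", {
  lib <- data.frame(
    metabolite = c("close", "closer"),
    mz = c(176.0706 * (1 + 5e-6), 176.0706),
    rt = c(74, 74), mode = "HILIC+", confidence = "annotated",
    stringsAsFactors = FALSE)
  ann <- annotate_features(
    feat_meta(176.0706, 74, "HILIC+"), lib)
  expect_equal(ann$metabolite, c("closer", "close"))
})

fake_scan <- function(ids, p, direction, modes = "C18-") {
  structure(
    data.frame(feature_id = ids, mode = modes,
               mz = seq_along(ids), rt = seq_along(ids),
               estimate = rnorm(length(ids)), se = 1, p_value = p,
               excluded = FALSE, stringsAsFactors = FALSE),
    direction = direction, class = c("mwas_result", "data.frame"))
}

test_that("the overlap is the intersection of significant sets", {
  set.seed(72)
  ids <- sprintf("F%02d", 1:10)
  s1 <- flag_significance(
    fake_scan(ids, c(rep(0.001, 4), rep(0.5, 6)),
              "exposure_to_feature"), 0.01, 0.0005)
  s2 <- flag_significance(
    fake_scan(ids, c(0.5, 0.002, 0.003, 0.5, 0.002, rep(0.5, 5)),
              "feature_to_outcome"), 0.01, 0.0005)
  ov <- find_overlap(s1, s2, "raw")
  expect_setequal(ov$feature_id, c("F02", "F03"))
  # significant on one side only is excluded
  expect_false("F01" %in% ov$feature_id)
  expect_false("F05" %in% ov$feature_id)
  # adjusted-tier overlap nests inside the raw-tier overlap
  ov_adj <- find_overlap(s1, s2, "adjusted")
  expect_true(all(ov_adj$feature_id %in% ov$feature_id))
  # disjoint universes are an error
  s3 <- fake_scan(sprintf("G%02d", 1:4), 0.5, "feature_to_outcome")
  expect_error(find_overlap(s1, flag_significance(s3, 0.01, 1e-4)),
               "share no feature")
})

test_that("ORA p-values equal exhaustive hypergeometric tail sums", {
  # the worked case: pathway of 10 in a background of 100 with 10
  # significant overall, 5 in the pathway
  lib <- data.frame(metabolite = sprintf("M%03d", 1:100),
                    mz = 1:100, rt = 1:100, mode = "C18-",
                    confidence = "annotated")
  ann <- data.frame(feature_id = sprintf("F%03d", 1:100),
                    metabolite = sprintf("M%03d", 1:100),
                    stringsAsFactors = FALSE)
  pw <- data.frame(pathway = "pw1", metabolite = sprintf("M%03d", 1:10))
  sig <- sprintf("F%03d", c(1:5, 50:54))
  res <- pathway_ora(sig, ann$feature_id, pw, ann)
  expect_equal(res$p_value, hyper_tail_oracle(5, 10, 100, 10),
               tolerance = 1e-12)
  expect_true(res$displayed)

  # random instances with background <= 200
  set.seed(73)
  for (i in 1:15) {
    N <- sample(20:200, 1)
    ann_i <- data.frame(feature_id = sprintf("F%03d", 1:N),
                        metabolite = sprintf("M%03d", 1:N),
                        stringsAsFactors = FALSE)
    K <- sample(3:min(30, N), 1)
    pw_i <- data.frame(pathway = "p",
                       metabolite = sprintf("M%03d", sample(N, K)))
    n_sig <- sample(1:(N %/% 2), 1)
    sig_i <- sprintf("F%03d", sample(N, n_sig))
    res_i <- pathway_ora(sig_i, ann_i$feature_id, pw_i, ann_i)
    k <- res_i$n_significant
    expect_equal(res_i$p_value, hyper_tail_oracle(k, K, N, n_sig),
                 tolerance = 1e-12)
  }
})

test_that("the display rule needs p < 0.05 and at least three hits", {
  ann <- data.frame(feature_id = sprintf("F%02d", 1:40),
                    metabolite = sprintf("M%02d", 1:40),
                    stringsAsFactors = FALSE)
  # 2 of 2 members significant: p well under 0.05 but only 2 hits
  pw <- data.frame(pathway = c("small", "small", "big", "big", "big",
                               "big"),
                   metabolite = c("M01", "M02", "M03", "M04", "M05",
                                  "M06"))
  sig <- sprintf("F%02d", 1:6)
  res <- pathway_ora(sig, ann$feature_id, pw, ann)
  expect_false(res$displayed[res$pathway == "small"])
  expect_lt(res$p_value[res$pathway == "small"], 0.05)
  expect_true(res$displayed[res$pathway == "big"])
  # no significant features: all p = 1
  res0 <- pathway_ora(character(0), ann$feature_id, pw, ann)
  expect_true(all(res0$p_value == 1))
  expect_true(all(!res0$displayed))
  # significance must be inside the background
  expect_error(pathway_ora("Z99", ann$feature_id, pw, ann), "subset")
  # empty-membership pathways are skipped with a note
  pw2 <- rbind(pw, data.frame(pathway = "ghost", metabolite = "none"))
  expect_message(res2 <- pathway_ora(sig, ann$feature_id, pw2, ann),
                 "ghost")
  expect_false("ghost" %in% res2$pathway)
})

test_that("overlapped pathways are those displayed on both sides", {
  e1 <- structure(data.frame(
    pathway = c("a", "b", "c"), n_members = 5, n_significant = 3,
    p_value = c(0.01, 0.01, 0.5), displayed = c(TRUE, TRUE, FALSE)),
    class = c("enrichment_result", "data.frame"))
  e2 <- structure(data.frame(
    pathway = c("a", "b", "c"), n_members = 5, n_significant = 3,
    p_value = c(0.02, 0.5, 0.01), displayed = c(TRUE, FALSE, TRUE)),
    class = c("enrichment_result", "data.frame"))
  expect_equal(overlapped_pathways(e1, e2), "a")
  e_empty <- e1[0, ]
  expect_equal(overlapped_pathways(e_empty, e_empty), character(0))
  bp <- bubble_plot_data(e1)
  expect_equal(bp$pathway, c("a", "b"))
  expect_equal(bp$neg_log10_p, -log10(c(0.01, 0.01)))
})
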