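test_that("configuration is validated", {
  expect_error(effect_config(effects = data.frame(
    trait = "nucleus_wl_ratio", outcome = "alizarin_au", r_s = 1.0)),
    "magnitude")
  expect_error(effect_config(effects = data.frame(
    trait = "not_a_trait", outcome = "alizarin_au", r_s = 0.3)),
    "unknown trait")
  expect_error(effect_config(effects = data.frame(
    trait = c("mean_cell_area", "nucleus_wl_ratio"),
    outcome = c("alizarin_au", "alizarin_au"), r_s = c(0.2, 0.3))),
    "one planted trait")
})

test_that("cohort generation respects support constraints and determinism", {
  cfg <- effect_config(n_donors = 56, seed = 17)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 56)
  expect_true(all(co$mean_cell_area > 0))
  expect_true(all(co$nucleus_wl_ratio > 0 & co$nucleus_wl_ratio <= 1))
  expect_true(all(co$cell_wl_ratio > 0 & co$cell_wl_ratio <= 1))
  expect_true(all(co$mean_nucleus_area < co$mean_cell_area))
  expect_identical(co, generate_cohort(cfg))
  # degenerate size: a single donor is fine
  co1 <- generate_cohort(effect_config(n_donors = 1, seed = 2))
  expect_equal(nrow(co1), 1)
})

test_that("zero planted effects leave trait-outcome pairs independent", {
  null_effects <- default_effects()
  null_effects$r_s <- 0
  hits <- vapply(1:40, function(i) {
    tbl <- generate_feature_table(
      effect_config(effects = null_effects, seed = 400 + i))
    max(abs(c(cor(tbl$nucleus_wl_ratio, tbl$alizarin_au, method = "spearman"),
              cor(tbl$cell_area, tbl$proliferation_auc, method = "spearman"),
              cor(tbl$nucleus_wl_ratio, tbl$cd146_pct, method = "spearman"))))
  }, numeric(1))
  expect_gte(mean(hits < 0.3), 0.95)
})

test_that("planted effects are recovered at the target Spearman scale", {
  rs <- t(vapply(1:25, function(i) {
    tbl <- generate_feature_table(effect_config(seed = 500 + i))
    c(osteo = cor(tbl$nucleus_wl_ratio, tbl$alizarin_au, method = "spearman"),
      prolif = cor(tbl$cell_area, tbl$proliferation_auc, method = "spearman"),
      cd146 = cor(tbl$nucleus_wl_ratio, tbl$cd146_pct, method = "spearman"))
  }, numeric(3)))
  means <- colMeans(rs)
  expect_equal(unname(means["osteo"]), -0.5, tolerance = 0.1 / 0.5)
  expect_equal(unname(means["prolif"]), -0.5, tolerance = 0.1 / 0.5)
  expect_equal(unname(means["cd146"]), -0.5, tolerance = 0.1 / 0.5)
})

test_that("assay panel marginals match the emulated cohort statistics", {
  cd <- vapply(1:15, function(i) {
    tbl <- generate_feature_table(effect_config(seed = 600 + i))
    mean(tbl$cd146_pct)
  }, numeric(1))
  expect_equal(mean(cd), 62, tolerance = 10 / 62)
  tbl <- generate_feature_table(effect_config(seed = 601))
  expect_true(all(tbl$lipid_pct > 0))        # log-transformable
  expect_true(all(tbl$cd146_pct >= 0 & tbl$cd146_pct <= 100))
  expect_true(all(is.finite(log(tbl$lipid_pct))))
})

test_that("noiseless growth replicates are identical and PDT-consistent", {
  cfg <- effect_config(n_donors = 4, triplicate_cv = 0, seed = 23)
  co <- generate_cohort(cfg)
  aa <- simulate_assays(co, cfg)
  g1 <- aa$growth[aa$growth$donor_id == co$donor_id[1], ]
  spread <- tapply(g1$count, g1$day, function(v) diff(range(v)))
  expect_true(all(spread < 1e-9))
  m <- tapply(g1$count, g1$day, mean)
  expect_equal(aa$panel$pdt_hours[1],
               120 * log(2) / log(m[["6"]] / m[["1"]]))
  expect_equal(aa$panel$proliferation_auc[1],
               growth_auc(c(1, 3, 6, 9, 12, 15),
                          m[as.character(c(1, 3, 6, 9, 12, 15))]))
})

test_that("feature table is complete, deterministic, and variance-controllable", {
  cfg <- effect_config(n_donors = 56, seed = 29)
  tbl <- generate_feature_table(cfg)
  expect_equal(nrow(tbl), 56)
  expect_false(any(is.na(tbl)))
  expect_identical(tbl, generate_feature_table(cfg))
  expect_true(all(c(morphology_feature_names(), ser_feature_names(),
                    "proliferation_auc", "alizarin_au", "lipid_pct",
                    "cd146_pct") %in% names(tbl)))
  # zero intra-donor variance -> all SD columns are exactly 0
  tbl0 <- generate_feature_table(effect_config(n_donors = 8,
                                               intra_sd_scale = 0, seed = 31))
  sd_cols <- grep("_sd$", names(tbl0), value = TRUE)
  expect_true(all(as.matrix(tbl0[, sd_cols]) == 0))
})
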