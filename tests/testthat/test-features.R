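test_that("morphometry matches closed forms for discs and ellipses", {
  circle <- disc_mask(20) * 1L
  f <- morphology_features(circle, 1)
  expect_equal(f$wl_ratio, 1, tolerance = 0.02)
  expect_equal(f$roundness, 1, tolerance = 0.05)
  expect_equal(f$length, 40, tolerance = 0.05)
  # ellipse with true full axes 30 / 10 um at 1 um/px
  ell <- ellipse_mask(15, 5, theta = 0.4) * 1L
  fe <- morphology_features(ell, 1)
  expect_equal(fe$wl_ratio, 1 / 3, tolerance = 0.06)
  expect_equal(fe$length, 30, tolerance = 0.05)
  expect_equal(fe$area, sum(ell))
  # pixel-size scaling
  fe2 <- morphology_features(ell, 1, pixel_size = 0.5)
  expect_equal(fe2$area, fe$area * 0.25)
  expect_equal(fe2$wl_ratio, fe$wl_ratio)
  expect_error(morphology_features(ell, 99), "not in label map")
})

test_that("morphometry is rotation invariant", {
  for (th in c(0, pi / 4, pi / 3)) {
    f <- morphology_features(ellipse_mask(36, 16, theta = th, size = 91) * 1L, 1)
    f0 <- morphology_features(ellipse_mask(36, 16, theta = 0, size = 91) * 1L, 1)
    expect_equal(f$wl_ratio, f0$wl_ratio, tolerance = 0.02)
    expect_equal(f$area, f0$area, tolerance = 0.02)
    expect_equal(f$length, f0$length, tolerance = 0.02)
  }
})

test_that("SER features vanish on constant regions and stay in [0,1]", {
  m <- matrix(TRUE, 32, 32)
  expect_true(all(ser_features(matrix(0.7, 32, 32), m) == 0))
  set.seed(71)
  for (i in 1:5) {
    img <- matrix(runif(32 * 32), 32, 32)
    v <- ser_features(img, m)
    expect_true(all(v >= 0 & v <= 1))
    expect_named(v, ser_patterns())
  }
  expect_error(ser_features(matrix(1, 8, 8), matrix(FALSE, 8, 8)), "empty mask")
  expect_error(ser_features(matrix(1, 8, 8), matrix(TRUE, 8, 8),
                            patterns = "swirl"), "unknown SER")
})

test_that("ridge responds to lines and spot to blobs", {
  sz <- 41
  line <- matrix(0, sz, sz); line[20:21, 6:36] <- 1
  xs <- outer(seq_len(sz) - 21, seq_len(sz) - 21, function(y, x) x^2 + y^2)
  blob <- exp(-xs / (2 * 3^2))
  m <- matrix(TRUE, sz, sz)
  expect_gt(ser_features(line, m)["ridge"], ser_features(blob, m)["ridge"])
  expect_gt(ser_features(blob, m)["spot"], ser_features(line, m)["spot"])
  # dark counterparts: valley for an inverted line, hole for an inverted blob
  expect_gt(ser_features(1 - line, m)["valley"],
            ser_features(1 - blob, m)["valley"])
  expect_gt(ser_features(1 - blob, m)["hole"], ser_features(1 - line, m)["hole"])
})

test_that("SER features are exactly invariant to 90-degree rotation and intensity scale", {
  set.seed(73)
  img <- matrix(runif(40 * 40), 40, 40)
  mask <- matrix(FALSE, 40, 40); mask[8:30, 5:35] <- TRUE
  v <- ser_features(img, mask)
  rot <- function(m) t(m)[, nrow(m):1]       # 90-degree rotation
  expect_equal(ser_features(rot(img), rot(mask)), v, tolerance = 1e-12)
  expect_equal(ser_features(img * 10, mask), v, tolerance = 1e-6)
  expect_equal(ser_features(img * 10 , mask), v, tolerance = 1e-6)
})

test_that("per-cell extraction recovers planted morphology from clean fields", {
  cfg <- effect_config(n_donors = 1, cells_per_field = 25, field_px = 768,
                       seed = 83)
  donor <- generate_cohort(cfg)[1, ]
  r <- render_field(donor, 1, seed = 84, cfg)
  recs <- extract_cells(r$field, r$truth$nucleus_label_map,
                        r$truth$cell_label_map, donor_id = "D001")
  expect_equal(nrow(recs), 25)
  tt <- r$truth$truth
  expect_equal(recs$nucleus_wl_ratio, tt$nucleus_wl_ratio, tolerance = 1e-9)
  expect_true(all(recs$cell_wl_ratio > 0 & recs$cell_wl_ratio <= 1))
  ser_cols <- grep("^ser_", names(recs), value = TRUE)
  expect_length(ser_cols, 24)
  expect_true(all(as.matrix(recs[, ser_cols]) >= 0 &
                    as.matrix(recs[, ser_cols]) <= 1))
})

test_that("donor aggregation computes mean/SD/CV and flags small donors", {
  rec <- data.frame(donor_id = "D1", field_id = 1, object_id = 1:1000,
                    cell_area = rep(2500, 1000),
                    nucleus_wl_ratio = rep(0.7, 1000))
  prof <- aggregate_donor(rec, min_cells = 1000)
  expect_equal(prof$cell_area, 2500)
  expect_equal(prof$cell_area_sd, 0)
  expect_equal(prof$cell_area_cv, 0)
  expect_false(prof$below_min_cells)
  expect_warning(p2 <- aggregate_donor(rec[1:999, ], min_cells = 1000),
                 "999")
  expect_true(p2$below_min_cells)
  expect_equal(p2$n_cells, 999)
  expect_error(aggregate_donor(rec[0, ]), "no cell records")
  expect_error(aggregate_donor(rbind(rec, within(rec, donor_id <- "D2"))),
               "one donor_id")
})

test_that("extracted donor means track the latent traits end to end", {
  cfg <- effect_config(n_donors = 3, cells_per_field = 40, field_px = 1024,
                       seed = 91)
  cohort <- generate_cohort(cfg)
  sp <- vapply(1:3, function(i) {
    r <- render_field(cohort[i, ], 1, seed = 92 + i, cfg)
    recs <- extract_cells(r$field, r$truth$nucleus_label_map,
                          r$truth$cell_label_map,
                          donor_id = cohort$donor_id[i])
    suppressWarnings(aggregate_donor(recs, min_cells = 10))$nucleus_wl_ratio
  }, numeric(1))
  # donor means from rendered truth within sampling error of latent means
  se <- 0.35 * cohort$nucleus_wl_ratio / sqrt(40)   # intra spread / sqrt(n)
  expect_true(all(abs(sp - cohort$nucleus_wl_ratio) < 0.05 + 3 * se))
})
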