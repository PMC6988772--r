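#' Default bivariate screening pairs
#'
#' The morphology-function pairs screened by default: nucleus and cell
#' geometry against differentiation outcomes, surface markers and
#' proliferation, plus tubulin ridge texture against proliferation.
#' @return Data frame with columns x, y.
#' @export
default_screen_pairs <- function() {
  data.frame(
    x = c("nucleus_wl_ratio", "nucleus_wl_ratio", "nucleus_wl_ratio",
          "nucleus_wl_ratio", "nucleus_area", "nucleus_area",
          "cell_area", "cell_area", "cell_wl_ratio", "ser_ridge_tubulin"),
    y = c("alizarin_au", "lipid_pct", "cd146_pct", "alp_activity_au",
          "proliferation_auc", "alizarin_au",
          "proliferation_auc", "cd146_pct", "cd271_pct", "proliferation_auc"),
    stringsAsFactors = FALSE)
}

# covariate sets for the m2 prediction models (nucleus/cell geometry =
# width-to-length ratio; texture tokens mapped to generated columns)
.m2_osteo <- c("nucleus_wl_ratio", "cell_wl_ratio", "nucleus_length",
               "ser_spot_tubulin")
.m2_adipo <- c("ser_hole_dapi", "nucleus_wl_ratio", "cell_wl_ratio",
               "ser_spot_actin")

#' Run the full simulate / extract / analyze pipeline
#'
#' Orchestrates one reproducible run: synthetic cohort and assay panel;
#' donor feature table (either the analytic fast path or full image
#' rendering + segmentation + feature extraction); ROUT-filtered Spearman
#' correlation screen; median-split differentiation grouping with unpaired
#' t-test and ROC analysis of nucleus geometry; Lasso stability selection
#' with PFER control for the osteogenic and log-transformed adipogenic
#' outcomes; and AIC model ladders (m0/m1/m2). All tables are written to
#' `out_dir` as comma-separated values, with a YAML manifest recording
#' seeds, configuration and a config checksum.
#'
#' @param config An [effect_config()].
#' @param out_dir Output directory (created; must not already contain a
#'   manifest — one directory per run).
#' @param mode "feature_table" (analytic fast path, default) or "images"
#'   (render, segment and extract every field).
#' @param pairs Correlation-screen pairs (default [default_screen_pairs()]).
#' @param stability A [stability_config()] (default seeded from `config`).
#' @param min_cells Donor cell-count threshold for flagging (images mode).
#' @param write_images In images mode, also write field and label TIFFs.
#' @return (Invisibly) a list with the donor table, screen, groups, group
#'   tests, stability results and AIC ladders.
#' @export
run_pipeline <- function(config = effect_config(), out_dir,
                         mode = c("feature_table", "images"),
                         pairs = default_screen_pairs(),
                         stability = stability_config(seed = config$seed + 10L),
                         min_cells = 100, write_images = FALSE) {
  mode <- match.arg(mode)
  stopifnot(!missing(out_dir))
  if (file.exists(file.path(out_dir, "manifest.yaml")))
    stop("out_dir already contains a completed run; use a fresh directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate / extract -------------------------------------------------
  tbl <- stage("simulate", {
    if (mode == "feature_table") {
      generate_feature_table(config)
    } else {
      .image_mode_table(config, out_dir, min_cells, write_images)
    }
  })
  message("donors: ", nrow(tbl), " (mode = ", mode, ")")
  utils::write.csv(tbl, file.path(out_dir, "donor_table.csv"),
                   row.names = FALSE)
  growth <- attr(tbl, "growth")
  if (!is.null(growth))
    utils::write.csv(growth, file.path(out_dir, "growth_counts.csv"),
                     row.names = FALSE)

  # --- bivariate screen ---------------------------------------------------
  screen <- stage("correlate", {
    keep <- pairs$x %in% names(tbl) & pairs$y %in% names(tbl)
    suppressWarnings(correlate_screen(tbl, pairs[keep, , drop = FALSE]))
  })
  message("correlation screen: ", nrow(screen), " pairs, ",
          sum(screen$n_outliers), " outliers removed in total")
  utils::write.csv(screen, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)

  # --- group comparison ---------------------------------------------------
  grp <- stage("groups", {
    g <- classify_differentiation(tbl$alizarin_au, tbl$lipid_pct,
                                  tbl$donor_id)
    ob <- tbl$nucleus_wl_ratio[g$group == "high_OB"]
    ad <- tbl$nucleus_wl_ratio[g$group == "high_AD"]
    tests <- NULL
    if (length(ob) >= 2 && length(ad) >= 2) {
      tt <- ttest_unpaired(ob, ad)
      lab <- g$group[g$group != "unclassified"]
      sc <- -tbl$nucleus_wl_ratio[g$group != "unclassified"]
      roc <- roc_auc(sc, lab == "high_OB")
      tests <- data.frame(feature = "nucleus_wl_ratio",
                          n_high_OB = length(ob), n_high_AD = length(ad),
                          t = tt$t, p = tt$p, auc = roc$auc,
                          ci_low = roc$ci_low, ci_high = roc$ci_high,
                          ci_level = roc$ci_level)
    }
    list(groups = g, tests = tests)
  })
  message("groups: ", sum(grp$groups$group == "high_OB"), " high_OB, ",
          sum(grp$groups$group == "high_AD"), " high_AD")
  utils::write.csv(grp$groups, file.path(out_dir, "diff_groups.csv"),
                   row.names = FALSE)
  if (!is.null(grp$tests))
    utils::write.csv(grp$tests, file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)

  # --- stability selection + AIC ladder -----------------------------------
  feat_cols <- intersect(c(morphology_feature_names(), ser_feature_names()),
                         names(tbl))
  X <- as.matrix(tbl[, feat_cols])
  run_stab <- nrow(tbl) >= 10
  if (!run_stab)
    message("cohort below 10 donors: stability selection and AIC skipped")
  stab <- stage("stabsel", {
    res <- list()
    for (oc in c("osteo", "adipo")) {
      y <- if (oc == "osteo") tbl$alizarin_au else log(tbl$lipid_pct)
      sign_assoc <- vapply(feat_cols, function(v)
        sign(stats::cor(tbl[[v]], y, method = "spearman")), numeric(1))
      if (run_stab) {
        cfg <- stability
        cfg$seed <- stability$seed + (oc == "adipo")
        r <- stability_selection(X, y, cfg)
        ranking <- names(sort(r$pi, decreasing = TRUE))
        ladder <- aic_ladder(cbind(tbl, .outcome_y = y), ".outcome_y", ranking,
                             m2_covariates = if (oc == "osteo") .m2_osteo else .m2_adipo)
      } else {
        r <- NULL; ranking <- character(0); ladder <- NULL
      }
      res[[oc]] <- list(result = r, ranking = ranking, ladder = ladder,
                        sign = sign_assoc)
    }
    res
  })
  for (oc in names(stab)) {
    r <- stab[[oc]]$result
    st_tab <- if (is.null(r)) {
      data.frame(variable = character(0), pi = numeric(0), sign = numeric(0),
                 stable = logical(0))
    } else {
      message("stability [", oc, "]: stable set {",
              paste(r$stable_set, collapse = ", "), "} (q = ", r$q_used, ")")
      data.frame(variable = names(r$pi), pi = unname(r$pi),
                 sign = unname(stab[[oc]]$sign[names(r$pi)]),
                 stable = names(r$pi) %in% r$stable_set)
    }
    utils::write.csv(st_tab,
                     file.path(out_dir, paste0("stability_", oc, ".csv")),
                     row.names = FALSE)
    ld_tab <- if (is.null(stab[[oc]]$ladder)) {
      data.frame(model = character(0), covariates = character(0),
                 n = integer(0), k = integer(0), rss = numeric(0),
                 aic = numeric(0))
    } else stab[[oc]]$ladder
    utils::write.csv(ld_tab, file.path(out_dir, paste0("aic_", oc, ".csv")),
                     row.names = FALSE)
  }

  # --- manifest (written last: marks the run complete) --------------------
  cfg_list <- unclass(config)
  cfg_list$effects <- as.list(config$effects)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg_list, cfg_path)
  yaml::write_yaml(list(
    package = "morphoscreen",
    version = as.character(utils::packageVersion("morphoscreen")),
    seed = config$seed, mode = mode,
    n_donors = config$n_donors,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stability = unclass(stability)),
    file.path(out_dir, "manifest.yaml"))

  invisible(list(table = tbl, screen = screen, groups = grp, stability = stab))
}

# full imaging route: render each donor's fields, segment, extract,
# aggregate, then join the simulated assay panel
.image_mode_table <- function(config, out_dir, min_cells, write_images) {
  cohort <- generate_cohort(config)
  assays <- simulate_assays(cohort, config, seed = config$seed + 1L)
  img_dir <- file.path(out_dir, "fields")
  if (write_images) dir.create(img_dir, showWarnings = FALSE)
  profiles <- lapply(seq_len(nrow(cohort)), function(i) {
    donor <- cohort[i, ]
    recs <- lapply(seq_len(config$fields_per_donor), function(f) {
      rf <- render_field(donor, f, seed = config$seed + 1000L * i + f, config)
      nuc <- segment_nuclei(rf$field$dapi)
      # pixelwise min of the two cytoskeleton channels: filament strokes are
      # channel-specific, so the min keeps the common cell body
      cyto <- pmin(rf$field$actin, rf$field$tubulin)
      cells <- segment_cells(cyto, nuc)
      bids <- border_ids(cells)
      cells <- exclude_border(cells, bids)
      nuc <- exclude_border(nuc, bids)
      if (write_images) {
        base <- sprintf("%s_f%02d", donor$donor_id, f)
        write_field_tiff(rf$field, file.path(img_dir, paste0(base, ".tif")))
        write_label_tiff(cells, file.path(img_dir, paste0(base, "_cells.tif")))
        write_label_tiff(nuc, file.path(img_dir, paste0(base, "_nuclei.tif")))
        write_label_tiff(rf$truth$cell_label_map,
                         file.path(img_dir, paste0(base, "_truth_cells.tif")))
        write_label_tiff(rf$truth$nucleus_label_map,
                         file.path(img_dir, paste0(base, "_truth_nuclei.tif")))
        utils::write.csv(rf$truth$truth,
                         file.path(img_dir, paste0(base, "_truth.csv")),
                         row.names = FALSE)
      }
      extract_cells(rf$field, nuc, cells)
    })
    recs <- do.call(rbind, recs[vapply(recs, nrow, 1L) > 0])
    suppressWarnings(aggregate_donor(recs, min_cells = min_cells))
  })
  prof <- do.call(rbind, profiles)
  merge(prof, assays$panel, by = "donor_id", sort = FALSE)
}

#' Human-readable summary of a completed pipeline run
#'
#' Reads the tables written by [run_pipeline()] and writes/returns a plain
#' text report: correlation screen (pair, r_s, p, n), group comparison
#' (t, p, AUC with CI), and the stability-selection listing (variable,
#' selection probability, sign of association).
#'
#' @param run_dir Directory of a completed run.
#' @param file Output file (default `report.txt` inside `run_dir`).
#' @return (Invisibly) the report lines.
#' @export
make_report <- function(run_dir, file = file.path(run_dir, "report.txt")) {
  need <- function(f) {
    p <- file.path(run_dir, f)
    if (!file.exists(p)) stop("missing table for stage: ", f)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  screen <- need("correlations.csv")
  lines <- c("== morphoscreen run report ==", "",
             "-- correlation screen (ROUT Q=1%, Spearman two-tailed) --")
  for (i in seq_len(nrow(screen)))
    lines <- c(lines, sprintf("  %-22s vs %-20s r_s = %+0.2f  p = %.4g  n = %d",
                              screen$x[i], screen$y[i], screen$r_s[i],
                              screen$p[i], screen$n_used[i]))
  gc_path <- file.path(run_dir, "group_comparison.csv")
  lines <- c(lines, "", "-- high_OB vs high_AD group comparison --")
  if (file.exists(gc_path)) {
    gc <- utils::read.csv(gc_path)
    lines <- c(lines, sprintf(
      "  %s: t = %+0.2f, p = %.4g; ROC AUC = %.2f (%.2f-%.2f, %.1f%% CI); n = %d vs %d",
      gc$feature, gc$t, gc$p, gc$auc, gc$ci_low, gc$ci_high, gc$ci_level,
      gc$n_high_OB, gc$n_high_AD))
  } else {
    lines <- c(lines, "  (groups too small for comparison)")
  }
  for (oc in c("osteo", "adipo")) {
    st <- need(paste0("stability_", oc, ".csv"))
    lines <- c(lines, "", sprintf("-- stability selection (%s outcome) --", oc))
    st <- st[order(-st$pi), ]
    top <- st[st$pi > 0, ]
    if (nrow(st) == 0 || sum(st$stable) == 0)
      lines <- c(lines, "  no stable predictors")
    for (i in seq_len(min(nrow(top), 8)))
      lines <- c(lines, sprintf("  %-24s pi = %.2f  (%s)%s", top$variable[i],
                                top$pi[i],
                                ifelse(top$sign[i] < 0, "negative", "positive"),
                                ifelse(top$stable[i], "  [stable]", "")))
    ld <- need(paste0("aic_", oc, ".csv"))
    if (nrow(ld) == 3)
      lines <- c(lines, sprintf("  AIC ladder: m0 = %.1f, m1 = %.1f, m2 = %.1f",
                                ld$aic[1], ld$aic[2], ld$aic[3]))
  }
  writeLines(lines, file)
  invisible(lines)
}
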