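#' Cohort / effect configuration for the synthetic generator
#'
#' Defines the simulated study conditions: cohort size, cells per donor,
#' donor-level trait marginals, intra-donor spread, and the planted
#' trait-outcome Spearman effects. Defaults emulate a 56-donor bone-marrow
#' MSC cohort: nucleus width/length ratio negatively associated with
#' osteoblastic outcome and with CD146+ fraction, and mean cell area
#' negatively associated with proliferation AUC (all at the -0.5 Spearman
#' scale).
#'
#' Effects are planted through a Gaussian copula: each trait is a monotone
#' transform (log-normal for areas, logit-normal for ratios) of a standard
#' normal latent, and each affected outcome is monotone in a latent
#' rho * z_trait + sqrt(1 - rho^2) * eps with rho = 2 sin(pi r_s / 6), the
#' Pearson latent correlation that yields Spearman r_s for a bivariate
#' normal pair. Monotone marginals preserve the rank correlation.
#'
#' @param n_donors Cohort size (default 56).
#' @param cells_per_donor Cells aggregated per donor (default 1000).
#' @param effects Data frame with columns `trait`, `outcome`, `r_s` (target
#'   Spearman, |r_s| < 1). At most one planted trait per outcome.
#' @param osteo_adipo_link Optional Spearman link between the osteo and
#'   adipo outcome latents (default 0 = independent).
#' @param triplicate_cv Multiplicative log-normal noise CV on growth-count
#'   replicates (default 0.10).
#' @param intra_sd_scale Multiplier on the intra-donor cell-to-cell spread
#'   (1 = default heterogeneity, 0 = identical cells within a donor).
#' @param fields_per_donor,cells_per_field,field_px,pixel_size Imaging-mode
#'   geometry: fields rendered per donor, target cells per field, square
#'   field side in pixels, and micrometres per pixel.
#' @param seed Integer RNG seed.
#' @return A list of class `effect_config`.
#' @export
effect_config <- function(n_donors = 56, cells_per_donor = 1000,
                          effects = default_effects(),
                          osteo_adipo_link = 0,
                          triplicate_cv = 0.10, intra_sd_scale = 1,
                          fields_per_donor = 3, cells_per_field = 20,
                          field_px = 1024, pixel_size = 1,
                          seed = 1L) {
  stopifnot(n_donors >= 1, cells_per_donor >= 1,
            all(c("trait", "outcome", "r_s") %in% names(effects)))
  if (any(abs(effects$r_s) >= 1) || abs(osteo_adipo_link) >= 1)
    stop("target correlation magnitudes must be < 1")
  if (anyDuplicated(effects$outcome))
    stop("at most one planted trait per outcome")
  bad <- setdiff(effects$trait, names(.trait_marginals))
  if (length(bad) > 0) stop("unknown trait(s): ", paste(bad, collapse = ", "))
  structure(list(
    n_donors = as.integer(n_donors),
    cells_per_donor = as.integer(cells_per_donor),
    effects = effects, osteo_adipo_link = osteo_adipo_link,
    triplicate_cv = triplicate_cv, intra_sd_scale = intra_sd_scale,
    fields_per_donor = as.integer(fields_per_donor),
    cells_per_field = as.integer(cells_per_field),
    field_px = as.integer(field_px), pixel_size = pixel_size,
    seed = as.integer(seed)), class = "effect_config")
}

#' Default planted effects
#' @return Data frame of the three default (trait, outcome, r_s) effects.
#' @export
default_effects <- function() {
  data.frame(
    trait   = c("nucleus_wl_ratio", "mean_cell_area", "nucleus_wl_ratio"),
    outcome = c("alizarin_au", "proliferation_auc", "cd146_pct"),
    r_s     = c(-0.5, -0.5, -0.5),
    stringsAsFactors = FALSE)
}

# donor-level trait marginals: monotone transforms of N(0,1) latents.
# Areas um^2 (log-normal), ratios dimensionless in (0,1] (logit-normal).
.trait_marginals <- list(
  mean_cell_area        = function(z) exp(log(3000) + 0.30 * z),
  cell_wl_ratio         = function(z) stats::plogis(stats::qlogis(0.45) + 0.30 * z),
  mean_nucleus_area     = function(z) exp(log(380) + 0.25 * z),
  nucleus_wl_ratio      = function(z) stats::plogis(stats::qlogis(0.72) + 0.35 * z),
  texture_intensity     = function(z) exp(0.30 * z),
  mean_cell_roundness   = function(z) stats::plogis(stats::qlogis(0.40) + 0.30 * z),
  mean_nucleus_roundness = function(z) stats::plogis(stats::qlogis(0.80) + 0.30 * z)
)

# inverse transforms (trait value -> latent), used to recover latents from a
# cohort table so simulate_assays works on any cohort-shaped input
.trait_inverses <- list(
  mean_cell_area        = function(v) (log(v) - log(3000)) / 0.30,
  cell_wl_ratio         = function(v) (stats::qlogis(v) - stats::qlogis(0.45)) / 0.30,
  mean_nucleus_area     = function(v) (log(v) - log(380)) / 0.25,
  nucleus_wl_ratio      = function(v) (stats::qlogis(v) - stats::qlogis(0.72)) / 0.35,
  texture_intensity     = function(v) log(v) / 0.30,
  mean_cell_roundness   = function(v) (stats::qlogis(v) - stats::qlogis(0.40)) / 0.30,
  mean_nucleus_roundness = function(v) (stats::qlogis(v) - stats::qlogis(0.80)) / 0.30
)

# intra-donor spread (log / logit scale sd) used for cell-level sampling
.intra_sd <- c(cell_area = 0.35, cell_wl_ratio = 0.40,
               nucleus_area = 0.25, nucleus_wl_ratio = 0.35,
               cell_roundness = 0.35, nucleus_roundness = 0.30)

# Pearson latent correlation giving Spearman r_s for a bivariate normal pair
.rho_from_rs <- function(r_s) 2 * sin(pi * r_s / 6)

#' Generate a donor cohort with known latent morphology traits
#'
#' Draws donor-level traits from log-normal (areas) / logit-normal (ratios)
#' marginals on correlated standard-normal latents (cell and nucleus area
#' latents share r = 0.6; all other trait pairs are independent). The
#' nucleus-inside-cell invariant is enforced (nucleus area capped at 45% of
#' cell area).
#'
#' @param config An [effect_config()].
#' @return Data frame of class `donor_cohort`, one row per donor, with the
#'   trait columns and a `latents` attribute (donor x trait latent normals).
#' @export
generate_cohort <- function(config = effect_config()) {
  stopifnot(inherits(config, "effect_config"))
  n <- config$n_donors
  set.seed(config$seed)

  z_ca <- stats::rnorm(n)
  z_na <- 0.6 * z_ca + sqrt(1 - 0.36) * stats::rnorm(n)
  z_cr <- stats::rnorm(n)
  z_nr <- stats::rnorm(n)
  z_tx <- stats::rnorm(n)
  z_crd <- 0.3 * z_cr + sqrt(1 - 0.09) * stats::rnorm(n)
  z_nrd <- 0.3 * z_nr + sqrt(1 - 0.09) * stats::rnorm(n)

  z <- cbind(mean_cell_area = z_ca, cell_wl_ratio = z_cr,
             mean_nucleus_area = z_na, nucleus_wl_ratio = z_nr,
             texture_intensity = z_tx,
             mean_cell_roundness = z_crd, mean_nucleus_roundness = z_nrd)

  cohort <- data.frame(donor_id = sprintf("D%03d", seq_len(n)),
                       stringsAsFactors = FALSE)
  for (tr in colnames(z)) cohort[[tr]] <- .trait_marginals[[tr]](z[, tr])
  cohort$mean_nucleus_area <- pmin(cohort$mean_nucleus_area,
                                   0.45 * cohort$mean_cell_area)
  attr(cohort, "latents") <- z
  attr(cohort, "config") <- config
  class(cohort) <- c("donor_cohort", "data.frame")
  cohort
}

# latent normal for one trait, recovered from the cohort's stored latents or
# by inverting the marginal transform
.trait_latent <- function(cohort, trait) {
  z <- attr(cohort, "latents")
  if (!is.null(z) && trait %in% colnames(z)) return(z[, trait])
  if (!trait %in% names(cohort)) stop("trait not in cohort: ", trait)
  .trait_inverses[[trait]](cohort[[trait]])
}

# outcome latent: planted rho * z_trait + sqrt(1-rho^2) * noise, or pure
# noise when no effect is planted on this outcome
.outcome_latent <- function(cohort, config, outcome, eps) {
  row <- config$effects[config$effects$outcome == outcome, , drop = FALSE]
  if (nrow(row) == 0) return(eps)
  rho <- .rho_from_rs(row$r_s[1])
  rho * .trait_latent(cohort, row$trait[1]) + sqrt(1 - rho^2) * eps
}

#' Simulate the per-donor functional assay panel
#'
#' Simulates, for every donor in the cohort: triplicate growth counts at
#' days 1, 3, 6, 9, 12, 15 (logistic growth from 1,000 seeded cells, donor
#' growth rate log-normal around 0.238/day so the cohort PDT centres near
#' 76.5 h, multiplicative replicate noise), alizarin red intensity (AU),
#' ALP activity (AU per viability unit), Oil-Red-O lipid area (%), and CD
#' marker percentages (CD146 62 +/- 30, CD271 26 +/- 25, ALP+ 26 +/- 16,
#' CD44/73/90/105 near-uniform high, all clipped to [0, 100]). Planted
#' trait-outcome effects from the config enter through the outcome latents.
#' Proliferation AUC and PDT are computed from the simulated counts with
#' [growth_auc()] and [population_doubling_time()].
#'
#' @param cohort A `donor_cohort` (or any data frame with the trait
#'   columns).
#' @param config The [effect_config()] used to generate the cohort.
#' @param seed RNG seed (default `config$seed + 1`).
#' @return List of class `assay_panel`: `panel` (one row per donor) and
#'   `growth` (long data frame donor_id / day / replicate / count).
#' @export
simulate_assays <- function(cohort, config = attr(cohort, "config"),
                            seed = config$seed + 1L) {
  stopifnot(is.data.frame(cohort), inherits(config, "effect_config"))
  n <- nrow(cohort)
  set.seed(seed)
  days <- c(1, 3, 6, 9, 12, 15)

  # growth: logistic, rate monotone in the proliferation latent
  u <- .outcome_latent(cohort, config, "proliferation_auc", stats::rnorm(n))
  rate <- 0.238 * exp(0.42 * u)          # per day
  n0 <- 1000; K <- 2e5
  sdlog <- sqrt(log(1 + config$triplicate_cv^2))
  growth <- do.call(rbind, lapply(seq_len(n), function(i) {
    mu <- K * n0 * exp(rate[i] * days) / (K + n0 * (exp(rate[i] * days) - 1))
    data.frame(donor_id = cohort$donor_id[i],
               day = rep(days, each = 3),
               replicate = rep(1:3, length(days)),
               count = rep(mu, each = 3) *
                 exp(stats::rnorm(3 * length(days), -sdlog^2 / 2, sdlog)),
               stringsAsFactors = FALSE)
  }))

  day_means <- function(id) {
    g <- growth[growth$donor_id == id, ]
    tapply(g$count, g$day, mean)[as.character(days)]
  }
  auc <- vapply(cohort$donor_id, function(id) growth_auc(days, day_means(id)),
                numeric(1))
  pdt <- vapply(cohort$donor_id, function(id) {
    m <- day_means(id)
    if (m["6"] > m["1"]) population_doubling_time(m["1"], m["6"]) else NA_real_
  }, numeric(1))

  # differentiation outcomes
  v_ost <- .outcome_latent(cohort, config, "alizarin_au", stats::rnorm(n))
  alizarin <- pmax(2 + 0.6 * v_ost, 0)

  eps_ad <- stats::rnorm(n)
  if (config$osteo_adipo_link != 0) {
    rl <- .rho_from_rs(config$osteo_adipo_link)
    eps_ad <- rl * v_ost + sqrt(1 - rl^2) * eps_ad
  }
  w_ad <- .outcome_latent(cohort, config, "lipid_pct", eps_ad)
  lipid <- 100 * stats::plogis(stats::qlogis(0.10) + 0.8 * w_ad)

  v_alp <- .outcome_latent(cohort, config, "alp_activity_au", stats::rnorm(n))
  alp_act <- exp(log(0.5) + 0.4 * v_alp)

  clip01 <- function(x) pmin(pmax(x, 0), 100)
  cd146 <- clip01(62 + 30 * .outcome_latent(cohort, config, "cd146_pct",
                                            stats::rnorm(n)))
  cd271 <- clip01(26 + 25 * .outcome_latent(cohort, config, "cd271_pct",
                                            stats::rnorm(n)))
  alp_pos <- clip01(26 + 16 * .outcome_latent(cohort, config, "alp_pos_pct",
                                              stats::rnorm(n)))
  cd44  <- clip01(99.87 + 0.21 * stats::rnorm(n))
  cd73  <- clip01(99.75 + 0.28 * stats::rnorm(n))
  cd90  <- clip01(99.24 + 0.81 * stats::rnorm(n))
  cd105 <- clip01(99.88 + 0.08 * stats::rnorm(n))

  panel <- data.frame(
    donor_id = cohort$donor_id,
    proliferation_auc = unname(auc), pdt_hours = unname(pdt),
    alizarin_au = alizarin, alp_activity_au = alp_act, lipid_pct = lipid,
    cd146_pct = cd146, cd271_pct = cd271, alp_pos_pct = alp_pos,
    cd44_pct = cd44, cd73_pct = cd73, cd90_pct = cd90, cd105_pct = cd105,
    stringsAsFactors = FALSE)
  structure(list(panel = panel, growth = growth), class = "assay_panel")
}

#' SER feature column names
#' @param patterns Texture pattern tokens (default the eight implemented).
#' @param channels Channel tokens.
#' @return Character vector `ser_<pattern>_<channel>`.
#' @export
ser_feature_names <- function(patterns = ser_patterns(),
                              channels = c("dapi", "actin", "tubulin")) {
  as.vector(t(outer(patterns, channels, function(p, c) paste0("ser_", p, "_", c))))
}

#' Morphology feature column names (donor-mean level)
#' @return Character vector of the ten morphometry features.
#' @export
morphology_feature_names <- function() {
  c("cell_area", "cell_width", "cell_length", "cell_wl_ratio",
    "cell_roundness", "nucleus_area", "nucleus_width", "nucleus_length",
    "nucleus_wl_ratio", "nucleus_roundness")
}

#' Donor-level feature + assay table (fast path)
#'
#' Produces the per-donor aggregated feature table directly from the latent
#' cohort draw, bypassing image rendering: morphometry donor means are the
#' latent traits plus cell-sampling noise (scaled by 1/sqrt(cells_per_donor)),
#' SD/CV columns reflect the intra-donor spread, SER texture donor means are
#' logit-normal with tubulin/actin ridge tied to the donor's filament
#' density (texture_intensity). Uses the identical latent draw as
#' [generate_cohort()] under the same seed, then joins the simulated assay
#' panel.
#'
#' @param config An [effect_config()].
#' @return Data frame, one row per donor: trait-derived feature means,
#'   `<feature>_sd` and `<feature>_cv` columns, `n_cells`, and all assay
#'   panel columns. Attributes `cohort` and `growth` carry the inputs.
#' @export
generate_feature_table <- function(config = effect_config()) {
  cohort <- generate_cohort(config)
  assays <- simulate_assays(cohort, config, seed = config$seed + 1L)
  n <- nrow(cohort); nc <- config$cells_per_donor
  iss <- config$intra_sd_scale
  set.seed(config$seed + 2L)

  # observed donor means = latent trait x mean-sampling noise (log scale)
  samp <- function(true, sdlog) true * exp(stats::rnorm(n, 0, iss * sdlog / sqrt(nc)))
  feat <- data.frame(donor_id = cohort$donor_id, stringsAsFactors = FALSE)
  feat$cell_area    <- samp(cohort$mean_cell_area, .intra_sd["cell_area"])
  feat$cell_wl_ratio <- samp(cohort$cell_wl_ratio, .intra_sd["cell_wl_ratio"])
  feat$nucleus_area <- samp(cohort$mean_nucleus_area, .intra_sd["nucleus_area"])
  feat$nucleus_wl_ratio <- samp(cohort$nucleus_wl_ratio, .intra_sd["nucleus_wl_ratio"])
  feat$cell_roundness <- samp(cohort$mean_cell_roundness, .intra_sd["cell_roundness"])
  feat$nucleus_roundness <- samp(cohort$mean_nucleus_roundness, .intra_sd["nucleus_roundness"])
  # full axis lengths of the area/ratio-equivalent ellipse
  feat$cell_length <- sqrt(4 * feat$cell_area / (pi * feat$cell_wl_ratio))
  feat$cell_width  <- feat$cell_length * feat$cell_wl_ratio
  feat$nucleus_length <- sqrt(4 * feat$nucleus_area / (pi * feat$nucleus_wl_ratio))
  feat$nucleus_width  <- feat$nucleus_length * feat$nucleus_wl_ratio

  # SER texture donor means: ridge on cytoskeletal channels tracks filament
  # density; remaining pattern/channel combinations are independent donor traits
  z_tx <- .trait_latent(cohort, "texture_intensity")
  for (nm in ser_feature_names()) {
    if (nm %in% c("ser_ridge_actin", "ser_ridge_tubulin")) {
      zz <- 0.8 * z_tx + sqrt(1 - 0.64) * stats::rnorm(n)
    } else {
      zz <- stats::rnorm(n)
    }
    feat[[nm]] <- stats::plogis(stats::qlogis(0.15) + 0.5 * zz +
                                  stats::rnorm(n, 0, iss * 0.5 / sqrt(nc)))
  }

  # intra-donor SD / CV columns (SD on the feature's own scale)
  sd_map <- c(cell_area = "cell_area", cell_wl_ratio = "cell_wl_ratio",
              nucleus_area = "nucleus_area", nucleus_wl_ratio = "nucleus_wl_ratio",
              cell_roundness = "cell_roundness", nucleus_roundness = "nucleus_roundness",
              cell_length = "cell_area", cell_width = "cell_area",
              nucleus_length = "nucleus_area", nucleus_width = "nucleus_area")
  all_feats <- c(morphology_feature_names(), ser_feature_names())
  for (nm in all_feats) {
    sdlog <- if (nm %in% names(sd_map)) .intra_sd[[sd_map[[nm]]]] else 0.5
    # log/logit-scale intra sd mapped to the feature scale, with sampling noise
    sd_est <- feat[[nm]] * iss * sdlog *
      exp(stats::rnorm(n, 0, 1 / sqrt(2 * max(nc - 1, 1))))
    feat[[paste0(nm, "_sd")]] <- sd_est
    feat[[paste0(nm, "_cv")]] <- sd_est / feat[[nm]]
  }
  feat$n_cells <- nc

  out <- merge(feat, assays$panel, by = "donor_id", sort = FALSE)
  attr(out, "cohort") <- cohort
  attr(out, "growth") <- assays$growth
  out
}
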