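#' Render one multi-channel fluorescence field with ground truth
#'
#' Draws the donor's cells as non-overlapping smoothed convex blobs
#' (ellipses with a small low-order radial perturbation) with per-cell area
#' and axis ratio sampled around the donor means, nuclei as interior
#' ellipses aligned with the cell axis, and three channels: DAPI (nucleus
#' fill), actin and tubulin (faint cell body plus oriented filament strokes
#' whose density scales with the donor's texture_intensity, Gaussian-blurred
#' at sigma = 1 px). All channels receive a background gradient and Gaussian
#' noise. Placement is by dart throwing with bounded retries; cells may clip
#' the field edge (border objects are part of the ground truth).
#'
#' @param donor One row of a `donor_cohort` (data frame with the trait
#'   columns).
#' @param field_index Field number (used only as metadata).
#' @param seed Integer RNG seed for this field.
#' @param config An [effect_config()] supplying field geometry
#'   (`field_px`, `pixel_size`, `cells_per_field`, `intra_sd_scale`).
#' @param noise_sd Gaussian pixel noise SD (default 0.01).
#' @return List with `field` (class `image_field`: channel matrices `dapi`,
#'   `actin`, `tubulin`, plus metadata) and `truth` (class `ground_truth`:
#'   `nucleus_label_map`, `cell_label_map`, per-object `truth` table with
#'   requested and rasterized areas, axis lengths, ratios, border flag).
#' @export
render_field <- function(donor, field_index = 1L, seed = 1L,
                         config = effect_config(), noise_sd = 0.01) {
  stopifnot(is.data.frame(donor), nrow(donor) == 1)
  S <- config$field_px
  ps <- config$pixel_size
  n_cells <- config$cells_per_field
  iss <- config$intra_sd_scale
  set.seed(seed)

  rl <- function(mean, sdlog) {           # log-normal around a donor mean
    s <- iss * sdlog
    mean * exp(stats::rnorm(n_cells, -s^2 / 2, s))
  }
  rr <- function(mean, sdlog) {           # logit-normal around a donor mean
    stats::plogis(stats::qlogis(mean) + stats::rnorm(n_cells, 0, iss * sdlog))
  }
  cell_area <- rl(donor$mean_cell_area, .intra_sd["cell_area"]) / ps^2   # px
  cell_ratio <- rr(donor$cell_wl_ratio, .intra_sd["cell_wl_ratio"])
  nuc_area <- pmin(rl(donor$mean_nucleus_area, .intra_sd["nucleus_area"]) / ps^2,
                   0.45 * cell_area)
  nuc_ratio <- rr(donor$nucleus_wl_ratio, .intra_sd["nucleus_wl_ratio"])

  a_c <- sqrt(cell_area / (pi * cell_ratio)); b_c <- a_c * cell_ratio
  theta <- stats::runif(n_cells, 0, pi)

  # dart-throwing placement, bounded retries; bounding circles must not touch
  cx <- cy <- numeric(n_cells)
  ord <- order(a_c, decreasing = TRUE)
  placed_r <- numeric(0); placed_x <- numeric(0); placed_y <- numeric(0)
  for (i in ord) {
    ok <- FALSE
    for (try in seq_len(300)) {
      px <- stats::runif(1, 1, S); py <- stats::runif(1, 1, S)
      if (length(placed_r) == 0 ||
          all((placed_x - px)^2 + (placed_y - py)^2 >
              (placed_r + a_c[i] + 2)^2)) { ok <- TRUE; break }
    }
    if (!ok) stop("placement error: cannot fit ", n_cells,
                  " non-overlapping cells in a ", S, "x", S, " field")
    cx[i] <- px; cy[i] <- py
    placed_x <- c(placed_x, px); placed_y <- c(placed_y, py)
    placed_r <- c(placed_r, a_c[i])
  }

  # nucleus axes, aligned with the cell (small angular jitter), kept interior
  a_n <- sqrt(nuc_area / (pi * nuc_ratio)); b_n <- a_n * nuc_ratio
  shrink <- pmin(1, 0.88 * a_c / a_n, 0.88 * b_c / b_n)
  a_n <- a_n * shrink; b_n <- b_n * shrink
  theta_n <- theta + stats::rnorm(n_cells, 0, 0.12)

  cell_lab <- matrix(0L, S, S)   # [row = y, col = x]
  nuc_lab <- matrix(0L, S, S)

  # low-order radial perturbation coefficients per cell (smoothed blob)
  p1 <- stats::runif(n_cells, 0, 0.04); ph1 <- stats::runif(n_cells, 0, 2 * pi)
  p2 <- stats::runif(n_cells, 0, 0.03); ph2 <- stats::runif(n_cells, 0, 2 * pi)

  fill_ellipse <- function(lab, id, cx, cy, a, b, th, pert = NULL) {
    R <- ceiling(a) + 2L
    xs <- max(1L, floor(cx - R)):min(S, ceiling(cx + R))
    ys <- max(1L, floor(cy - R)):min(S, ceiling(cy + R))
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    u <- (dx * cos(th) + dy * sin(th)) / a
    v <- (-dx * sin(th) + dy * cos(th)) / b
    r2 <- u^2 + v^2
    if (is.null(pert)) {
      inside <- r2 <= 1
    } else {
      phi <- atan2(v, u)
      m <- 1 + pert$p1 * cos(2 * phi + pert$ph1) + pert$p2 * cos(3 * phi + pert$ph2)
      inside <- sqrt(r2) <= m
    }
    sub <- lab[ys, xs, drop = FALSE]
    sub[inside] <- id
    lab[ys, xs] <- sub
    lab
  }

  for (i in seq_len(n_cells)) {
    cell_lab <- fill_ellipse(cell_lab, i, cx[i], cy[i], a_c[i], b_c[i], theta[i],
                             pert = list(p1 = p1[i], ph1 = ph1[i],
                                         p2 = p2[i], ph2 = ph2[i]))
    nuc_lab <- fill_ellipse(nuc_lab, i, cx[i], cy[i], a_n[i], b_n[i], theta_n[i])
  }
  nuc_lab[cell_lab == 0] <- 0L           # containment by construction

  # ground truth from the rasterized masks
  truth <- .truth_table(cell_lab, nuc_lab, ps)
  truth$cell_area_um2_requested <- cell_area[truth$object_id] * ps^2
  truth$nucleus_area_um2_requested <- (pi * a_n * b_n)[truth$object_id] * ps^2

  # channels
  dapi <- matrix(0, S, S)
  bright_n <- exp(stats::rnorm(n_cells, 0, 0.10))
  for (i in seq_len(n_cells)) dapi[nuc_lab == i] <- 0.75 * bright_n[i]

  body <- 0.12 * (cell_lab > 0)
  actin <- body + .filament_layer(cell_lab, cx, cy, a_c, b_c, theta,
                                  donor$texture_intensity, n_cells)
  tubulin <- body + .filament_layer(cell_lab, cx, cy, a_c, b_c, theta,
                                    donor$texture_intensity, n_cells)
  actin <- .gauss_smooth(actin, 1); tubulin <- .gauss_smooth(tubulin, 1)
  dapi <- .gauss_smooth(dapi, 0.5)

  grad <- 0.02 + 0.02 * outer(rep(1, S), seq_len(S) / S)
  addn <- function(ch) pmin(pmax(ch + grad +
    matrix(stats::rnorm(S * S, 0, noise_sd), S, S), 0), 1)

  field <- structure(list(dapi = addn(dapi), actin = addn(actin),
                          tubulin = addn(tubulin),
                          pixel_size = ps, donor_id = donor$donor_id,
                          field_index = as.integer(field_index)),
                     class = "image_field")
  gt <- structure(list(nucleus_label_map = nuc_lab, cell_label_map = cell_lab,
                       truth = truth), class = "ground_truth")
  list(field = field, truth = gt)
}

# per-object truth table from label maps (moment-based axes)
.truth_table <- function(cell_lab, nuc_lab, ps) {
  ids <- sort(setdiff(unique(as.vector(cell_lab)), 0L))
  cm <- .shape_moments(cell_lab, ids, ps)
  nm <- .shape_moments(nuc_lab, ids, ps)
  S <- dim(cell_lab)
  border <- vapply(ids, function(id) {
    any(cell_lab[1, ] == id) || any(cell_lab[S[1], ] == id) ||
      any(cell_lab[, 1] == id) || any(cell_lab[, S[2]] == id)
  }, logical(1))
  data.frame(object_id = ids,
             cell_area_px = cm$n_px, cell_area = cm$area,
             cell_width = cm$width, cell_length = cm$length,
             cell_wl_ratio = cm$wl_ratio,
             nucleus_area_px = nm$n_px, nucleus_area = nm$area,
             nucleus_width = nm$width, nucleus_length = nm$length,
             nucleus_wl_ratio = nm$wl_ratio,
             border = border)
}

# oriented filament strokes clipped to each cell mask
.filament_layer <- function(cell_lab, cx, cy, a_c, b_c, theta, tex, n_cells) {
  S <- nrow(cell_lab)
  layer <- matrix(0, S, S)
  n_fil <- pmax(2L, round(5 * tex * exp(stats::rnorm(n_cells, 0, 0.2))))
  for (i in seq_len(n_cells)) {
    for (f in seq_len(n_fil[i])) {
      # anchor inside the ellipse, stroke direction loosely along the cell axis
      rho <- sqrt(stats::runif(1)); phi <- stats::runif(1, 0, 2 * pi)
      ax <- cx[i] + rho * (a_c[i] * cos(phi) * cos(theta[i]) -
                             b_c[i] * sin(phi) * sin(theta[i])) * 0.8
      ay <- cy[i] + rho * (a_c[i] * cos(phi) * sin(theta[i]) +
                             b_c[i] * sin(phi) * cos(theta[i])) * 0.8
      ang <- theta[i] + stats::rnorm(1, 0, 0.5)
      len <- stats::runif(1, 0.5, 1.6) * a_c[i]
      tt <- seq(-len / 2, len / 2, by = 0.4)
      xs <- round(ax + tt * cos(ang)); ys <- round(ay + tt * sin(ang))
      ok <- xs >= 1 & xs <= S & ys >= 1 & ys <= S
      xs <- xs[ok]; ys <- ys[ok]
      if (length(xs) == 0) next
      idx <- cbind(ys, xs)
      inside <- cell_lab[idx] == i
      idx <- idx[inside, , drop = FALSE]
      layer[idx] <- pmin(layer[idx] + 0.45, 0.8)
    }
  }
  layer
}

# separable Gaussian smoothing with replicated edges (deterministic,
# equivariant under 90-degree grid rotation)
.gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad <- function(m, r) m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), ]
  conv_rows <- function(m) {
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[j:(j + nrow(m) - 1), ]
    out
  }
  t(conv_rows(t(conv_rows(img))))
}
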