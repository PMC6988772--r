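#' The implemented SER texture pattern tokens
#' @return Character vector of the eight pattern tokens.
#' @export
ser_patterns <- function() {
  c("spot", "edge", "ridge", "saddle", "valley", "hole", "bright", "dark")
}

# second-moment shape descriptors for a set of label ids.
# Axis lengths come from the equivalent ellipse: a solid ellipse with
# semi-axes A >= B has eigenvalues A^2/4, B^2/4 of its pixel covariance, so
# full lengths are 4*sqrt(lambda). A 1/12 pixel self-variance term keeps
# single-pixel objects finite.
.shape_moments <- function(labels, ids, pixel_size = 1) {
  pos <- which(labels > 0)
  lab <- labels[pos]
  rows <- (pos - 1) %% nrow(labels) + 1
  cols <- (pos - 1) %/% nrow(labels) + 1
  by_id <- split(seq_along(pos), lab)
  out <- data.frame(object_id = ids, n_px = 0L, area = 0,
                    width = NA_real_, length = NA_real_,
                    wl_ratio = NA_real_, roundness = NA_real_)
  for (k in seq_along(ids)) {
    sel <- by_id[[as.character(ids[k])]]
    n <- length(sel)
    out$n_px[k] <- n
    out$area[k] <- n * pixel_size^2
    if (n == 0) next
    x <- cols[sel]; y <- rows[sel]
    mxx <- stats::var(x) * (n - 1) / n + 1 / 12
    myy <- stats::var(y) * (n - 1) / n + 1 / 12
    mxy <- if (n > 1) stats::cov(x, y) * (n - 1) / n else 0
    tr <- mxx + myy
    dd <- sqrt(max((mxx - myy)^2 + 4 * mxy^2, 0))
    l1 <- (tr + dd) / 2; l2 <- (tr - dd) / 2
    L <- 4 * sqrt(max(l1, 0)) * pixel_size
    W <- 4 * sqrt(max(l2, 0)) * pixel_size
    out$length[k] <- L; out$width[k] <- W
    out$wl_ratio[k] <- if (L > 0) W / L else 1
    out$roundness[k] <- if (L > 0) 4 * out$area[k] / (pi * L^2) else 1
  }
  out
}

#' Morphometry of one segmented object
#'
#' Area (pixel count times pixel_size^2), full width and length of the
#' second-moment-equivalent ellipse, width-to-length ratio, and roundness
#' defined as 4*area / (pi * length^2) (1 for a circle, smaller for
#' elongated or irregular objects).
#'
#' @param labels Integer label map.
#' @param object_id Object id (must exist in `labels`).
#' @param pixel_size Micrometres per pixel.
#' @return One-row data frame: object_id, n_px, area, width, length,
#'   wl_ratio, roundness.
#' @export
morphology_features <- function(labels, object_id, pixel_size = 1) {
  if (!object_id %in% labels) stop("object_id ", object_id, " not in label map")
  .shape_moments(labels, object_id, pixel_size)
}

#' Morphometry table for every object in a label map
#' @inheritParams morphology_features
#' @return Data frame, one row per object id.
#' @export
morphology_table <- function(labels, pixel_size = 1) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  .shape_moments(labels, ids, pixel_size)
}

#' SER texture features over a masked region
#'
#' Gaussian-derivative pattern responses at a fixed scale: the channel is
#' smoothed at sigma = scale, then per pixel the gradient magnitude g and
#' the Hessian eigenvalues lambda1 <= lambda2 drive nonnegative response
#' maps — spot (both eigenvalues negative: sqrt(l1*l2)), hole (both
#' positive), ridge (l1 strongly negative, |l2| small: max(-l1-|l2|, 0)),
#' valley (l2 strongly positive: max(l2-|l1|, 0)), saddle (l1 < 0 < l2:
#' sqrt(-l1*l2)), edge (g), bright/dark (intensity above/below the region
#' mean). Each feature is the mean response over the mask divided by the
#' maximum of the corresponding magnitude over the mask (total curvature
#' sqrt(l1^2+l2^2) for Hessian patterns, max g for edge, max |I - mean| for
#' bright/dark), so features lie in [0, 1], are exactly invariant to
#' intensity rescaling, and are 0 on a constant region.
#'
#' @param channel Numeric intensity matrix.
#' @param mask Logical matrix (same shape) or integer label map with
#'   `object_id`.
#' @param scale Gaussian scale in pixels (default 1).
#' @param object_id Required when `mask` is a label map.
#' @param patterns Which pattern tokens to return (default all eight).
#' @return Named numeric vector of pattern responses in [0, 1].
#' @export
ser_features <- function(channel, mask, scale = 1, object_id = NULL,
                         patterns = ser_patterns()) {
  stopifnot(scale > 0, all(dim(channel) == dim(mask)))
  unknown <- setdiff(patterns, ser_patterns())
  if (length(unknown) > 0)
    stop("unknown SER pattern(s): ", paste(unknown, collapse = ", "))
  m <- if (is.logical(mask)) mask else {
    if (is.null(object_id)) mask > 0 else mask == object_id
  }
  if (!any(m)) stop("empty mask")
  maps <- .ser_response_maps(channel, scale)
  .ser_aggregate(maps, which(m))[patterns]
}

# response maps shared by all objects of one channel (computed once)
.ser_response_maps <- function(channel, scale) {
  sm <- .gauss_smooth(channel, scale)
  gx <- .cdiff_cols(sm); gy <- .cdiff_rows(sm)
  ixx <- .cdiff_cols(gx); iyy <- .cdiff_rows(gy); ixy <- .cdiff_rows(gx)
  tr <- ixx + iyy
  dd <- sqrt(pmax((ixx - iyy)^2 + 4 * ixy^2, 0))
  l1 <- (tr - dd) / 2; l2 <- (tr + dd) / 2      # l1 <= l2
  g <- sqrt(gx^2 + gy^2)
  list(channel = channel,
       spot   = ifelse(l2 < 0, sqrt(pmax(l1 * l2, 0)), 0),
       hole   = ifelse(l1 > 0, sqrt(pmax(l1 * l2, 0)), 0),
       ridge  = pmax(-l1 - abs(l2), 0),
       valley = pmax(l2 - abs(l1), 0),
       saddle = ifelse(l1 < 0 & l2 > 0, sqrt(pmax(-l1 * l2, 0)), 0),
       edge   = g,
       curv   = sqrt(l1^2 + l2^2))
}

# masked, normalized features from precomputed maps; idx = pixel indices
.ser_aggregate <- function(maps, idx) {
  nf <- function(r, denom) {
    d <- max(denom)
    if (d <= 0) 0 else mean(r) / d
  }
  curv <- maps$curv[idx]; g <- maps$edge[idx]
  dev <- maps$channel[idx] - mean(maps$channel[idx])
  c(spot = nf(maps$spot[idx], curv), edge = nf(g, g),
    ridge = nf(maps$ridge[idx], curv), saddle = nf(maps$saddle[idx], curv),
    valley = nf(maps$valley[idx], curv), hole = nf(maps$hole[idx], curv),
    bright = nf(pmax(dev, 0), abs(dev)), dark = nf(pmax(-dev, 0), abs(dev)))
}

# central differences with replicated edges
.cdiff_rows <- function(m) {
  n <- nrow(m)
  (m[c(2:n, n), ] - m[c(1, 1:(n - 1)), ]) / 2
}
.cdiff_cols <- function(m) t(.cdiff_rows(t(m)))

#' Extract per-cell records from one segmented field
#'
#' Combines cell and nucleus morphometry with SER texture per channel: DAPI
#' texture over each nucleus mask, actin and tubulin texture over each cell
#' mask. Column names follow `<compartment>_<feature>` and
#' `ser_<pattern>_<channel>`.
#'
#' @param field An `image_field` (channel matrices dapi/actin/tubulin).
#' @param nucleus_labels,cell_labels Integer label maps sharing ids.
#' @param pixel_size Micrometres per pixel (default from the field).
#' @param donor_id,field_id Identifier metadata.
#' @param ser_scale SER scale in pixels (default 1).
#' @param patterns SER pattern tokens to extract.
#' @return Data frame, one row per retained cell id.
#' @export
extract_cells <- function(field, nucleus_labels, cell_labels,
                          pixel_size = field$pixel_size,
                          donor_id = field$donor_id,
                          field_id = field$field_index,
                          ser_scale = 1, patterns = ser_patterns()) {
  ids <- sort(intersect(setdiff(unique(as.vector(cell_labels)), 0L),
                        setdiff(unique(as.vector(nucleus_labels)), 0L)))
  if (length(ids) == 0) {
    return(data.frame())
  }
  cm <- .shape_moments(cell_labels, ids, pixel_size)
  nm <- .shape_moments(nucleus_labels, ids, pixel_size)
  names(cm)[-1] <- paste0("cell_", names(cm)[-1])
  names(nm)[-1] <- paste0("nucleus_", names(nm)[-1])

  # response maps are computed once per channel; each object then only
  # aggregates over its own pixel indices
  maps <- list(dapi = .ser_response_maps(field$dapi, ser_scale),
               actin = .ser_response_maps(field$actin, ser_scale),
               tubulin = .ser_response_maps(field$tubulin, ser_scale))
  nuc_idx <- split(which(nucleus_labels > 0),
                   nucleus_labels[nucleus_labels > 0])
  cell_idx <- split(which(cell_labels > 0), cell_labels[cell_labels > 0])
  ser_rows <- lapply(ids, function(id) {
    k <- as.character(id)
    c(stats::setNames(.ser_aggregate(maps$dapi, nuc_idx[[k]])[patterns],
                      paste0("ser_", patterns, "_dapi")),
      stats::setNames(.ser_aggregate(maps$actin, cell_idx[[k]])[patterns],
                      paste0("ser_", patterns, "_actin")),
      stats::setNames(.ser_aggregate(maps$tubulin, cell_idx[[k]])[patterns],
                      paste0("ser_", patterns, "_tubulin")))
  })
  ser_df <- as.data.frame(do.call(rbind, ser_rows))

  cbind(data.frame(donor_id = donor_id, field_id = field_id,
                   object_id = ids, stringsAsFactors = FALSE),
        cm[, c("cell_area", "cell_width", "cell_length", "cell_wl_ratio",
               "cell_roundness")],
        nm[, c("nucleus_area", "nucleus_width", "nucleus_length",
               "nucleus_wl_ratio", "nucleus_roundness")],
        ser_df)
}

#' Aggregate per-cell records into a donor profile
#'
#' Per-feature mean, SD and CV (CV only where the mean is positive) over all
#' cells of one donor, with the cell count. Donors below `min_cells` are
#' flagged, not dropped.
#'
#' @param records Data frame of per-cell records sharing one donor_id.
#' @param min_cells Minimum cells for a donor to be considered fully
#'   powered (default 1000).
#' @return One-row data frame: donor_id, feature means (plain name),
#'   `<feature>_sd`, `<feature>_cv`, `n_cells`, `below_min_cells`.
#' @export
aggregate_donor <- function(records, min_cells = 1000) {
  if (nrow(records) == 0) stop("no cell records to aggregate")
  ids <- unique(records$donor_id)
  if (length(ids) != 1) stop("records must share one donor_id")
  feat_cols <- setdiff(names(records),
                       c("donor_id", "field_id", "object_id",
                         "cell_n_px", "nucleus_n_px"))
  out <- data.frame(donor_id = ids, stringsAsFactors = FALSE)
  for (nm in feat_cols) {
    v <- records[[nm]]
    mu <- mean(v, na.rm = TRUE)
    sd_v <- stats::sd(v, na.rm = TRUE)
    if (nrow(records) == 1) sd_v <- 0
    out[[nm]] <- mu
    out[[paste0(nm, "_sd")]] <- sd_v
    out[[paste0(nm, "_cv")]] <- if (is.finite(mu) && mu > 0) sd_v / mu else NA_real_
  }
  out$n_cells <- nrow(records)
  out$below_min_cells <- nrow(records) < min_cells
  if (out$below_min_cells)
    warning("donor ", ids, ": only ", nrow(records), " cells (< ", min_cells, ")")
  out
}
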