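#' Segment nuclei from a DAPI channel
#'
#' Background-corrected global Otsu threshold, hole filling, and a
#' distance-transform watershed to split touching nuclei; objects below
#' `min_area` pixels are discarded. Returns an integer label map
#' (background 0).
#'
#' @param nucleus_channel Numeric intensity matrix with finite values.
#' @param min_area Minimum nucleus area in pixels (default 30 at ~1 um/px;
#'   rejects sub-nuclear debris).
#' @param watershed_tolerance Minimum distance-map depth between split
#'   objects (default 1).
#' @return Integer label map (matrix), empty (all zero) with a warning for
#'   a blank image.
#' @export
segment_nuclei <- function(nucleus_channel, min_area = 30,
                           watershed_tolerance = 1) {
  stopifnot(is.matrix(nucleus_channel), all(is.finite(nucleus_channel)))
  img <- nucleus_channel - stats::median(nucleus_channel)
  img[img < 0] <- 0
  rng <- max(img)
  if (rng <= 0) {
    warning("blank nucleus channel: no foreground")
    return(matrix(0L, nrow(nucleus_channel), ncol(nucleus_channel)))
  }
  img <- img / rng
  th <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  mask <- img > th
  if (!any(mask)) {
    warning("no foreground after thresholding")
    return(matrix(0L, nrow(nucleus_channel), ncol(nucleus_channel)))
  }
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  lab <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(lab)),
                nrow(nucleus_channel), ncol(nucleus_channel))
  .drop_small(lab, min_area)
}

#' Segment cells from a cytoskeleton channel, seeded by nuclei
#'
#' Seeded region growing (Voronoi-based propagation on the smoothed
#' cytoskeleton intensity) constrained to a foreground mask; each cell
#' inherits the id of its seed nucleus, and every retained cell mask is a
#' superset of its nucleus mask. Nuclei whose seed falls outside the
#' foreground mask keep the nucleus footprint as the cell (with a warning
#' from the mask union).
#'
#' @param cyto_channel Numeric intensity matrix (actin, tubulin, or their
#'   sum).
#' @param nuclei Integer nucleus label map (seeds).
#' @param smooth_sigma Gaussian smoothing in pixels before thresholding
#'   (default 2).
#' @return Integer cell label map with the same ids as `nuclei`.
#' @export
segment_cells <- function(cyto_channel, nuclei, smooth_sigma = 2) {
  stopifnot(all(dim(cyto_channel) == dim(nuclei)))
  if (!any(nuclei > 0)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  sm <- .flatten_background(.gauss_smooth(cyto_channel, smooth_sigma))
  sm0 <- sm
  sm0[sm0 < 0] <- 0
  rng <- max(sm0)
  fg <- if (rng > 0) {
    # two-pass: Otsu finds the foreground, then the final cut sits at the
    # half-maximum between background and the cell-body level (40th
    # percentile of foreground — robust to bright filament pixels; the
    # half-maximum of a blurred step edge recovers the true boundary)
    t1 <- EBImage::otsu(EBImage::Image(sm0 / rng), range = c(0, 1)) * rng
    body <- stats::quantile(sm0[sm0 > t1], 0.40, names = FALSE)
    sm0 > body / 2
  } else matrix(FALSE, nrow(nuclei), ncol(nuclei))
  fg <- fg | nuclei > 0                    # seeds always inside the mask
  lab <- EBImage::propagate(EBImage::Image(sm), EBImage::Image(nuclei),
                            mask = EBImage::Image(fg * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(nuclei), ncol(nuclei))
  lab[nuclei > 0] <- nuclei[nuclei > 0]    # containment guarantee
  lab
}

#' Ids of objects touching the image border
#' @param labels Integer label map.
#' @return Integer vector of border-touching ids.
#' @export
border_ids <- function(labels) {
  edge <- c(labels[1, ], labels[nrow(labels), ],
            labels[, 1], labels[, ncol(labels)])
  sort(setdiff(unique(edge), 0L))
}

#' Remove border-touching objects from a label map
#'
#' Any object touching any image edge is removed; surviving ids are
#' preserved (no relabelling). To deselect border cells from paired
#' cell/nucleus maps, pass the cell map's [border_ids()] as `ids` to both.
#'
#' @param labels Integer label map.
#' @param ids Ids to remove (default: the map's own border-touching ids).
#' @return Label map with the given ids zeroed.
#' @export
exclude_border <- function(labels, ids = border_ids(labels)) {
  if (length(ids) > 0) labels[labels %in% ids] <- 0L
  labels
}

# illumination correction: fit a planar background to the below-median
# pixels (sampled) and subtract it
.flatten_background <- function(img) {
  n <- length(img)
  idx <- which(img <= stats::median(img))
  if (length(idx) > 20000) idx <- idx[seq(1, length(idx), length.out = 20000)]
  y <- (idx - 1) %% nrow(img) + 1
  x <- (idx - 1) %/% nrow(img) + 1
  fit <- stats::lm.fit(cbind(1, x, y), img[idx])
  co <- fit$coefficients
  xx <- outer(rep(1, nrow(img)), seq_len(ncol(img)))
  yy <- outer(seq_len(nrow(img)), rep(1, ncol(img)))
  img - (co[1] + co[2] * xx + co[3] * yy)
}

.drop_small <- function(lab, min_area) {
  if (min_area <= 1) return(lab)
  tab <- tabulate(lab[lab > 0])
  small <- which(tab > 0 & tab < min_area)
  if (length(small) > 0) lab[lab %in% small] <- 0L
  lab
}
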