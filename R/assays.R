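#' Growth-curve area under the curve
#'
#' Trapezoidal integral of mean cell count over culture day; replicate
#' counts are averaged per day first. Expressed in arbitrary units
#' (count x day).
#'
#' @param days Strictly increasing numeric vector of culture days.
#' @param counts Numeric vector of mean counts, or a matrix with one row per
#'   day and one column per replicate.
#' @return Numeric AUC.
#' @examples
#' growth_auc(c(1, 3, 6, 9, 12, 15), rep(100, 6))  # 14 * 100
#' @export
growth_auc <- function(days, counts) {
  if (is.matrix(counts)) counts <- rowMeans(counts)
  stopifnot(length(days) == length(counts))
  if (length(days) < 2) stop("need at least two time points")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (any(counts < 0)) stop("negative counts")
  sum(diff(days) * (utils::head(counts, -1) + utils::tail(counts, -1)) / 2)
}

#' Population doubling time between day 1 and day 6
#'
#' PDT = 120 h * log(2) / log(N_day6 / N_day1). The formula is
#' logarithm-base invariant; natural log is used.
#'
#' @param n_day1,n_day6 Cell counts (> 0) at days 1 and 6.
#' @return Doubling time in hours.
#' @examples
#' population_doubling_time(1000, 4000)  # 60 h
#' @export
population_doubling_time <- function(n_day1, n_day6) {
  stopifnot(n_day1 > 0, n_day6 > 0)
  if (n_day6 <= n_day1)
    stop("PDT undefined: culture did not grow between day 1 and day 6")
  120 * log(2) / log(n_day6 / n_day1)
}

#' Quantify alizarin red staining intensity
#'
#' Mean (default) or integrated red-signal intensity above the image
#' background, in arbitrary units; monotone in the amount of stain.
#' Background is estimated as the median of the red channel (mineralized
#' nodules cover a minority of a well image).
#'
#' @param image Numeric matrix (single channel) or 3-d array
#'   (height x width x channel, red first), values in [0, 1].
#' @param statistic "mean" (mean signal over the image) or "integrated"
#'   (summed signal).
#' @return Arbitrary-unit staining intensity (0 for a blank image).
#' @export
quantify_alizarin <- function(image, statistic = c("mean", "integrated")) {
  statistic <- match.arg(statistic)
  red <- if (length(dim(image)) == 3) image[, , 1] else image
  stopifnot(all(is.finite(red)))
  # lower-quantile background: robust up to ~80% stain coverage
  bg <- stats::quantile(red, 0.2, names = FALSE)
  signal <- pmax(red - bg, 0)
  if (statistic == "mean") mean(signal) else sum(signal)
}

#' Quantify lipid-droplet area fraction
#'
#' Per image, droplet pixels are those above a fixed intensity threshold on
#' a [0, 1] scale; the droplet area fraction (%) is averaged across images
#' (six fields per sample in the standard protocol).
#'
#' @param images A list of numeric matrices (or a single matrix), values in
#'   [0, 1].
#' @param threshold Droplet intensity threshold (default 0.5).
#' @return Mean droplet area percentage in [0, 100].
#' @export
quantify_lipid_area <- function(images, threshold = 0.5) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1)
  fracs <- vapply(images, function(im) 100 * mean(im > threshold), numeric(1))
  mean(fracs)
}

#' ALP enzymatic activity normalized per cell number
#'
#' Absorbance at 405 nm divided by a cell-viability signal, giving activity
#' per viability unit (scale-invariant to joint dilution).
#'
#' @param absorbance_405 Absorbance reading (AU).
#' @param viability_signal Viability (cell number surrogate) signal, > 0.
#' @return Normalized ALP activity (AU).
#' @export
alp_activity <- function(absorbance_405, viability_signal) {
  stopifnot(is.finite(absorbance_405), is.finite(viability_signal))
  if (viability_signal <= 0) stop("viability signal must be > 0")
  absorbance_405 / viability_signal
}

#' Median-split differentiation grouping
#'
#' Classifies donors by contrasting differentiation potential: `high_OB`
#' when the osteoblastic outcome is strictly above the cohort median and the
#' adipocytic outcome strictly below it; `high_AD` for the reverse. Donors
#' at a median, or high (or low) in both, are `unclassified`. Medians are
#' computed over the full cohort.
#'
#' @param osteo,adipo Per-donor outcome vectors (equal length >= 4, no NAs).
#' @param donor_id Optional identifiers.
#' @return Data frame: donor_id, group (factor high_OB / high_AD /
#'   unclassified).
#' @export
classify_differentiation <- function(osteo, adipo, donor_id = NULL) {
  stopifnot(length(osteo) == length(adipo), length(osteo) >= 4,
            all(is.finite(osteo)), all(is.finite(adipo)))
  if (is.null(donor_id)) donor_id <- seq_along(osteo)
  m_o <- stats::median(osteo); m_a <- stats::median(adipo)
  group <- rep("unclassified", length(osteo))
  group[osteo > m_o & adipo < m_a] <- "high_OB"
  group[adipo > m_a & osteo < m_o] <- "high_AD"
  if (all(group == "unclassified"))
    warning("no donor classified (degenerate or tied outcomes)")
  data.frame(donor_id = donor_id,
             group = factor(group, levels = c("high_OB", "high_AD", "unclassified")),
             stringsAsFactors = FALSE)
}
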