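#' Unpaired two-tailed Student's t-test
#'
#' Pooled-variance Student t-test (equal variances assumed), two-tailed.
#'
#' @param a,b Numeric vectors, each with n >= 2.
#' @return List with `t`, `p` (two-tailed), `df`, and group sizes.
#' @export
ttest_unpaired <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n_a = length(a), n_b = length(b))
}

#' ROC curve AUC with DeLong confidence interval
#'
#' Area under the ROC curve by the rank (Mann-Whitney) formulation with
#' midrank ties, with a DeLong confidence interval at the configured level
#' (clamped to [0, 1]).
#'
#' Orientation: with the default `orientation = "fixed"`, AUC estimates
#' P(score of a positive > score of a negative) and may fall below 0.5 — the
#' estimator is unbiased at 0.5 for scores independent of labels.
#' `orientation = "auto"` folds the reported AUC to >= 0.5 and flags the
#' direction; use it only for exploratory reporting since folding biases a
#' null AUC upward.
#'
#' @param score Numeric vector.
#' @param label Binary vector (logical, 0/1, or two-level factor); TRUE/1 is
#'   the positive class.
#' @param ci_level Confidence level in percent (default 97.5).
#' @param orientation "fixed" (default) or "auto".
#' @return List with `auc`, `ci_low`, `ci_high`, `ci_level`, `n_pos`,
#'   `n_neg`, and `direction` ("positives_higher" or "positives_lower").
#' @export
roc_auc <- function(score, label, ci_level = 97.5, orientation = c("fixed", "auto")) {
  orientation <- match.arg(orientation)
  lab <- if (is.factor(label)) label == levels(label)[2] else as.logical(label)
  stopifnot(length(score) == length(lab), !any(is.na(lab)), all(is.finite(score)))
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")

  # rank (Mann-Whitney) AUC with midrank ties: fixed direction
  r <- rank(score)
  auc <- (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  direction <- "positives_higher"
  if (orientation == "auto" && auc < 0.5) {
    auc <- 1 - auc
    direction <- "positives_lower"
  }

  # DeLong CI via pROC on the oriented score
  sc <- if (direction == "positives_lower") -score else score
  roc <- pROC::roc(response = lab, predictor = sc, direction = "<",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  ci <- tryCatch(
    suppressWarnings(as.numeric(
      pROC::ci.auc(roc, conf.level = ci_level / 100, method = "delong"))),
    error = function(e) c(auc, auc, auc)   # degenerate (e.g. all ties)
  )
  list(auc = auc,
       ci_low = max(0, min(ci[1], auc)), ci_high = min(1, max(ci[3], auc)),
       ci_level = ci_level, n_pos = n_pos, n_neg = n_neg,
       direction = direction)
}
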