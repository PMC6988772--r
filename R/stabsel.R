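#' Stability-selection configuration
#'
#' @param n_subsamples Number of random subsamples (default 50).
#' @param theta Selection-probability threshold for the stable set, in
#'   (0.5, 1] (default 0.75).
#' @param pfer Per-family error rate: budget on the expected number of
#'   falsely selected variables (default 2).
#' @param q Per-subsample active-set size; if NULL, derived from the PFER
#'   bound via [q_from_pfer()].
#' @param subsample_fraction Fraction of donors per subsample, drawn without
#'   replacement (default 0.5).
#' @param seed Integer RNG seed.
#' @return A list of class `stability_config`.
#' @export
stability_config <- function(n_subsamples = 50, theta = 0.75, pfer = 2,
                             q = NULL, subsample_fraction = 0.5, seed = 1L) {
  stopifnot(theta > 0.5, theta <= 1, pfer > 0, n_subsamples >= 2,
            subsample_fraction > 0, subsample_fraction <= 1)
  if (!is.null(q)) stopifnot(q >= 1)
  structure(list(n_subsamples = as.integer(n_subsamples), theta = theta,
                 pfer = pfer, q = q, subsample_fraction = subsample_fraction,
                 seed = as.integer(seed)),
            class = "stability_config")
}

#' Per-subsample active-set size consistent with a PFER budget
#'
#' Inverts the stability-selection error bound
#' E(false selections) <= q^2 / ((2 theta - 1) p): returns the largest
#' integer q with q^2 / ((2 theta - 1) p) <= pfer, at least 1, at most p.
#'
#' @param pfer Expected-false-selection budget (> 0).
#' @param theta Threshold probability in (0.5, 1].
#' @param p Number of candidate predictors.
#' @return Integer q.
#' @examples
#' q_from_pfer(2, 0.75, 50)  # 7
#' @export
q_from_pfer <- function(pfer, theta, p) {
  stopifnot(pfer > 0, theta > 0.5, theta <= 1)
  if (p <= 0) stop("p must be positive")
  q <- floor(sqrt(pfer * (2 * theta - 1) * p))
  as.integer(min(max(q, 1), p))
}

#' First q variables on the Lasso regularization path
#'
#' Computes the Lasso path from the fully penalized (all-zero) end and
#' returns the set of the first `q` distinct variables to attain nonzero
#' coefficients. When more than the remaining budget of variables enter at
#' one path step, ties are broken toward the lowest column index and the
#' event is flagged.
#'
#' @param X Numeric matrix (rows = samples); columns are standardized
#'   internally. Zero-variance columns are excluded with a warning.
#' @param y Numeric response.
#' @param q Number of variables to select (>= 1).
#' @return Integer vector of column indices (a set, unordered); attribute
#'   `tie_break` is TRUE if the q-th slot was resolved by a tie-break.
#' @export
lasso_first_q <- function(X, y, q) {
  stopifnot(is.matrix(X), nrow(X) == length(y), q >= 1)
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) warning("excluding ", sum(!keep), " zero-variance column(s)")
  idx_map <- which(keep)
  Xs <- scale(X[, keep, drop = FALSE])
  q <- min(q, ncol(Xs))

  fit <- glmnet::glmnet(Xs, y, family = "gaussian", standardize = FALSE,
                        nlambda = 200, lambda.min.ratio = 1e-4,
                        thresh = 1e-12)
  beta <- fit$beta                      # p x nlambda sparse matrix
  selected <- integer(0)
  tie_break <- FALSE
  for (j in seq_len(ncol(beta))) {
    active <- which(beta[, j] != 0)
    new <- setdiff(active, selected)
    if (length(new) > 0) {
      room <- q - length(selected)
      if (length(new) > room) {
        new <- sort(new)[seq_len(room)]  # lowest column index wins
        tie_break <- TRUE
      }
      selected <- c(selected, new)
    }
    if (length(selected) >= q) break
  }
  out <- sort(idx_map[selected])
  attr(out, "tie_break") <- tie_break
  out
}

#' Lasso stability selection with PFER control
#'
#' Draws `n_subsamples` subsamples of size floor(n * subsample_fraction)
#' without replacement, runs [lasso_first_q()] on each (predictors are
#' re-standardized within each subsample), and reports each variable's
#' selection probability pi_j = (times selected) / n_subsamples. The stable
#' set is {j : pi_j >= theta}; q comes from the PFER bound unless overridden
#' in the config.
#'
#' @param X Numeric matrix, donors x predictors (named columns recommended).
#' @param y Numeric outcome (log-transform skewed positive outcomes
#'   upstream).
#' @param config A [stability_config()].
#' @return List of class `stability_result`: `pi` (named selection
#'   probabilities), `stable_set` (names), `q_used`, `theta`, `pfer`,
#'   `subsamples` (list of index vectors), `selected_sets` (list of
#'   per-subsample selections).
#' @export
stability_selection <- function(X, y, config = stability_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("stability selection requires n >= 10")
  m <- floor(n * config$subsample_fraction)
  if (m <= 2) stop("subsample size <= 2; increase n or subsample_fraction")
  q <- if (is.null(config$q)) q_from_pfer(config$pfer, config$theta, p) else
    as.integer(min(config$q, p))

  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("V", seq_len(p))

  set.seed(config$seed)
  counts <- integer(p)
  subsamples <- vector("list", config$n_subsamples)
  selected_sets <- vector("list", config$n_subsamples)
  for (b in seq_len(config$n_subsamples)) {
    idx <- sample.int(n, m)
    sel <- suppressWarnings(lasso_first_q(X[idx, , drop = FALSE], y[idx], q))
    counts[sel] <- counts[sel] + 1L
    subsamples[[b]] <- idx
    selected_sets[[b]] <- cn[sel]
  }
  pi <- stats::setNames(counts / config$n_subsamples, cn)
  structure(list(pi = pi,
                 stable_set = cn[pi >= config$theta],
                 q_used = q, theta = config$theta, pfer = config$pfer,
                 n_subsamples = config$n_subsamples,
                 subsamples = subsamples, selected_sets = selected_sets),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("Stability selection: q =", x$q_used, ", theta =", x$theta,
      ", PFER budget =", x$pfer, "\n")
  top <- sort(x$pi, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top) == 0) {
    cat("no variable was ever selected\n")
  } else {
    for (nm in names(utils::head(top, 10)))
      cat(sprintf("  %-28s pi = %.2f%s\n", nm, top[nm],
                  if (top[nm] >= x$theta) "  [stable]" else ""))
  }
  invisible(x)
}

#' AIC model ladder m0 / m1 / m2
#'
#' Compares nested least-squares prediction models for one outcome:
#' m0 = intercept only, m1 = the top stable variable, m2 = the top four
#' variables by selection probability (or an explicit covariate list).
#' AIC = n * ln(RSS / n) + 2k with k counting coefficients including the
#' intercept (additive constants shared across models are dropped, so only
#' AIC differences are meaningful).
#'
#' @param table Data frame with outcome and covariate columns.
#' @param outcome Column name of the (already transformed) outcome.
#' @param ranking Character vector of covariate names ranked by selection
#'   probability (from [stability_selection()]); m1 uses `ranking[1]`, m2
#'   uses `ranking[1:4]` (or fewer if unavailable).
#' @param m2_covariates Optional explicit covariate set for m2.
#' @return Data frame with one row per model: model, covariates, k, rss, aic.
#' @export
aic_ladder <- function(table, outcome, ranking, m2_covariates = NULL) {
  stopifnot(outcome %in% names(table), length(ranking) >= 1)
  y <- table[[outcome]]
  ok <- is.finite(y)
  covs2 <- if (is.null(m2_covariates)) ranking[seq_len(min(4, length(ranking)))] else
    m2_covariates
  miss <- setdiff(c(ranking[1], covs2), names(table))
  if (length(miss) > 0) stop("covariates not in table: ", paste(miss, collapse = ", "))
  for (v in unique(c(ranking[1], covs2))) ok <- ok & is.finite(table[[v]])
  dat <- table[ok, , drop = FALSE]
  n <- nrow(dat)

  fit_one <- function(covs) {
    if (length(covs) == 0) {
      f <- stats::lm(dat[[outcome]] ~ 1)
    } else {
      fml <- stats::reformulate(sprintf("`%s`", covs), response = sprintf("`%s`", outcome))
      f <- stats::lm(fml, data = dat)
      if (f$rank < length(covs) + 1)
        warning("collinear covariates; rank-deficient fit (pivoted)")
    }
    rss <- sum(stats::residuals(f)^2)
    k <- f$rank
    data.frame(k = k, rss = rss, aic = n * log(rss / n) + 2 * k)
  }

  rows <- rbind(fit_one(character(0)), fit_one(ranking[1]), fit_one(covs2))
  cbind(data.frame(model = c("m0", "m1", "m2"),
                   covariates = c("(intercept)", ranking[1],
                                  paste(covs2, collapse = "+")),
                   n = n, stringsAsFactors = FALSE),
        rows)
}
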