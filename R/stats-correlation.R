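#' Spearman rank correlation with two-tailed p-value
#'
#' Rank correlation with midrank handling of ties. The two-tailed p-value is
#' computed by full permutation enumeration for n <= 9 and by the
#' t-approximation (t = r * sqrt((n-2)/(1-r^2)) on n-2 df) for larger n.
#'
#' @param x,y Numeric vectors of equal length (>= 4), finite values.
#' @return A list with elements `r_s` (Spearman coefficient), `p`
#'   (two-tailed), `n`, and `method` ("exact" or "t-approximation").
#' @examples
#' spearman_test(1:10, (1:10)^3)  # monotone => r_s = 1
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("spearman_test requires n >= 4")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")

  rx <- rank(x)
  ry <- rank(y)
  r_s <- stats::cor(rx, ry)

  if (n <= 9) {
    # exact: enumerate all n! orderings of y against fixed x ranks
    perms <- .permutations(n)
    rs_null <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rs_null) >= abs(r_s) - 1e-12)
    method <- "exact"
  } else {
    if (abs(r_s) >= 1) {
      p <- 0
    } else {
      tstat <- r_s * sqrt((n - 2) / (1 - r_s^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approximation"
  }
  list(r_s = r_s, p = min(p, 1), n = n, method = method)
}

# all permutations of 1..n as a matrix (n! rows); n <= 9 in practice
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' ROUT outlier detection on a scatter
#'
#' Identifies outliers from robust regression with a maximum false discovery
#' rate Q, using a straight-line baseline model:
#' (1) robust fit by iteratively reweighted least squares with Lorentzian
#' loss; (2) robust standard deviation of residuals (RSDR) as the 68.27th
#' percentile of absolute residuals scaled by n/(n-K), K = 2 fitted
#' parameters; (3) two-tailed t p-values of residual/RSDR on n-K df;
#' (4) a false-discovery-rate step from the most extreme residual inward:
#' with p-values ordered ascending (rank j = 1 is the largest absolute
#' residual), the flagged set is the largest j with p_(j) < Q * j / n
#' together with all points of larger residual — the Benjamini-Hochberg
#' schedule, under which a clean dataset loses any point with probability
#' of only about Q.
#'
#' @param x,y Numeric vectors (equal length). A warning is issued for n < 10.
#' @param Q Maximum false discovery rate, in percent (default 1).
#' @return Logical vector: TRUE for retained (inlier) points.
#' @export
rout_outliers <- function(x, y, Q = 1) {
  stopifnot(length(x) == length(y), Q >= 0)
  n <- length(x)
  K <- 2L
  if (n <= K) stop("rout_outliers requires n > 2")
  if (n < 10) warning("rout_outliers: n < 10, outlier detection is unreliable")
  if (Q == 0) return(rep(TRUE, n))

  fit <- .lorentzian_line_fit(x, y)
  res <- y - (fit$a + fit$b * x)
  rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE, type = 7) * n / (n - K)
  if (rsdr <= 0) return(rep(TRUE, n))

  tval <- abs(res) / rsdr
  pval <- 2 * stats::pt(-tval, df = n - K)

  ord <- order(abs(res), decreasing = TRUE)    # rank 1 = largest residual
  alpha <- (Q / 100) * seq_len(n) / n
  hits <- which(pval[ord] < alpha)
  keep <- rep(TRUE, n)
  if (length(hits) > 0) keep[ord[seq_len(max(hits))]] <- FALSE
  keep
}

# IRLS straight-line fit with Lorentzian (Cauchy) weights; scale re-estimated
# each iteration from the 68.27th percentile of |residuals|
.lorentzian_line_fit <- function(x, y, max_iter = 60, tol = 1e-10) {
  w <- rep(1, length(x))
  a <- b <- 0
  for (iter in seq_len(max_iter)) {
    sw <- sum(w); mx <- sum(w * x) / sw; my <- sum(w * y) / sw
    sxx <- sum(w * (x - mx)^2)
    b_new <- if (sxx > 0) sum(w * (x - mx) * (y - my)) / sxx else 0
    a_new <- my - b_new * mx
    if (abs(a_new - a) + abs(b_new - b) < tol * (1 + abs(a) + abs(b))) {
      a <- a_new; b <- b_new; break
    }
    a <- a_new; b <- b_new
    res <- y - (a + b * x)
    s <- stats::quantile(abs(res), 0.6827, names = FALSE)
    if (s <= 0) break
    w <- 1 / (1 + (res / s)^2)
  }
  list(a = a, b = b)
}

#' Correlation screen over donor-level feature/assay pairs
#'
#' For each requested (x, y) column pair: drop rows with missing values,
#' remove outliers with [rout_outliers()] at the given Q, then compute the
#' two-tailed Spearman correlation on retained points.
#'
#' @param table Data frame, one row per donor.
#' @param pairs Data frame with character columns `x` and `y` naming columns
#'   of `table`.
#' @param Q ROUT maximum false discovery rate in percent (default 1).
#' @param rout Logical; set FALSE to skip outlier removal.
#' @param fdr Logical; if TRUE a Benjamini-Hochberg adjusted-p column is
#'   appended across the screen (off by default: each pair is reported
#'   unadjusted, as in bivariate screening practice).
#' @return Data frame: pair names, `r_s`, `p`, `n_used`, `n_outliers`,
#'   `outlier_ids` (comma-separated row identifiers).
#' @export
correlate_screen <- function(table, pairs, Q = 1, rout = TRUE, fdr = FALSE) {
  stopifnot(is.data.frame(table), all(c("x", "y") %in% names(pairs)))
  miss <- setdiff(unique(c(pairs$x, pairs$y)), names(table))
  if (length(miss) > 0)
    stop("columns not found in table: ", paste(miss, collapse = ", "))
  ids <- if ("donor_id" %in% names(table)) table$donor_id else seq_len(nrow(table))

  res <- lapply(seq_len(nrow(pairs)), function(i) {
    xn <- pairs$x[i]; yn <- pairs$y[i]
    ok <- is.finite(table[[xn]]) & is.finite(table[[yn]])
    x <- table[[xn]][ok]; y <- table[[yn]][ok]; id <- ids[ok]
    keep <- if (rout) rout_outliers(x, y, Q = Q) else rep(TRUE, length(x))
    ct <- spearman_test(x[keep], y[keep])
    data.frame(
      x = xn, y = yn, r_s = ct$r_s, p = ct$p,
      n_used = sum(keep), n_outliers = sum(!keep),
      outlier_ids = paste(id[!keep], collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (fdr) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
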