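# shared fixtures and independent oracles

# solid disc / rotated ellipse masks on a square grid
disc_mask <- function(r, size = 2 * r + 11) {
  cx <- (size + 1) / 2
  d2 <- outer(seq_len(size) - cx, seq_len(size) - cx,
              function(y, x) x^2 + y^2)
  d2 <= r^2
}

ellipse_mask <- function(a, b, theta = 0, size = 2 * ceiling(a) + 11) {
  cx <- (size + 1) / 2
  xs <- outer(rep(1, size), seq_len(size) - cx)
  ys <- outer(seq_len(size) - cx, rep(1, size))
  u <- (xs * cos(theta) + ys * sin(theta)) / a
  v <- (-xs * sin(theta) + ys * cos(theta)) / b
  u^2 + v^2 <= 1
}

# ROC AUC by brute-force pair counting (ties count 1/2)
brute_auc <- function(score, label) {
  pos <- score[as.logical(label)]
  neg <- score[!as.logical(label)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# independent Lasso path oracle: cyclic coordinate descent on standardized
# columns over a dense log-spaced lambda grid; returns the first q distinct
# variables to become active
cd_lasso_first_q <- function(X, y, q, n_lambda = 400) {
  Xs <- scale(X)
  yc <- y - mean(y)
  n <- nrow(Xs); p <- ncol(Xs)
  lam_max <- max(abs(crossprod(Xs, yc)) / n)
  lams <- exp(seq(log(lam_max), log(lam_max * 1e-4), length.out = n_lambda))
  beta <- rep(0, p)
  entered <- integer(0)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (lam in lams) {
    for (it in 1:500) {
      b_old <- beta
      for (j in 1:p) {
        r_j <- yc - Xs %*% beta + Xs[, j] * beta[j]
        beta[j] <- soft(mean(Xs[, j] * r_j), lam)
      }
      if (max(abs(beta - b_old)) < 1e-9) break
    }
    new <- setdiff(which(abs(beta) > 1e-10), entered)
    if (length(new) > 0) entered <- c(entered, sort(new))
    if (length(entered) >= q) break
  }
  sort(entered[seq_len(min(q, length(entered)))])
}

# tiny donor row with exact trait values (no sampling)
fixed_donor <- function(mean_cell_area = 3000, cell_wl_ratio = 0.5,
                        mean_nucleus_area = 380, nucleus_wl_ratio = 0.75,
                        texture_intensity = 1) {
  data.frame(donor_id = "TEST",
             mean_cell_area = mean_cell_area, cell_wl_ratio = cell_wl_ratio,
             mean_nucleus_area = mean_nucleus_area,
             nucleus_wl_ratio = nucleus_wl_ratio,
             texture_intensity = texture_intensity,
             mean_cell_roundness = 0.4, mean_nucleus_roundness = 0.8,
             stringsAsFactors = FALSE)
}

# match ground-truth object ids to segmentation ids by majority overlap
match_truth_ids <- function(truth_map, seg_map, truth_ids) {
  vapply(truth_ids, function(id) {
    seg <- seg_map[truth_map == id]
    seg <- seg[seg > 0]
    if (length(seg) == 0) NA_integer_ else
      as.integer(names(which.max(table(seg))))
  }, integer(1))
}
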