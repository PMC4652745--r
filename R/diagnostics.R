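# Quality-control summaries (RLE, MDS, p-value histograms) and ranking
# evaluation (ROC/AUC, cumulative true positives). All functions return
# plain data structures; plotting helpers render them but are never
# required by the analysis.

#' Relative log expression (RLE) summary
#'
#' For each feature, deviations from its across-sample median M-value are
#' computed; the five-number summary of each sample's deviations is
#' returned. Arrays whose boxes sit away from zero or are unusually wide
#' flag batch or quality problems.
#'
#' @param Y Methylation matrix (samples x features), at least 2 samples.
#' @return Data frame with columns `sample_id`, `min`, `q1`, `median`,
#'   `q3`, `max`.
#' @export
rle_summary <- function(Y) {
  check_meth(Y)
  if (nrow(Y) < 2L) fail("need at least 2 samples")
  med <- apply(Y, 2, stats::median)
  D <- sweep(Y, 2, med)
  qs <- t(apply(D, 1, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
  out <- data.frame(sample_id = rownames(Y),
                    min = qs[, 1], q1 = qs[, 2], median = qs[, 3],
                    q3 = qs[, 4], max = qs[, 5],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("rle_summary", "data.frame")
  out
}

#' Classical MDS of samples on the most variable features
#'
#' Selects the `top_n` features with the largest across-sample standard
#' deviation (ties broken by column order), computes sample-sample
#' Euclidean distances on that submatrix, and applies classical
#' (Torgerson) scaling: double-center the squared distances,
#' eigendecompose, and scale eigenvectors by the square roots of the
#' nonnegative eigenvalues. Dimension 1 captures the largest source of
#' variation between samples, dimension 2 the next largest orthogonal
#' source, and so on — the plot is read like a PCA of samples.
#'
#' @param Y Methylation matrix, at least 3 samples.
#' @param top_n Number of most-variable features to use (default 1000,
#'   capped at the number available).
#' @return List with `coords` (samples x dimensions, columns centered),
#'   `eig_share` (nonincreasing shares of the positive eigenvalues) and
#'   `features` (the selected feature ids).
#' @export
mds_coordinates <- function(Y, top_n = 1000L) {
  check_meth(Y)
  n <- nrow(Y)
  if (n < 3L) fail("need at least 3 samples")
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 2L) fail("`top_n` must be at least 2")
  top_n <- min(top_n, ncol(Y))
  sds <- apply(Y, 2, stats::sd)
  sel <- order(-sds, seq_along(sds))[seq_len(top_n)]
  sub <- Y[, sel, drop = FALSE]
  d <- stats::dist(sub)
  if (max(d) == 0) {
    warning("all samples identical on the selected features; zero coordinates",
            call. = FALSE)
    coords <- matrix(0, n, 1L, dimnames = list(rownames(Y), "dim1"))
    return(list(coords = coords, eig_share = 1, features = colnames(sub)))
  }
  # k = n-1 may exceed the embedding rank; the eigenvalue filter below
  # handles that, so cmdscale's count warning is redundant
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  ev <- mds$eig
  keep <- which(ev > max(ev) * 1e-8)
  coords <- mds$points[, keep, drop = FALSE]
  colnames(coords) <- paste0("dim", seq_along(keep))
  rownames(coords) <- rownames(Y)
  pos <- ev[ev > 0]
  list(coords = coords,
       eig_share = ev[keep] / sum(pos),
       features = colnames(sub))
}

#' Histogram counts of p-values
#'
#' Equal-width bins on \[0, 1\]; the last bin is right-closed so every
#' p-value is counted exactly once. Under the global null the counts are
#' near-uniform; genuine signal appears as a spike in the first bin(s).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param bins Number of bins (default 20).
#' @return Data frame with columns `lower`, `upper`, `count`.
#' @export
pvalue_histogram <- function(p, bins = 20L) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    fail("p-values must lie in [0, 1]")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L) fail("`bins` must be a positive integer")
  idx <- pmin(floor(p * bins) + 1L, bins)
  counts <- tabulate(idx, nbins = bins)
  br <- seq(0, 1, length.out = bins + 1L)
  data.frame(lower = br[-(bins + 1L)], upper = br[-1L], count = counts)
}

# ROC from a score vector (higher = more significant) and 0/1 labels.
# Tied scores are grouped: one vertex per distinct score.
roc_points <- function(score, label) {
  o <- order(score, decreasing = TRUE)
  score <- score[o]
  label <- label[o]
  grp <- cumsum(!duplicated(score))
  tp <- cumsum(label)
  fp <- cumsum(1 - label)
  last <- !duplicated(grp, fromLast = TRUE)
  npos <- sum(label)
  nneg <- sum(1 - label)
  data.frame(fpr = c(0, fp[last] / nneg), tpr = c(0, tp[last] / npos))
}

#' ROC curve and AUC against a truth set
#'
#' Features are scored by `-pvalue` (most significant first); features in
#' neither truth list are ignored. Tied scores produce a single ROC
#' vertex, so the trapezoidal AUC equals the tie-corrected Mann-Whitney
#' probability that a random true positive outranks a random true
#' negative.
#'
#' @param fit A `ruv_fit` (or any data frame with `feature_id` and
#'   `pvalue` columns).
#' @param truth A [truth_set()] whose ids lie in the fit's universe.
#' @return List with `points` (data frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(fit, truth) {
  if (!inherits(truth, "truth_set")) fail("`truth` must be a truth_set")
  if (!all(c("feature_id", "pvalue") %in% names(fit)))
    fail("`fit` must have feature_id and pvalue columns")
  missing <- setdiff(c(truth$positives, truth$negatives), fit$feature_id)
  if (length(missing) > 0L)
    fail("truth ids outside the fit universe: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  ids <- c(truth$positives, truth$negatives)
  label <- c(rep(1L, length(truth$positives)),
             rep(0L, length(truth$negatives)))
  score <- -fit$pvalue[match(ids, fit$feature_id)]
  pts <- roc_points(score, label)
  k <- nrow(pts)
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-k]) / 2)
  list(points = pts, auc = auc)
}

#' Cumulative true positives along the ranking
#'
#' Entry `k` counts the known positives among the `k` best-ranked
#' features — the curve used to compare how quickly competing analyses
#' surface true signal near the top of their lists.
#'
#' @param fit A `ruv_fit` (or data frame with `feature_id` and `rank`).
#' @param positives Character vector of true-positive feature ids.
#' @param top_k Depth of the ranking to scan (default 1000, at most the
#'   universe size).
#' @return Integer vector of length `top_k`.
#' @export
cumulative_tp_curve <- function(fit, positives, top_k = 1000L) {
  if (!all(c("feature_id", "rank") %in% names(fit)))
    fail("`fit` must have feature_id and rank columns")
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L || top_k > nrow(fit))
    fail("`top_k` must be between 1 and the number of features")
  ord <- fit$feature_id[order(fit$rank)]
  cumsum(ord[seq_len(top_k)] %in% positives)
}

#' Plot an RLE summary as per-sample boxes
#'
#' @param rle A [rle_summary()] result.
#' @param ... Passed to [graphics::bxp()].
#' @export
plot_rle <- function(rle, ...) {
  stats_mat <- t(as.matrix(rle[, c("min", "q1", "median", "q3", "max")]))
  bx <- list(stats = stats_mat, n = rep(1, nrow(rle)),
             conf = stats_mat[c(2, 4), , drop = FALSE],
             out = numeric(0), group = numeric(0), names = rle$sample_id)
  graphics::bxp(bx, ylab = "deviation from feature median (M)", las = 2, ...)
  graphics::abline(h = 0, lty = 2)
  invisible(bx)
}

#' Plot MDS coordinates
#'
#' @param mds A [mds_coordinates()] result.
#' @param dims Which two dimensions to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_mds <- function(mds, dims = c(1L, 2L), ...) {
  co <- mds$coords
  if (max(dims) > ncol(co)) fail("requested dimension not available")
  lab <- sprintf("dim %d (%.1f%%)", dims, 100 * mds$eig_share[dims])
  graphics::plot(co[, dims[1]], co[, dims[2]],
                 xlab = lab[1], ylab = lab[2], ...)
  graphics::text(co[, dims[1]], co[, dims[2]], rownames(co),
                 pos = 3, cex = 0.7)
  invisible(co[, dims])
}
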