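# RLE/MDS/p-value diagnostics and ranking evaluation.

test_that("RLE deviations behave under shifts and constants", {
  Y <- meth_matrix(matrix(3, 4, 5), paste0("s", 1:4), paste0("g", 1:5))
  out <- rle_summary(Y)
  expect_true(all(out[, c("min", "q1", "median", "q3", "max")] == 0))

  # 5 samples, one shifted by +1 on every feature: per-feature medians are
  # attained at unshifted samples, so the shifted sample reads (1,1,1,1,1)
  set.seed(40)
  Y2 <- matrix(rnorm(5 * 20), 5, 20)
  Y2[2, ] <- Y2[2, ] + 1
  # brute-force oracle on the toy
  med <- apply(Y2, 2, median)
  dev <- sweep(Y2, 2, med)
  out2 <- rle_summary(meth_matrix(Y2, paste0("s", 1:5), paste0("g", 1:20)))
  expect_equal(out2$median, apply(dev, 1, median))
  expect_equal(out2$max, apply(dev, 1, max))

  # one shifted sample among constant others has summary (1,1,1,1,1)
  Y3 <- matrix(0, 5, 10, dimnames = list(paste0("s", 1:5), paste0("g", 1:10)))
  Y3[3, ] <- 1
  out3 <- rle_summary(Y3)
  expect_equal(as.numeric(out3[3, -1]), rep(1, 5))
  expect_true(all(out3[-3, -1] == 0))

  # adding a constant leaves deviations unchanged
  out4 <- rle_summary(meth_matrix(Y2 + 7, paste0("s", 1:5), paste0("g", 1:20)))
  expect_equal(out4[, -1], out2[, -1])
})

test_that("MDS separates two point clusters at +-d/2 on dimension 1", {
  d <- 4
  Y <- rbind(matrix(0, 3, 8), matrix(d / sqrt(8), 3, 8))
  Y <- meth_matrix(Y, paste0("s", 1:6), paste0("g", 1:8))
  mds <- mds_coordinates(Y, top_n = 8)
  expect_equal(abs(mds$coords[, 1]), rep(d / 2, 6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(mds$coords[, 1]), 0, tolerance = 1e-8)
})

test_that("MDS reconstructs Euclidean distances and ignores feature order", {
  set.seed(41)
  Y <- meth_matrix(matrix(rnorm(5 * 30), 5, 30),
                   paste0("s", 1:5), paste0("g", 1:30))
  mds <- mds_coordinates(Y, top_n = 30)
  expect_true(all(diff(mds$eig_share) <= 1e-12))
  expect_equal(as.matrix(dist(mds$coords)), as.matrix(dist(Y)),
               tolerance = 1e-8, ignore_attr = TRUE)
  perm <- sample(30)
  mds2 <- mds_coordinates(meth_matrix(Y[, perm], rownames(Y),
                                      colnames(Y)[perm]), top_n = 30)
  for (j in seq_len(ncol(mds$coords)))
    expect_equal(abs(mds2$coords[, j]), abs(mds$coords[, j]),
                 tolerance = 1e-8)
})

test_that("MDS selects the top-variance features and handles degeneracy", {
  set.seed(42)
  Y <- matrix(rnorm(4 * 10, sd = 0.1), 4, 10)
  Y[, 3] <- Y[, 3] * 50
  Y <- meth_matrix(Y, paste0("s", 1:4), paste0("g", 1:10))
  mds <- mds_coordinates(Y, top_n = 2)
  expect_true("g3" %in% mds$features)
  flat <- meth_matrix(matrix(1, 4, 5), paste0("s", 1:4), paste0("g", 1:5))
  expect_warning(out <- mds_coordinates(flat, top_n = 5), "identical")
  expect_true(all(out$coords == 0))
})

test_that("p-value histogram bins are equal width with a right-closed last bin", {
  p <- (seq_len(100) - 0.5) / 100
  h <- pvalue_histogram(p, bins = 10)
  expect_equal(h$count, rep(10L, 10))
  h0 <- pvalue_histogram(rep(0, 7), bins = 20)
  expect_equal(h0$count[1], 7L)
  expect_equal(sum(pvalue_histogram(runif(57))$count), 57L)
  expect_equal(pvalue_histogram(1, bins = 4)$count[4], 1L)
})

test_that("ROC/AUC reach the perfect and reversed extremes", {
  fit <- data.frame(feature_id = paste0("g", 1:6),
                    pvalue = c(0.01, 0.02, 0.03, 0.5, 0.6, 0.7))
  truth <- truth_set(paste0("g", 1:3), paste0("g", 4:6))
  expect_equal(roc_auc(fit, truth)$auc, 1.0)
  truth_rev <- truth_set(paste0("g", 4:6), paste0("g", 1:3))
  expect_equal(roc_auc(fit, truth_rev)$auc, 0.0)
  pts <- roc_auc(fit, truth)$points
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
})

test_that("tied scores give the Mann-Whitney tie-corrected AUC", {
  fit <- data.frame(feature_id = paste0("g", 1:6),
                    pvalue = c(0.1, 0.2, 0.3, 0.2, 0.5, 0.6))
  truth <- truth_set(paste0("g", 1:3), paste0("g", 4:6))
  oracle <- mw_auc_oracle(-fit$pvalue[1:3], -fit$pvalue[4:6])
  expect_equal(roc_auc(fit, truth)$auc, oracle)

  set.seed(43)
  for (i in 1:20) {
    p <- sample(seq(0.05, 0.5, by = 0.05), 8, replace = TRUE)
    fit <- data.frame(feature_id = paste0("g", 1:8), pvalue = p)
    truth <- truth_set(paste0("g", 1:4), paste0("g", 5:8))
    expect_equal(roc_auc(fit, truth)$auc,
                 mw_auc_oracle(-p[1:4], -p[5:8]), tolerance = 1e-12)
  }
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(44)
  p <- runif(100)
  fit1 <- data.frame(feature_id = paste0("g", 1:100), pvalue = p)
  fit2 <- data.frame(feature_id = paste0("g", 1:100), pvalue = p^3)
  truth <- truth_set(paste0("g", 1:40), paste0("g", 41:100))
  expect_equal(roc_auc(fit1, truth)$auc, roc_auc(fit2, truth)$auc)
})

test_that("random scores on balanced truth give AUC near one half", {
  set.seed(45)
  p <- runif(2000)
  fit <- data.frame(feature_id = paste0("g", 1:2000), pvalue = p)
  truth <- truth_set(paste0("g", 1:1000), paste0("g", 1001:2000))
  auc <- roc_auc(fit, truth)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("cumulative true-positive curves count set intersections exactly", {
  fit <- data.frame(feature_id = paste0("g", 1:20), rank = 1:20)
  pos_top <- paste0("g", 1:5)
  expect_equal(cumulative_tp_curve(fit, pos_top, top_k = 10),
               pmin(1:10, 5))
  expect_equal(cumulative_tp_curve(fit, paste0("g", 15:20), top_k = 10),
               rep(0L, 10))
  # brute-force recount on a shuffled toy
  set.seed(46)
  fit2 <- data.frame(feature_id = paste0("g", 1:20), rank = sample(20))
  pos <- sample(fit2$feature_id, 7)
  curve <- cumulative_tp_curve(fit2, pos, top_k = 20)
  ord <- fit2$feature_id[order(fit2$rank)]
  oracle <- vapply(1:20, function(k) length(intersect(ord[1:k], pos)),
                   integer(1))
  expect_equal(curve, oracle)
  expect_true(all(diff(curve) >= 0))
  expect_lte(curve[20], 7)
})
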