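# Synthetic-data generator.

test_that("null generator output yields uniform two-group t-test p-values", {
  sim <- simulate_methylation(sim_params(n_samples = 40, n_cpg = 2000,
                                         n_inc = 50, p_true_positive = 0,
                                         effect_size = 0, k_unwanted = 0L,
                                         seed = 50))
  g <- sim$design$X[, 1]
  p <- apply(sim$Y_cpg, 2, function(y)
    t.test(y[g == 0], y[g == 1], var.equal = TRUE)$p.value)
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("with no unwanted variation, OLS recovers the true effects", {
  sim <- simulate_methylation(sim_params(n_samples = 40, n_cpg = 1000,
                                         n_inc = 50, p_true_positive = 0.2,
                                         effect_size = 2, k_unwanted = 0L,
                                         seed = 51))
  fit <- fit_baseline(sim$Y_cpg, sim$design, moderate = FALSE)
  pos <- sim$truth$true_positives
  idx <- match(pos, fit$feature_id)
  err <- fit$coef[idx] - sim$truth$beta[pos]
  # analytic per-feature OLS SE: sd_g * sqrt([ (M'M)^-1 ]_bb)
  M <- cbind(1, sim$design$X)
  u <- solve(crossprod(M))[2, 2]
  se_true <- sim$truth$noise_sd_cpg[pos] * sqrt(u)
  expect_lt(mean(abs(err)), 3 * mean(se_true))
})

test_that("generation is byte-identical under the same seed", {
  p <- sim_params(n_samples = 12, n_cpg = 60, n_inc = 20, seed = 52,
                  mislabel_fraction = 0.1, confounding_rho = 0.4)
  a <- simulate_methylation(p)
  b <- simulate_methylation(p)
  expect_identical(a$Y_cpg, b$Y_cpg)
  expect_identical(a$Y_inc, b$Y_inc)
  expect_identical(a$truth, b$truth)
  p2 <- p; p2$seed <- 53L
  expect_false(identical(simulate_methylation(p2)$Y_cpg, a$Y_cpg))
})

test_that("the first unwanted factor carries the requested correlation with X", {
  p <- sim_params(n_samples = 500, n_cpg = 10, n_inc = 10,
                  k_unwanted = 2L, confounding_rho = 0.6, seed = 54)
  sim <- simulate_methylation(p)
  expect_lt(abs(cor(sim$truth$W[, 1], sim$truth$true_labels) - 0.6), 0.05)
  expect_lt(abs(cor(sim$truth$W[, 2], sim$truth$true_labels)), 0.15)
})

test_that("control features carry no group signal when W is unconfounded", {
  inc_frac <- function(sim) {
    g <- sim$truth$true_labels
    p <- apply(sim$Y_inc, 2, function(y)
      t.test(y[g == 0], y[g == 1], var.equal = TRUE)$p.value)
    mean(p < 0.05)
  }
  # without a shared factor the features are independent: binomial band
  sim0 <- simulate_methylation(sim_params(n_samples = 60, n_cpg = 10,
                                          n_inc = 2000, k_unwanted = 0L,
                                          seed = 55))
  expect_lt(abs(inc_frac(sim0) - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # with a shared unconfounded factor all controls move with one W draw, so
  # per-dataset fractions are over-dispersed; averaged over datasets the
  # naive t-test is conservative and controls show no systematic group signal
  fr <- vapply(1:5, function(s) {
    inc_frac(simulate_methylation(
      sim_params(n_samples = 60, n_cpg = 10, n_inc = 2000,
                 k_unwanted = 1L, confounding_rho = 0, seed = 55 + s)))
  }, numeric(1))
  expect_lt(mean(fr), 0.06)
})

test_that("mislabeling flips exactly the requested fraction of labels", {
  sim <- simulate_methylation(sim_params(n_samples = 40, n_cpg = 20,
                                         n_inc = 10,
                                         mislabel_fraction = 0.1, seed = 56))
  obs <- sim$design$X[, 1]
  truevals <- as.numeric(sim$truth$true_labels)
  expect_equal(sum(obs != truevals), 4)
  expect_setequal(rownames(sim$Y_cpg)[obs != truevals],
                  sim$truth$flipped_samples)
})

test_that("presets encode the documented scenarios and pass validation", {
  expect_equal(sim_preset("clean")$k_unwanted, 0L)
  expect_equal(sim_preset("clean")$p_true_positive, 0)
  expect_equal(sim_preset("high_dm")$p_true_positive, 0.4)
  expect_equal(sim_preset("confounded_mislabel")$confounding_rho, 0.6)
  expect_equal(sim_preset("confounded_mislabel")$mislabel_fraction, 0.05)
  for (nm in c("clean", "batch_dominated", "confounded_mislabel", "high_dm"))
    expect_s3_class(sim_preset(nm), "sim_params")
  expect_error(sim_preset("nope"))
  expect_error(sim_params(confounding_rho = 1), "rho")
  # INC block never carries a true effect
  sim <- simulate_methylation(sim_params(n_samples = 10, n_cpg = 20,
                                         n_inc = 10, seed = 57))
  expect_false(any(colnames(sim$Y_inc) %in% sim$truth$true_positives))
})
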