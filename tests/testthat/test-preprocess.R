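# M-value computation and filtering rules.

test_that("M-values follow the log2 channel ratio", {
  meth <- matrix(c(100, 200, 300, 400), 2, 2,
                 dimnames = list(c("s1", "s2"), c("g1", "g2")))
  unmeth <- matrix(c(100, 100, 300, 100), 2, 2,
                   dimnames = dimnames(meth))
  M <- m_from_intensities(meth, unmeth, offset = 0)
  expect_equal(M[1, 1], 0)           # equal channels
  expect_equal(M[2, 1], 1)           # 200/100
  expect_equal(M[2, 2], 2)           # 400/100
  # swapping channels negates M
  expect_equal(m_from_intensities(unmeth, meth, offset = 0), -M)
  zero <- meth; zero[1, 1] <- 0
  expect_error(m_from_intensities(zero, unmeth, offset = 0), "offset")
  expect_silent(m_from_intensities(zero, unmeth, offset = 100))
})

test_that("beta_to_m is the logit2 transform and agrees with the intensity route", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  b <- seq(0.05, 0.95, by = 0.05)
  expect_equal(beta_to_m(b), -beta_to_m(1 - b))
  expect_error(beta_to_m(c(0.2, 1)), "strictly in")

  set.seed(30)
  meth <- matrix(runif(20, 10, 1000), 4, 5,
                 dimnames = list(paste0("s", 1:4), paste0("g", 1:5)))
  unmeth <- matrix(runif(20, 10, 1000), 4, 5, dimnames = dimnames(meth))
  M1 <- m_from_intensities(meth, unmeth, offset = 0)
  M2 <- beta_to_m(meth / (meth + unmeth))
  expect_lt(max(abs(M1 - M2)), 1e-12)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
})

test_that("sample filtering drops high mean-detection-p arrays", {
  detp <- matrix(c(0.001, 0.02, 0.005), 3, 4,
                 dimnames = list(c("s1", "s2", "s3"), paste0("g", 1:4)))
  out <- filter_samples(detp)
  expect_equal(out$dropped, "s2")
  expect_setequal(out$retained, c("s1", "s3"))
  # all clean -> identity
  ok <- matrix(0.001, 3, 4, dimnames = dimnames(detp))
  expect_length(filter_samples(ok)$dropped, 0)
  expect_error(filter_samples(detp, threshold = 0), "strictly in")
  bad <- matrix(0.02, 3, 4, dimnames = dimnames(detp))
  expect_error(filter_samples(bad), "all samples")
})

test_that("probe filtering applies the four rules with per-rule tallies", {
  ids <- paste0("g", 1:6)
  detp <- matrix(0.001, 2, 6, dimnames = list(c("s1", "s2"), ids))
  detp["s2", "g1"] <- 0.02
  ann <- probe_annotation(ids,
                          chromosome = c("1", "chrX", "2", "3", "4", "5"),
                          has_snp_at_cpg_or_sbe = c(F, F, T, F, F, F),
                          is_cross_reactive = c(F, F, F, T, F, F))
  out <- filter_probes(detp, ann)
  expect_setequal(out$retained, c("g5", "g6"))
  expect_equal(out$counts[["total_removed"]], 4)
  expect_equal(out$counts[["detection"]], 1)
  expect_equal(out$counts[["sex_chromosome"]], 1)
  expect_equal(out$counts[["snp"]], 1)
  expect_equal(out$counts[["cross_reactive"]], 1)

  # all clean -> identity
  clean <- matrix(0.001, 2, 6, dimnames = dimnames(detp))
  ann_ok <- probe_annotation(ids, chromosome = rep("1", 6))
  expect_identical(filter_probes(clean, ann_ok)$retained, ids)
})

test_that("a probe failing several rules is removed once, tallied per rule", {
  ids <- c("g1", "g2")
  detp <- matrix(c(0.5, 0.001, 0.001, 0.001), 2, 2,
                 dimnames = list(c("s1", "s2"), ids))
  ann <- probe_annotation(ids, chromosome = c("chrY", "1"),
                          has_snp_at_cpg_or_sbe = c(TRUE, FALSE))
  out <- filter_probes(detp, ann)
  expect_equal(out$counts[["total_removed"]], 1)
  expect_equal(out$counts[["detection"]], 1)
  expect_equal(out$counts[["sex_chromosome"]], 1)
  expect_equal(out$counts[["snp"]], 1)
  expect_identical(out$retained, "g2")
})

test_that("negative controls bypass annotation rules but obey the detection rule", {
  ids <- c("neg1", "neg2", "g1")
  detp <- matrix(c(0.5, 0.001, 0.001, 0.001, 0.001, 0.001), 2, 3,
                 dimnames = list(c("s1", "s2"), ids))
  ann <- probe_annotation(ids, chromosome = c("X", "Y", "1"),
                          is_negative_control = c(TRUE, TRUE, FALSE))
  out <- filter_probes(detp, ann)
  expect_setequal(out$retained, c("neg2", "g1"))
  expect_equal(out$counts[["sex_chromosome"]], 0)
  # missing annotation for a tested (non-control) probe names it
  expect_error(filter_probes(detp, ann[-3, ], feature_ids = ids), "g1")
})

test_that("chromosome-name dialects are recognized case-insensitively", {
  ids <- paste0("g", 1:5)
  ann <- probe_annotation(ids, chromosome = c("X", "chrX", "y", "CHRY", "1"))
  out <- filter_probes(NULL, ann, feature_ids = ids)
  expect_identical(out$retained, "g5")
})

test_that("filtering masks commute: filter samples then probes == intersect masks", {
  set.seed(31)
  n <- 6; m <- 30
  detp <- matrix(runif(n * m, 0, 0.02), n, m,
                 dimnames = list(paste0("s", 1:n), paste0("g", 1:m)))
  ann <- probe_annotation(paste0("g", 1:m), chromosome = rep("1", m),
                          has_snp_at_cpg_or_sbe = runif(m) < 0.1)
  sf <- filter_samples(detp)
  seq_out <- filter_probes(detp[sf$retained, , drop = FALSE], ann)
  # computing both masks on originals with the sample restriction applied
  keep_s <- rowMeans(detp) <= 0.01
  joint <- filter_probes(detp[keep_s, , drop = FALSE], ann)
  expect_identical(seq_out$retained, joint$retained)
})
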