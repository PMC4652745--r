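# The two-stage RUVm pipeline.
#
# Stage 1 ranks all CpGs by fitting RUV-inverse with the platform
# negative controls (on 450k arrays, the 613 Illumina negative controls),
# which carry technical but no biological variation. Stage 2 designates
# the least associated CpGs from that ranking as empirical control probes
# (ECPs) and refits RUV-inverse with the covariance estimated from them;
# ECPs stay in the tested universe and receive statistics like any other
# feature. Stage 2 may be iterated to refine the ECP set.

#' Rule for selecting empirical control probes
#'
#' @param method `"fdr_cutoff"` keeps features with FDR-adjusted p-value
#'   above `threshold`; `"bottom_fraction"` keeps the `threshold` fraction
#'   of features with the largest p-values (worst ranked). In the absence
#'   of other information an FDR cut-off around 0.5 or the bottom 50% of
#'   the ranked list is a sensible default; studies expecting widespread
#'   differential methylation (e.g. cancer vs normal, where ~40% of probes
#'   can be associated) should use an FDR cut-off or a smaller fraction.
#' @param threshold Number in (0, 1).
#' @return An object of class `"ecp_rule"`.
#' @export
ecp_rule <- function(method = c("bottom_fraction", "fdr_cutoff"),
                     threshold = 0.5) {
  method <- match.arg(method)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1)
    fail("`threshold` must be a number strictly between 0 and 1")
  structure(list(method = method, threshold = threshold), class = "ecp_rule")
}

# Degrees of freedom of the expanded mean model.
design_df <- function(design, n) {
  n - qr(design$Z)$rank - qr(design$X)$rank
}

# Shared fitting engine for both stages: GLS coefficients, inverse-method
# SEs, t/p/fdr/ranks for the selected coefficient of interest.
ruv_inverse_fit <- function(Y, design, ctx, B, seed, coef = 1L,
                            method = "ruv_inverse") {
  p <- ncol(design$X)
  if (coef < 1L || coef > p)
    fail("`coef` must index a column of design$X")
  beta <- gls_fit(Y, design, ctx)
  sefit <- inverse_method_se(Y, design, ctx, B = B, seed = seed)
  df <- design_df(design, nrow(Y))
  if (df <= 0) fail("nonpositive residual degrees of freedom")
  tp <- t_and_p(beta[coef, ], sefit$se[coef, ], df)
  fit <- new_ruv_fit(colnames(Y), beta[coef, ], sefit$se[coef, ],
                     tp$t, tp$p, df = df, B = B, seed = seed,
                     method = method, n_controls = ctx$n_controls_used)
  attr(fit, "kappa") <- sefit$kappa[coef]
  fit
}

#' Stage 1: RUV-inverse fit using platform negative controls
#'
#' Estimates the control covariance from a separate matrix of platform
#' negative-control features (which share samples with the CpG matrix but
#' are disjoint from it) and fits every CpG by GLS with inverse-method
#' standard errors, ranking CpGs by p-value.
#'
#' @param Y_cpg Methylation matrix (samples x features) of CpGs to test.
#' @param Y_inc Methylation matrix of platform negative-control features,
#'   same samples in the same order.
#' @param design A [design_spec()].
#' @param B Random-column replicates for the inverse-method SEs.
#' @param seed Integer seed.
#' @param coef Which column of `design$X` to report (default the first).
#' @param ridge_lambda Optional explicit covariance ridge
#'   (see [control_covariance()]).
#' @return A `ruv_fit` data frame with columns `feature_id`, `coef`, `se`,
#'   `t`, `pvalue`, `fdr`, `rank`.
#' @export
stage1_fit <- function(Y_cpg, Y_inc, design, B = 50L, seed = 1L,
                       coef = 1L, ridge_lambda = NULL) {
  check_meth(Y_cpg, "Y_cpg")
  check_meth(Y_inc, "Y_inc")
  if (!identical(rownames(Y_cpg), rownames(Y_inc)))
    fail("Y_cpg and Y_inc must share the same samples in the same order")
  shared <- intersect(colnames(Y_cpg), colnames(Y_inc))
  if (length(shared) > 0L)
    fail("negative-control features must be disjoint from tested CpGs: ",
         paste(utils::head(shared, 5L), collapse = ", "))
  ctx <- control_covariance(Y_inc, design,
                            control_set(colnames(Y_inc), "platform_negative"),
                            ridge_lambda = ridge_lambda)
  ruv_inverse_fit(Y_cpg, design, ctx, B = B, seed = seed, coef = coef,
                  method = "ruvm_stage1")
}

#' Select empirical control probes from a ranked fit
#'
#' @param fit A `ruv_fit`, typically the Stage-1 result.
#' @param rule An [ecp_rule()].
#' @return A [control_set()] with origin `"empirical"`.
#' @export
select_ecps <- function(fit, rule = ecp_rule()) {
  if (!inherits(fit, "ruv_fit")) fail("`fit` must be a ruv_fit")
  if (!inherits(rule, "ecp_rule")) fail("`rule` must be an ecp_rule")
  m <- nrow(fit)
  if (m == 0L) fail("empty fit")
  ids <- switch(rule$method,
    fdr_cutoff = fit$feature_id[fit$fdr > rule$threshold],
    bottom_fraction = {
      k <- floor(rule$threshold * m)
      if (k >= 1L) fit$feature_id[fit$rank > m - k] else character(0)
    })
  if (length(ids) == 0L)
    fail("ECP selection is empty; lower the cut-off. Datasets with a high ",
         "proportion of truly associated probes (e.g. cancer vs normal, ",
         "where ~40% of probes can be significant) shrink the admissible pool.")
  log_info("selected ", length(ids), "/", m, " ECPs (",
           format(100 * length(ids) / m, digits = 3), "%) by ",
           rule$method, " ", rule$threshold)
  control_set(ids, origin = "empirical")
}

#' Stage 2: RUV-inverse fit using empirical control probes
#'
#' The control covariance is estimated from the ECP columns of the CpG
#' matrix itself; all CpGs (including the ECPs) are then refit and ranked.
#'
#' @inheritParams stage1_fit
#' @param ecps A [control_set()] (or character vector) of ECP feature ids,
#'   a subset of `colnames(Y_cpg)` of size at least 2.
#' @return A `ruv_fit` data frame.
#' @export
stage2_fit <- function(Y_cpg, design, ecps, B = 50L, seed = 1L,
                       coef = 1L, ridge_lambda = NULL) {
  check_meth(Y_cpg, "Y_cpg")
  ids <- control_ids(ecps)
  if (length(ids) < 2L) fail("need at least 2 ECPs")
  ctx <- control_covariance(Y_cpg, design, ids, ridge_lambda = ridge_lambda)
  ruv_inverse_fit(Y_cpg, design, ctx, B = B, seed = seed, coef = coef,
                  method = "ruvm_stage2")
}

#' The full two-stage RUVm analysis
#'
#' Runs Stage 1 on the platform negative controls, selects ECPs from its
#' ranking, and refits with Stage 2; the select/refit round can be
#' iterated, each round re-selecting ECPs from the latest fit. Per-stage
#' seeds are derived from the master seed as `seed + stage index`, so a
#' single seed makes the whole analysis reproducible. If `Y_inc` is
#' `NULL`, a user-supplied `initial_controls` set (drawn from the CpG
#' universe, e.g. invariant CpGs from previous experiments) starts the
#' pipeline instead of the platform controls.
#'
#' @inheritParams stage1_fit
#' @param Y_inc Platform negative-control matrix, or `NULL` to start from
#'   `initial_controls`.
#' @param rule An [ecp_rule()]; default bottom 50% of the ranked list.
#' @param iterations Number of select-ECPs/refit rounds (>= 1; once is
#'   usually enough).
#' @param initial_controls Optional [control_set()] used when `Y_inc` is
#'   absent.
#' @return An object of class `"ruvm_result"`: list with `stage1` (fit),
#'   `ecps` (list of [control_set()]s, one per iteration), `stage2`
#'   (final fit) and `n_stage2_iterations`.
#' @examples
#' sim <- simulate_methylation(sim_params(n_samples = 20, n_cpg = 200,
#'                                        n_inc = 100, seed = 3))
#' res <- ruvm(sim$Y_cpg, sim$Y_inc, sim$design, B = 20, seed = 3)
#' head(res$stage2[order(res$stage2$rank), ])
#' @export
ruvm <- function(Y_cpg, Y_inc, design, rule = ecp_rule(),
                 iterations = 1L, B = 50L, seed = 1L, coef = 1L,
                 ridge_lambda = NULL, initial_controls = NULL) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L)
    fail("`iterations` must be an integer >= 1")
  if (is.null(Y_inc)) {
    if (is.null(initial_controls))
      fail("either Y_inc or initial_controls must be supplied")
    log_info("stage 1: user-supplied control set (",
             length(control_ids(initial_controls)), " features)")
    stage1 <- stage2_fit(Y_cpg, design, initial_controls, B = B,
                         seed = seed + 1L, coef = coef,
                         ridge_lambda = ridge_lambda)
    attr(stage1, "method") <- "ruvm_stage1_user_controls"
  } else {
    log_info("stage 1: platform negative controls")
    stage1 <- stage1_fit(Y_cpg, Y_inc, design, B = B, seed = seed + 1L,
                         coef = coef, ridge_lambda = ridge_lambda)
  }
  ecps <- vector("list", iterations)
  fit <- stage1
  for (i in seq_len(iterations)) {
    ecps[[i]] <- select_ecps(fit, rule)
    log_info("stage 2, iteration ", i)
    fit <- stage2_fit(Y_cpg, design, ecps[[i]], B = B,
                      seed = seed + 1L + i, coef = coef,
                      ridge_lambda = ridge_lambda)
  }
  structure(list(stage1 = stage1, ecps = ecps, stage2 = fit,
                 n_stage2_iterations = iterations,
                 rule = rule, B = as.integer(B), seed = as.integer(seed)),
            class = "ruvm_result")
}

#' @export
print.ruvm_result <- function(x, ...) {
  cat("ruvm_result:", nrow(x$stage2), "features,",
      x$n_stage2_iterations, "stage-2 iteration(s),",
      length(x$ecps[[x$n_stage2_iterations]]$feature_ids), "final ECPs\n")
  cat("top of final ranking:\n")
  print(utils::head(as.data.frame(x$stage2)[order(x$stage2$rank), ], 5L))
  invisible(x)
}

#' Unadjusted moderated-t baseline
#'
#' Per-feature ordinary least squares of the M-values on `[Z X]` followed
#' by empirical Bayes variance moderation — the standard regression
#' analysis that makes no attempt to remove unwanted variation. Used as
#' the comparator the two-stage procedure is measured against.
#'
#' @inheritParams stage1_fit
#' @param Y Methylation matrix (samples x features).
#' @param moderate If `FALSE`, skip variance moderation.
#' @return A `ruv_fit` data frame.
#' @export
fit_baseline <- function(Y, design, coef = 1L, moderate = TRUE) {
  check_meth(Y)
  check_design(design)
  n <- nrow(Y)
  if (nrow(design$X) != n) fail("design and Y disagree on samples")
  M <- cbind(design$Z, design$X)
  qm <- qr(M)
  cf <- qr.coef(qm, Y)
  res <- qr.resid(qm, Y)
  df <- n - qm$rank
  if (df <= 0) fail("nonpositive residual degrees of freedom")
  s2 <- colSums(res^2) / df
  MtMinv <- chol2inv(qr.R(qm))
  j <- ncol(design$Z) + coef
  unscaled <- MtMinv[j, j]
  beta <- cf[j, ]
  se <- sqrt(s2 * unscaled)
  if (moderate) {
    mod <- moderate_variances(se, df, beta)
    new_ruv_fit(colnames(Y), beta, mod$se, mod$t, mod$p, df = mod$df,
                method = "baseline_moderated")
  } else {
    tp <- t_and_p(beta, se, df)
    new_ruv_fit(colnames(Y), beta, se, tp$t, tp$p, df = df,
                method = "baseline_ols")
  }
}
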