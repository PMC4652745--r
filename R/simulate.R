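# Seeded generator of 450k-like datasets with known ground truth.
#
# The generator draws from the working model Y = Z gamma + X beta +
# W alpha + eps on the M-value scale: a balanced two-group factor of
# interest with a sparse effect, k unwanted factors loading on both the
# CpG features and a separate block of platform-negative-control-like
# features (which carry no beta by construction), per-feature lognormal
# noise scales, optional correlation between the first unwanted factor
# and the group, and optional label flipping to emulate misreported
# phenotypes or sample mix-ups.

#' Simulation parameters
#'
#' @param n_samples Number of samples (balanced two-group design).
#' @param n_cpg Number of CpG features.
#' @param n_inc Number of negative-control features (>= 2); the 450k array
#'   carries 613.
#' @param p_true_positive Fraction of CpGs with a nonzero group effect.
#' @param effect_size Magnitude of the group effect, in M-value units.
#'   For orientation: a large ageing-type effect (~25% methylation
#'   difference) is about 1.5 on the M scale, a subtle smoking-type
#'   effect (~5%) about 0.3.
#' @param k_unwanted Number of unwanted factors W (>= 0).
#' @param alpha_scale_cpg,alpha_scale_inc Standard deviations of the W
#'   loadings on CpG and control features.
#' @param confounding_rho Correlation between the first unwanted factor
#'   and the (standardized) group indicator, in (-1, 1).
#' @param mislabel_fraction Fraction of samples whose group label is
#'   flipped after the data are generated.
#' @param noise_meanlog,noise_sdlog Parameters of the lognormal
#'   distribution of per-feature noise standard deviations. The defaults
#'   (median 0.3, spread 0.3 on the log scale) match typical residual
#'   M-value variability on 450k arrays.
#' @param baseline_sd Standard deviation of per-CpG baseline M-values.
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(n_samples = 40L, n_cpg = 2000L, n_inc = 613L,
                       p_true_positive = 0.05, effect_size = 1,
                       k_unwanted = 1L, alpha_scale_cpg = 1,
                       alpha_scale_inc = 1, confounding_rho = 0,
                       mislabel_fraction = 0,
                       noise_meanlog = log(0.3), noise_sdlog = 0.3,
                       baseline_sd = 2, seed = 1L) {
  p <- list(n_samples = as.integer(n_samples), n_cpg = as.integer(n_cpg),
            n_inc = as.integer(n_inc),
            p_true_positive = p_true_positive, effect_size = effect_size,
            k_unwanted = as.integer(k_unwanted),
            alpha_scale_cpg = alpha_scale_cpg,
            alpha_scale_inc = alpha_scale_inc,
            confounding_rho = confounding_rho,
            mislabel_fraction = mislabel_fraction,
            noise_meanlog = noise_meanlog, noise_sdlog = noise_sdlog,
            baseline_sd = baseline_sd, seed = as.integer(seed))
  if (p$n_samples < 4L) fail("need at least 4 samples")
  if (p$n_cpg < 2L || p$n_inc < 2L)
    fail("need at least 2 CpG and 2 control features")
  if (p$p_true_positive < 0 || p$p_true_positive > 1 ||
      p$mislabel_fraction < 0 || p$mislabel_fraction > 1)
    fail("fractions must lie in [0, 1]")
  if (abs(p$confounding_rho) >= 1)
    fail("|confounding_rho| must be strictly below 1")
  if (p$k_unwanted < 0 || p$alpha_scale_cpg < 0 || p$alpha_scale_inc < 0 ||
      p$effect_size < 0 || p$baseline_sd < 0)
    fail("scales must be nonnegative")
  structure(p, class = "sim_params")
}

#' Named simulation presets
#'
#' Parameter bundles echoing the archetypal study designs:
#' * `clean` — no unwanted variation and no true effects; a pure null.
#' * `batch_dominated` — an ageing-type merge of studies: a large effect
#'   (1.5 M units) but an even larger batch factor (loading sd 3) mildly
#'   correlated with the groups.
#' * `confounded_mislabel` — a smoking-type scenario: a small effect
#'   (0.3 M units, ~5% methylation), a batch factor correlated 0.6 with
#'   the groups, and 5% of labels flipped.
#' * `high_dm` — a cancer-type comparison where 40% of CpGs carry a large
#'   effect, which shrinks the pool of admissible empirical control probes.
#'
#' @param name Preset name.
#' @return A [sim_params()] object with a fixed default seed.
#' @export
sim_preset <- function(name = c("clean", "batch_dominated",
                                "confounded_mislabel", "high_dm")) {
  name <- match.arg(name)
  switch(name,
    clean = sim_params(n_samples = 40L, n_cpg = 2000L, n_inc = 613L,
                       p_true_positive = 0, effect_size = 0,
                       k_unwanted = 0L, alpha_scale_cpg = 0,
                       alpha_scale_inc = 0, confounding_rho = 0,
                       mislabel_fraction = 0, seed = 1L),
    batch_dominated = sim_params(n_samples = 60L, n_cpg = 2000L,
                                 n_inc = 613L, p_true_positive = 0.05,
                                 effect_size = 1.5, k_unwanted = 1L,
                                 alpha_scale_cpg = 3, alpha_scale_inc = 3,
                                 confounding_rho = 0.3,
                                 mislabel_fraction = 0, seed = 1L),
    confounded_mislabel = sim_params(n_samples = 60L, n_cpg = 2000L,
                                     n_inc = 613L, p_true_positive = 0.05,
                                     effect_size = 0.3, k_unwanted = 1L,
                                     alpha_scale_cpg = 1, alpha_scale_inc = 1,
                                     confounding_rho = 0.6,
                                     mislabel_fraction = 0.05, seed = 1L),
    high_dm = sim_params(n_samples = 40L, n_cpg = 2000L, n_inc = 613L,
                         p_true_positive = 0.4, effect_size = 2,
                         k_unwanted = 1L, alpha_scale_cpg = 1,
                         alpha_scale_inc = 1, confounding_rho = 0.2,
                         mislabel_fraction = 0, seed = 1L))
}

pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), seq_len(n))
}

#' Simulate a 450k-like dataset with known truth
#'
#' @param params A [sim_params()] (or [sim_preset()]) object.
#' @return An object of class `"sim_dataset"`: list with `Y_cpg`, `Y_inc`
#'   (methylation matrices), `design` (a [design_spec()] built from the
#'   possibly mislabeled groups), `truth` (true `beta` per CpG, the
#'   `true_positives` id set, `W`, the loadings, per-feature noise sds,
#'   `true_labels` and the ids of `flipped_samples`) and `params`.
#' @examples
#' sim <- simulate_methylation(sim_params(n_samples = 12, n_cpg = 50,
#'                                        n_inc = 20, seed = 42))
#' dim(sim$Y_cpg)
#' @export
simulate_methylation <- function(params) {
  if (!inherits(params, "sim_params"))
    fail("`params` must come from sim_params() or sim_preset()")
  p <- params
  n <- p$n_samples
  m <- p$n_cpg
  k <- p$k_unwanted

  sample_ids <- pad_ids("sample_", n)
  cpg_ids <- pad_ids("cg", m)
  inc_ids <- pad_ids("neg", p$n_inc)

  out <- with_seed(p$seed, {
    # balanced groups: first half 0, second half 1
    group_true <- c(rep(0L, floor(n / 2)), rep(1L, n - floor(n / 2)))
    x_std <- as.numeric(scale(group_true))

    W <- matrix(0, n, k)
    if (k >= 1L) {
      rho <- p$confounding_rho
      W[, 1L] <- rho * x_std + sqrt(1 - rho^2) * stats::rnorm(n)
      if (k >= 2L)
        W[, 2:k] <- stats::rnorm(n * (k - 1L))
    }

    beta <- numeric(m)
    n_pos <- round(p$p_true_positive * m)
    pos_idx <- if (n_pos > 0L) sort(sample.int(m, n_pos)) else integer(0)
    if (n_pos > 0L)
      beta[pos_idx] <- p$effect_size * sample(c(-1, 1), n_pos, replace = TRUE)

    gamma_cpg <- stats::rnorm(m, 0, p$baseline_sd)
    alpha_cpg <- matrix(stats::rnorm(k * m, 0, p$alpha_scale_cpg), k, m)
    sd_cpg <- stats::rlnorm(m, p$noise_meanlog, p$noise_sdlog)
    E_cpg <- matrix(stats::rnorm(n * m), n, m) %*% diag(sd_cpg, m)
    Y_cpg <- matrix(gamma_cpg, n, m, byrow = TRUE) +
      outer(as.numeric(group_true), beta) + W %*% alpha_cpg + E_cpg

    gamma_inc <- stats::rnorm(p$n_inc, 0, 0.1)
    alpha_inc <- matrix(stats::rnorm(k * p$n_inc, 0, p$alpha_scale_inc),
                        k, p$n_inc)
    sd_inc <- stats::rlnorm(p$n_inc, p$noise_meanlog, p$noise_sdlog)
    E_inc <- matrix(stats::rnorm(n * p$n_inc), n, p$n_inc) %*%
      diag(sd_inc, p$n_inc)
    Y_inc <- matrix(gamma_inc, n, p$n_inc, byrow = TRUE) +
      W %*% alpha_inc + E_inc

    group_obs <- group_true
    n_flip <- round(p$mislabel_fraction * n)
    flip_idx <- if (n_flip > 0L) sample.int(n, n_flip) else integer(0)
    group_obs[flip_idx] <- 1L - group_obs[flip_idx]

    list(group_true = group_true, group_obs = group_obs,
         flip_idx = flip_idx, W = W, beta = beta, pos_idx = pos_idx,
         alpha_cpg = alpha_cpg, alpha_inc = alpha_inc,
         sd_cpg = sd_cpg, sd_inc = sd_inc,
         Y_cpg = Y_cpg, Y_inc = Y_inc)
  })

  Y_cpg <- meth_matrix(out$Y_cpg, sample_ids, cpg_ids)
  Y_inc <- meth_matrix(out$Y_inc, sample_ids, inc_ids)
  design <- design_spec(as.numeric(out$group_obs), coef_names = "group")
  truth <- list(beta = stats::setNames(out$beta, cpg_ids),
                true_positives = cpg_ids[out$pos_idx],
                W = out$W,
                alpha_cpg = out$alpha_cpg,
                alpha_inc = out$alpha_inc,
                noise_sd_cpg = stats::setNames(out$sd_cpg, cpg_ids),
                noise_sd_inc = stats::setNames(out$sd_inc, inc_ids),
                true_labels = stats::setNames(out$group_true, sample_ids),
                flipped_samples = sample_ids[out$flip_idx])
  structure(list(Y_cpg = Y_cpg, Y_inc = Y_inc, design = design,
                 truth = truth, params = params),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  p <- x$params
  cat("sim_dataset:", p$n_samples, "samples,", p$n_cpg, "CpGs,",
      p$n_inc, "negative controls,",
      length(x$truth$true_positives), "true positives, k =",
      p$k_unwanted, ", rho =", p$confounding_rho, "\n")
  invisible(x)
}

#' Truth set derived from a simulated dataset
#'
#' Positives are the CpGs with nonzero simulated effect; negatives are all
#' remaining CpGs.
#'
#' @param sim A [simulate_methylation()] result.
#' @return A [truth_set()].
#' @export
sim_truth_set <- function(sim) {
  if (!inherits(sim, "sim_dataset")) fail("`sim` must be a sim_dataset")
  pos <- sim$truth$true_positives
  neg <- setdiff(colnames(sim$Y_cpg), pos)
  truth_set(pos, neg)
}
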