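---
title: "Two-stage removal of unwanted variation for differential methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage removal of unwanted variation for differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
options(ruvm.quiet = TRUE)
library(ruvm)
```

## The problem

Large differential methylation (DM) studies on Illumina 450k-style arrays
are routinely contaminated by unwanted variation: batch effects from
processing samples over days or labs, shifts in blood cell composition,
misreported phenotypes and sample mix-ups. When these effects are larger
than the biological effect of interest — common in epigenome-wide
association studies — an unadjusted per-CpG regression ranks artefacts
above real signal.

This package implements a two-stage adjustment built around negative
control features. The working model for the M-values (log2 ratio of
methylated to unmethylated signal) of each CpG is

$$ Y = Z\gamma + X\beta + W\alpha + \varepsilon , $$

where `X` holds the factor of interest, `Z` the known covariates
(intercept by default), and `W` an unknown matrix of unwanted factors
with per-feature loadings `alpha`. `W` is never estimated explicitly.
Instead, features believed to carry no `X` signal — negative controls —
are used to estimate the sample-by-sample covariance that the unwanted
factors induce, and each CpG is fit by generalized least squares (GLS)
with that covariance:

$$ \hat\beta_g = \left[(M'\Sigma^{-1}M)^{-1}M'\Sigma^{-1}Y_g\right]_X,
   \qquad M = [Z\ X],\quad
   \Sigma = \tfrac{1}{n_c} R_c R_c' + \lambda I , $$

with `R_c` the control M-values residualized against `Z`. Directions of
sample space dominated by unwanted factors have large control covariance
and are downweighted; no number of factors `k` ever has to be chosen.

## The two stages

1. **Stage 1** uses the platform negative controls — on 450k arrays the
   613 randomly permuted probe sequences that should not hybridize and
   capture technical variation only — to rank all CpGs by p-value
   (`stage1_fit()`).
2. **Empirical control probes (ECPs)** are selected from the *least*
   associated CpGs of that ranking (`select_ecps()`), either by an FDR
   cut-off (`fdr > threshold`) or by taking a fixed bottom fraction of
   the ranked list. Unlike the platform controls, ECPs are real CpGs and
   carry biological unwanted variation (e.g. cell composition), which
   makes them more informative controls.
3. **Stage 2** refits every CpG with the covariance estimated from the
   ECP columns of the data themselves (`stage2_fit()`). ECPs stay in the
   tested universe and receive statistics like any other feature. The
   select/refit round can be iterated (`ruvm(iterations = )`), each round
   re-selecting ECPs from the latest fit; once is usually enough.

The procedure relies on Stage 1 being "good enough" and Stage 2 being
robust to an imperfect control set; the acceptance tests check that
contaminating the ECPs with 5% truly associated CpGs moves the final
AUC by less than 0.02 on the bundled confounded scenario.

## Standard errors by the inverse method

Classical GLS standard errors depend only on the design and `Sigma`, so
every CpG would get the same SE — undesirable, since CpGs differ in
variability. The inverse method instead augments the design with a
random column `z_b` (iid standard normal, residualized against `[Z X]`,
unit-normalized), whose true coefficient is zero by construction, refits,
and records its estimated coefficient $\hat\gamma_{g,b}$ per feature.
Over `B` replicates,

$$ SE_g = \sqrt{\kappa\,\overline{\hat\gamma^2_{g,\cdot}}},\qquad
   \kappa = \frac{a_X}{\overline{v}} , $$

where $a_X$ is the analytic sampling variance of $\hat\beta$ and $v_b$
that of $\hat\gamma_b$, both evaluated under unit-variance white noise.
This calibration makes $E[SE_g^2]$ equal the true sampling variance of
$\hat\beta_g$ under homoscedastic Gaussian noise — the contract the test
suite checks against the closed-form ordinary-least-squares variance.
The exact SE construction in the original derivation is not spelled out
at this level of detail; this calibrated reconstruction is validated by
its homoscedastic oracle rather than taken from a reference.

Tunable parameters:

* `B` (default 50): random-column replicates. SEs stabilize as `B` grows;
  50 balances stability against runtime, and the suite verifies that the
  Monte-Carlo spread of SEs shrinks from `B = 50` to `B = 500`. For
  sharp null calibration checks we use `B = 200`.
* `ridge_lambda` (default automatic): when fewer controls than samples
  are available, or the control covariance is numerically singular
  (condition number above 1e12), `0.1 * trace(Sigma_c)/n` is added to the
  diagonal. A 450k analysis (613 controls, tens to hundreds of samples)
  never triggers this.
* degrees of freedom: `n - rank(Z) - rank(X)`, the residual df of the
  expanded mean model; with the grouped-replicate structure of the
  random-column average this yields near-uniform null p-values (checked
  by a Kolmogorov–Smirnov test at the 1% level).
* tie-breaking in ranks: p ascending, then |t| descending, then feature
  id — ranks are a deterministic permutation.

Per-stage seeds are derived from one master seed as `seed + stage index`,
so a single integer reproduces the whole analysis bit-for-bit.

## Choosing the ECP rule

The default is the bottom 50% of the ranked list (equivalently an FDR
cut-off around 0.5), a sensible middle ground when nothing is known about
the expected amount of DM. Guidance encoded in `ecp_rule()`:

* subtle phenotypes (smoking-like, few loci, ~5% methylation
  differences): a large bottom fraction (up to 90%) is safe;
* widespread DM (cancer vs normal, where ~40% of CpGs can be truly
  associated): prefer an FDR cut-off, which avoids designating truly
  associated probes as controls; large bottom fractions degrade the fit.
  `select_ecps()` errors, rather than silently proceeding, when a rule
  selects nothing.

## Preprocessing

`m_from_intensities()` computes `M = log2((meth + offset)/(unmeth +
offset))`; the default offset is 0 with strictly positive channels
required (common practice adds a small offset; none is assumed here).
`filter_samples()` drops arrays with mean detection p-value above 0.01;
`filter_probes()` then drops probes failing detection in any retained
sample, on chromosome X/Y (dialects `X`/`chrX` etc., case-insensitive),
with a SNP at the CpG or single-base-extension site, or known to
cross-hybridize. Samples are filtered before the probe detection rule is
applied. Negative-control probes have no genomic locus and bypass the
annotation rules but respect the detection rule when detection values
are provided. Normalization (SWAN/SQN/functional) and IDAT decoding are
upstream of this package: it consumes already-normalized matrices.

## Diagnostics and evaluation

* `rle_summary()`: per-array five-number summaries of deviations from
  each feature's across-array median M-value; displaced or wide boxes
  flag batches and bad arrays.
* `mds_coordinates()`: classical (Torgerson) scaling of sample-sample
  Euclidean distances on the `top_n = 1000` most variable features;
  chosen over nonmetric MDS because the display is read like a PCA of
  samples. Coordinates are centered and dimensions ordered by
  eigenvalue.
* `pvalue_histogram()`: the ideal shape is near-uniform with a spike at
  zero; equal-width bins with a right-closed last bin.
* `roc_auc()`: features scored by `-pvalue`; tied scores are grouped
  into single ROC vertices so the trapezoidal AUC equals the
  tie-corrected Mann–Whitney probability (determinism under ties).
* `cumulative_tp_curve()`: known positives recovered among the top-k
  ranked features.

Truth sets are user-supplied (`truth_set()`, `read_truth_set()`); the
published truth lists used in the original evaluations are not bundled.

## The synthetic-data generator

`simulate_methylation()` draws directly from the working model on the
M-value scale: balanced two-group `X`; sparse effects of magnitude
`effect_size` with random signs; `k_unwanted` Gaussian factors, the
first optionally correlated `confounding_rho` with the standardized
group indicator (`W1 = rho * x_std + sqrt(1 - rho^2) * noise`, which has
exactly the requested population correlation); loadings on both CpGs and
a separate negative-control block (which never receives `beta`);
per-feature noise sds drawn lognormal(`log 0.3`, `0.3`) to emulate CpGs
differing in variability; per-CpG baselines N(0, 2); and optional label
flipping after generation to emulate misreported phenotypes.

Presets encode the archetypal scenarios: `clean` (pure null),
`batch_dominated` (large effect, even larger batch — the merged
multi-study ageing situation), `confounded_mislabel` (small ~5%-type
effect, batch correlated 0.6 with the groups, 5% mislabels — the
constructed smoking-plus-foreign-samples situation) and `high_dm`
(40% of CpGs affected — cancer-like).

What the generator does **not** emulate: Infinium I/II probe-type
chemistry, the bimodal beta-value distribution of real arrays (baselines
are Gaussian on the M scale), spatial/chip layout structure, and
detection-p mechanisms. A green test therefore establishes that the
estimator removes linear factor structure shared with controls under
realistic noise — not that it reproduces any published dataset's
numbers, which depend on large external cohorts and truth lists.

One statistical subtlety the tests respect: with a shared unwanted
factor, all control features move with the same factor draw, so the
per-dataset fraction of nominally significant controls is over-dispersed
relative to a binomial band (and the naive t-test is conservative); the
exact binomial check applies only with `k_unwanted = 0`.

## Numerical choices and degenerate inputs

* Whitening via the Cholesky factor of `Sigma_c + lambda I`; a
  non-positive-definite effective covariance is an error, not a silent
  fallback.
* Random columns numerically collinear with `[Z X]` are redrawn (bounded
  retries), then an error is raised.
* `se = 0` with a zero estimate yields `t = 0, p = 1`; with a nonzero
  estimate `p = 0` plus a logged warning — never `NaN`.
* All-constant control features (zero covariance) and empty ECP
  selections are errors with actionable messages.
* Variance moderation (baseline path) falls back to unmoderated
  statistics with a warning if the moment estimation of the prior fails.
* Input TSVs are validated: duplicate ids, ragged rows and non-numeric
  cells are rejected with the offending line named; `NA` cells are not
  accepted (imputation is out of scope).

## A worked example

```{r example}
params <- sim_preset("confounded_mislabel")
sim <- simulate_methylation(params)
res <- ruvm(sim$Y_cpg, sim$Y_inc, sim$design,
            rule = ecp_rule("bottom_fraction", 0.5), B = 50, seed = 1)
base <- fit_baseline(sim$Y_cpg, sim$design)
truth <- sim_truth_set(sim)
c(ruvm = roc_auc(res$stage2, truth)$auc,
  baseline = roc_auc(base, truth)$auc)
```

Under confounding the two-stage fit recovers most true positives while
the unadjusted moderated-t baseline is near chance; the package's test
suite asserts this gap (positive margin in at least 9 of 10 seeds, mean
above 0.05) along with the estimator-level contracts described above.

## Known limitations

* Only RUV-inverse is provided; the 2-step and rank-k variants of the
  removal-of-unwanted-variation family, and comparators such as ComBat,
  SVA and ISVA, are out of scope.
* One coefficient of interest is reported per fit (`coef` selects a
  column of `X`); there is no contrast machinery or trended/robust
  empirical Bayes.
* The pipeline expects complete matrices on the M-value scale;
  normalization and IDAT parsing happen upstream.
* With very few samples the control covariance is rank-deficient and the
  ridge dominates; results then approach ordinary least squares.
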