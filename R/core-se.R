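# Inverse-method standard errors.
#
# Classical GLS standard errors depend on the design and covariance only,
# so every feature would get the same SE. To let features differ, the
# model is refit B times with an extra randomly generated design column
# whose true coefficient is zero; the spread of that coefficient's
# estimates across replicates measures each feature's variability. A
# design-based calibration constant kappa rescales the mean squared
# random-column coefficient so that, under homoscedastic unit-variance
# noise, the expected squared SE equals the true sampling variance of the
# coefficient of interest.

#' Per-feature standard errors by the inverse (random column) method
#'
#' For replicates `b = 1..B`: draw an n-vector of iid standard normals,
#' residualize it against `[Z X]`, normalize to unit length, refit the GLS
#' model with this extra column and record its coefficient
#' \eqn{\hat\gamma_{g,b}} for every feature g. The standard error is
#' \eqn{SE_g = \sqrt{\kappa\, \mathrm{mean}_b\, \hat\gamma^2_{g,b}}} with
#' \eqn{\kappa = a_X / \mathrm{mean}_b v_b}, where \eqn{a_X} is the
#' sampling variance of \eqn{\hat\beta} and \eqn{v_b} that of
#' \eqn{\hat\gamma_b}, both evaluated analytically under unit-variance
#' white noise. Deterministic given `(seed, B)`.
#'
#' @param Y Methylation matrix (samples x features).
#' @param design A [design_spec()].
#' @param ctx A [gls_context()] on the same samples.
#' @param B Number of random-column replicates (at least 2; default 50).
#' @param seed Integer seed for the random columns.
#' @param keep_replicates If `TRUE`, return the per-replicate coefficient
#'   matrix and the random columns themselves.
#' @param max_retries Redraw budget for random columns that are numerically
#'   collinear with `[Z X]`.
#' @return A list with `se` (matrix, coefficients of interest x features),
#'   `kappa` (per-coefficient calibration constants), `mean_gamma2`
#'   (per-feature mean squared random-column coefficient), `v_b`
#'   (per-replicate analytic variances), `B`, `seed`, and when requested
#'   `gamma` (features x B) and `z` (samples x B).
#' @export
inverse_method_se <- function(Y, design, ctx, B = 50L, seed = 1L,
                              keep_replicates = FALSE, max_retries = 10L) {
  check_meth(Y)
  check_design(design)
  if (!inherits(ctx, "gls_context"))
    fail("`ctx` must be a gls_context")
  B <- as.integer(B)
  if (is.na(B) || B < 2L)
    fail("`B` must be an integer >= 2")
  n <- nrow(Y)
  m <- ncol(Y)
  if (nrow(ctx$sigma_c) != n || nrow(design$X) != n)
    fail("Y, design and ctx disagree on the number of samples")

  M <- cbind(design$Z, design$X)
  q <- ncol(design$Z)
  p <- ncol(design$X)
  Mw <- whiten(ctx, M)
  Yw <- whiten(ctx, Y)
  qmw <- qr(Mw)
  if (qmw$rank < ncol(M)) fail("whitened design is rank deficient")
  qm_raw <- qr(M)

  # Analytic sampling variance of beta-hat under Sigma0 = I noise:
  # rows of (Mw'Mw)^-1 Mw' W applied to raw data, W = inverse whitener.
  Wmat <- backsolve(ctx$chol, diag(n), transpose = TRUE) # R^-T
  G <- solve(crossprod(Mw), t(Mw) %*% Wmat)              # (q+p) x n
  a_X <- rowSums(G^2)[q + seq_len(p)]

  gamma2_sum <- numeric(m)
  gamma_all <- if (keep_replicates) matrix(NA_real_, m, B) else NULL
  z_all <- if (keep_replicates) matrix(NA_real_, n, B) else NULL
  gamma_grand_sum <- 0
  v_b <- numeric(B)

  with_seed(seed, {
    for (b in seq_len(B)) {
      zb <- NULL
      for (try in seq_len(max_retries)) {
        z <- stats::rnorm(n)
        zr <- qr.resid(qm_raw, z)
        nz <- sqrt(sum(zr^2))
        if (nz > 1e-8) {
          zb <- zr / nz
          break
        }
      }
      if (is.null(zb))
        fail("random column collinear with [Z X] after ", max_retries,
             " redraws")
      zw <- whiten(ctx, zb)
      zt <- qr.resid(qmw, zw)      # whitened column, net of [Z X]
      d <- sum(zt^2)
      if (d <= 1e-12)
        fail("random column numerically collinear with [Z X] in the GLS metric")
      gam <- as.numeric(crossprod(zt, Yw)) / d
      v_b[b] <- sum(backsolve(ctx$chol, zt)^2) / d^2
      gamma2_sum <- gamma2_sum + gam^2
      gamma_grand_sum <- gamma_grand_sum + sum(gam)
      if (keep_replicates) {
        gamma_all[, b] <- gam
        z_all[, b] <- zb
      }
    }
  })

  mean_gamma2 <- gamma2_sum / B
  kappa <- a_X / mean(v_b)
  se <- sqrt(outer(kappa, mean_gamma2))
  rownames(se) <- design$coef_names
  colnames(se) <- colnames(Y)

  out <- list(se = se, kappa = kappa, mean_gamma2 = mean_gamma2,
              v_b = v_b, a_X = a_X, B = B, seed = as.integer(seed),
              gamma_grand_mean = gamma_grand_sum / (B * m))
  if (keep_replicates) {
    dimnames(gamma_all) <- list(colnames(Y), NULL)
    out$gamma <- gamma_all
    out$z <- z_all
  }
  out
}
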