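# RUV-inverse core: control-derived sample covariance and per-feature GLS.
#
# Differential methylation is estimated by generalized least squares with
# weight matrix the inverse of the empirical sample covariance of the
# negative-control features. Because the controls carry only unwanted and
# technical variation, directions of sample space dominated by unwanted
# factors get large control covariance and are downweighted in the fit;
# no explicit factor count k is ever chosen.

# Residualize the columns of A against the column space of Z (Euclidean
# projection). Zero-column Z is the identity.
residualize <- function(A, Z) {
  if (is.null(Z) || ncol(Z) == 0L) return(A)
  qz <- qr(Z)
  qr.resid(qz, A)
}

#' Build a GLS context from an explicit covariance matrix
#'
#' Low-level constructor used by [control_covariance()] and useful in its
#' own right for fitting with a known covariance (e.g. the identity, under
#' which GLS reduces to ordinary least squares).
#'
#' @param sigma_c Symmetric n x n sample covariance matrix.
#' @param ridge_lambda Nonnegative ridge added to the diagonal before
#'   inversion; 0 uses `sigma_c` as is.
#' @param n_controls Number of control features the covariance was
#'   estimated from (metadata only).
#' @return An object of class `"gls_context"` holding `sigma_c`,
#'   `ridge_lambda`, `n_controls_used`, the effective covariance
#'   `sigma_eff = sigma_c + ridge_lambda * I` and its upper Cholesky factor.
#' @export
gls_context <- function(sigma_c, ridge_lambda = 0, n_controls = NA_integer_) {
  if (!is.matrix(sigma_c) || nrow(sigma_c) != ncol(sigma_c))
    fail("`sigma_c` must be a square matrix")
  if (max(abs(sigma_c - t(sigma_c))) > 1e-8 * max(1, max(abs(sigma_c))))
    fail("`sigma_c` must be symmetric")
  if (!is.numeric(ridge_lambda) || length(ridge_lambda) != 1L ||
      !is.finite(ridge_lambda) || ridge_lambda < 0)
    fail("`ridge_lambda` must be a nonnegative number")
  sigma_c <- (sigma_c + t(sigma_c)) / 2
  sigma_eff <- sigma_c + diag(ridge_lambda, nrow(sigma_c))
  ch <- tryCatch(chol(sigma_eff), error = function(e) NULL)
  if (is.null(ch))
    fail("effective covariance sigma_c + ridge_lambda*I is not positive definite; ",
         "increase ridge_lambda")
  structure(list(sigma_c = sigma_c,
                 ridge_lambda = ridge_lambda,
                 n_controls_used = as.integer(n_controls),
                 sigma_eff = sigma_eff,
                 chol = ch),
            class = "gls_context")
}

#' @export
print.gls_context <- function(x, ...) {
  cat("gls_context:", nrow(x$sigma_c), "samples,",
      x$n_controls_used, "control features, ridge lambda =",
      format(x$ridge_lambda, digits = 4), "\n")
  invisible(x)
}

#' Empirical covariance of negative-control features
#'
#' Computes the sample-by-sample covariance \eqn{\Sigma_c = R_c R_c' / n_c}
#' where \eqn{R_c} holds the control M-values residualized against the
#' known covariates `Z` (factor of interest columns are *not* removed:
#' controls are assumed unassociated with it). When the number of controls
#' is smaller than the number of samples, or the covariance is numerically
#' singular (condition number above 1e12), a ridge
#' \eqn{\lambda = 0.1\,\mathrm{tr}(\Sigma_c)/n} is added by default.
#'
#' @param Y Methylation matrix (samples x features) containing the control
#'   features, e.g. the platform negative-control block.
#' @param design A [design_spec()]; only `Z` is used.
#' @param controls A [control_set()] or character vector of feature ids,
#'   all present in `colnames(Y)`.
#' @param ridge_lambda Optional explicit ridge; `NULL` (default) applies
#'   the automatic rule above.
#' @return A [gls_context()].
#' @export
control_covariance <- function(Y, design, controls, ridge_lambda = NULL) {
  check_meth(Y)
  check_design(design)
  ids <- control_ids(controls)
  unknown <- setdiff(ids, colnames(Y))
  if (length(unknown) > 0L)
    fail("unknown control feature ids: ",
         paste(utils::head(unknown, 10L), collapse = ", "),
         if (length(unknown) > 10L) ", ...")
  if (length(ids) < 2L)
    fail("need at least 2 control features")
  if (nrow(design$Z) != nrow(Y))
    fail("design and Y disagree on the number of samples")
  n <- nrow(Y)
  Yc <- Y[, ids, drop = FALSE]
  R <- residualize(Yc, design$Z)
  nc <- ncol(R)
  sigma <- tcrossprod(R) / nc
  if (max(abs(sigma)) == 0)
    fail("all control features are constant after residualization (zero covariance)")
  if (is.null(ridge_lambda)) {
    ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    singular <- nc < n || min(ev) <= max(ev) / 1e12
    ridge_lambda <- if (singular) 0.1 * sum(diag(sigma)) / n else 0
  }
  ctx <- gls_context(sigma, ridge_lambda = ridge_lambda, n_controls = nc)
  log_info("control covariance from ", nc, " features over ", n,
           " samples (ridge lambda = ", format(ctx$ridge_lambda, digits = 4), ")")
  ctx
}

# Whitened design and response: multiply by the inverse transpose of the
# upper Cholesky factor so crossprod(Mw) = M' Sigma^-1 M.
whiten <- function(ctx, A) {
  backsolve(ctx$chol, A, transpose = TRUE)
}

#' Per-feature GLS coefficient estimates
#'
#' Fits each feature's M-values on `[Z X]` by generalized least squares
#' with weight matrix \eqn{(\Sigma_c + \lambda I)^{-1}}, returning the
#' coefficients of the factor of interest:
#' \eqn{\hat\beta = [(M'\Sigma^{-1}M)^{-1} M'\Sigma^{-1} Y]_X} with
#' \eqn{M = [Z\ X]}.
#'
#' @param Y Methylation matrix (samples x features) of the features to test.
#' @param design A [design_spec()].
#' @param ctx A [gls_context()] built on the same samples, in the same order.
#' @return Numeric matrix, `ncol(design$X)` rows (named by `coef_names`)
#'   by `ncol(Y)` feature columns.
#' @export
gls_fit <- function(Y, design, ctx) {
  check_meth(Y)
  check_design(design)
  if (!inherits(ctx, "gls_context"))
    fail("`ctx` must be a gls_context")
  n <- nrow(Y)
  if (nrow(ctx$sigma_c) != n || nrow(design$X) != n)
    fail("Y, design and ctx disagree on the number of samples")
  M <- cbind(design$Z, design$X)
  Mw <- whiten(ctx, M)
  Yw <- whiten(ctx, Y)
  qm <- qr(Mw)
  if (qm$rank < ncol(M))
    fail("whitened design is rank deficient")
  cf <- qr.coef(qm, Yw)
  q <- ncol(design$Z)
  p <- ncol(design$X)
  beta <- cf[q + seq_len(p), , drop = FALSE]
  rownames(beta) <- design$coef_names
  colnames(beta) <- colnames(Y)
  beta
}
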