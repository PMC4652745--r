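# Test statistics, multiple-testing adjustment and the moderated-variance
# path used by the baseline comparator.

#' t-statistics and two-sided p-values
#'
#' @param beta_hat Numeric vector of coefficient estimates.
#' @param se Numeric vector of standard errors (nonnegative; same length).
#' @param df Residual degrees of freedom (positive; may be `Inf`).
#' @return A list with elements `t` and `p`. Features with `se = 0` and
#'   `beta_hat = 0` get `t = 0, p = 1`; `se = 0` with a nonzero estimate
#'   gets `p = 0` (infinite t) and a warning is logged.
#' @export
t_and_p <- function(beta_hat, se, df) {
  if (length(beta_hat) != length(se))
    fail("`beta_hat` and `se` must have the same length")
  if (any(se < 0)) fail("`se` must be nonnegative")
  if (!is.numeric(df) || length(df) != 1L || is.na(df) || df <= 0)
    fail("`df` must be a positive number")
  t <- ifelse(se > 0, beta_hat / se,
              ifelse(beta_hat == 0, 0, sign(beta_hat) * Inf))
  zero_se_signal <- se == 0 & beta_hat != 0
  if (any(zero_se_signal))
    log_warn(sum(zero_se_signal),
             " feature(s) with zero SE but nonzero estimate; p set to 0")
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  p[zero_se_signal] <- 0
  list(t = t, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: with sorted p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, the adjusted value is
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}, mapped back to
#' the original order.
#'
#' @param p_values Numeric vector with entries in \[0, 1\].
#' @return Numeric vector of FDR-adjusted p-values, same order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) fail("`p_values` must be numeric")
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    fail("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Empirical Bayes variance moderation (baseline comparator path)
#'
#' Shrinks per-feature squared standard errors toward a common prior using
#' the scaled-F moment-matching machinery of limma:
#' \eqn{\tilde s^2_g = (d_0 s_0^2 + d\, s^2_g)/(d_0 + d)}, with the prior
#' \eqn{(d_0, s_0^2)} estimated from the spread of \eqn{\log s^2_g}. The
#' moderated t uses \eqn{d + d_0} degrees of freedom. If the moment
#' estimation fails or yields a non-finite prior the unmoderated
#' statistics are returned with a logged warning.
#'
#' @param se Per-feature standard errors (at least 4 must be positive).
#' @param df Residual degrees of freedom of each `se`.
#' @param beta_hat Per-feature coefficient estimates.
#' @return A list with moderated `se`, total `df`, `t`, `p`, plus
#'   `df_prior` and `var_prior`.
#' @export
moderate_variances <- function(se, df, beta_hat) {
  if (length(se) != length(beta_hat))
    fail("`se` and `beta_hat` must have the same length")
  if (sum(se > 0) < 4L)
    fail("need at least 4 features with positive SE for moment estimation")
  s2 <- se^2
  sq <- tryCatch(limma::squeezeVar(s2, df = df), error = function(e) NULL)
  if (is.null(sq) || !is.numeric(sq$df.prior) ||
      any(is.na(sq$df.prior)) || any(sq$df.prior < 0)) {
    log_warn("variance moderation failed; falling back to unmoderated statistics")
    tp <- t_and_p(beta_hat, se, df)
    return(list(se = se, df = df, t = tp$t, p = tp$p,
                df_prior = NA_real_, var_prior = NA_real_))
  }
  se_mod <- sqrt(sq$var.post)
  df_total <- df + sq$df.prior
  tp <- t_and_p(beta_hat, se_mod, df_total)
  list(se = se_mod, df = df_total, t = tp$t, p = tp$p,
       df_prior = sq$df.prior, var_prior = sq$var.prior)
}

# Deterministic feature ranking: p ascending, then |t| descending, then
# feature id lexicographic.
rank_features <- function(p, t, feature_ids) {
  o <- order(p, -abs(t), feature_ids)
  r <- integer(length(p))
  r[o] <- seq_along(o)
  r
}

# Assemble the per-feature result table shared by all fitting routines.
new_ruv_fit <- function(feature_ids, coef, se, t, p, df, B = NA_integer_,
                        seed = NA_integer_, method = "ruv_inverse",
                        n_controls = NA_integer_) {
  fdr <- bh_adjust(p)
  fit <- data.frame(feature_id = feature_ids,
                    coef = coef, se = se, t = t,
                    pvalue = p, fdr = fdr,
                    rank = rank_features(p, t, feature_ids),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(fit, "df") <- df
  attr(fit, "B") <- as.integer(B)
  attr(fit, "seed") <- as.integer(seed)
  attr(fit, "method") <- method
  attr(fit, "n_controls") <- as.integer(n_controls)
  class(fit) <- c("ruv_fit", "data.frame")
  fit
}

#' @export
print.ruv_fit <- function(x, n = 6L, ...) {
  cat("ruv_fit (", attr(x, "method"), "): ", nrow(x), " features, df = ",
      format(attr(x, "df"), digits = 4), "\n", sep = "")
  print(utils::head(as.data.frame(x)[order(x$rank), ], n))
  invisible(x)
}
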