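# Independent oracles and small fixture builders used across the suite.
options(ruvm.quiet = TRUE)

# Dense GLS formula, coded independently of gls_fit's whitening path.
gls_oracle <- function(Y, Z, X, Sigma) {
  M <- cbind(Z, X)
  Si <- solve(Sigma)
  solve(t(M) %*% Si %*% M) %*% t(M) %*% Si %*% Y
}

# Brute-force Benjamini-Hochberg step-up: p_(j) * m / j, suffix minima.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Tie-corrected Mann-Whitney AUC by exhaustive pair enumeration.
mw_auc_oracle <- function(score_pos, score_neg) {
  tot <- 0
  for (sp in score_pos) for (sn in score_neg)
    tot <- tot + (sp > sn) + 0.5 * (sp == sn)
  tot / (length(score_pos) * length(score_neg))
}

# Random small regression instance for property tests.
random_instance <- function(n, m = 3, q = 1, p = 1) {
  Z <- cbind(rep(1, n),
             if (q > 1) matrix(rnorm(n * (q - 1)), n) else NULL)
  X <- matrix(rnorm(n * p), n)
  A <- matrix(rnorm(n * n), n)
  Sigma <- crossprod(A) / n + diag(n) * 0.3
  Y <- meth_matrix(matrix(rnorm(n * m), n, m),
                   paste0("s", seq_len(n)), paste0("g", seq_len(m)))
  list(Y = Y, Z = Z, X = X, Sigma = Sigma,
       design = design_spec(X, Z))
}

quiet_cli <- function(args) {
  withCallingHandlers(ruv_cli(args),
                      message = function(m) invokeRestart("muffleMessage"))
}
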