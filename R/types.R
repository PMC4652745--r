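# Domain containers: methylation matrices, design specifications and
# control-probe sets. Matrices follow the internal convention
# samples x features (rownames = sample ids, colnames = feature ids);
# on disk the conventional layout is features x samples and the readers
# in io.R transpose.

#' Construct a methylation matrix (samples x features)
#'
#' Wraps a numeric matrix of M-values with validated sample and feature
#' identifiers. M-values are the log2 ratio of methylated to unmethylated
#' signal; all analysis functions in this package operate on that scale.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `rownames(values)`).
#' @param feature_ids Character vector of unique feature identifiers
#'   (defaults to `colnames(values)`).
#' @return A numeric matrix with validated dimnames.
#' @examples
#' Y <- meth_matrix(matrix(rnorm(6), 2, 3),
#'                  sample_ids = c("s1", "s2"),
#'                  feature_ids = c("cg1", "cg2", "cg3"))
#' @export
meth_matrix <- function(values, sample_ids = rownames(values),
                        feature_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    fail("`values` must be a numeric matrix")
  if (is.null(sample_ids) || is.null(feature_ids))
    fail("sample and feature identifiers are required")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values))
    fail("length of sample_ids (", length(sample_ids),
         ") does not match the number of rows (", nrow(values), ")")
  if (length(feature_ids) != ncol(values))
    fail("length of feature_ids (", length(feature_ids),
         ") does not match the number of columns (", ncol(values), ")")
  if (anyDuplicated(sample_ids))
    fail("duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_ids))
    fail("duplicated feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    fail("matrix contains non-finite values")
  dimnames(values) <- list(sample_ids, feature_ids)
  values
}

# Validate that Y looks like a meth_matrix; returns it invisibly.
check_meth <- function(Y, arg = "Y") {
  if (!is.matrix(Y) || !is.numeric(Y))
    fail("`", arg, "` must be a numeric matrix (samples x features)")
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    fail("`", arg, "` must carry sample ids (rownames) and feature ids (colnames)")
  if (!all(is.finite(Y)))
    fail("`", arg, "` contains non-finite values")
  invisible(Y)
}

#' Specify the regression design
#'
#' Builds the design for the per-feature model
#' \eqn{Y = Z\gamma + X\beta + W\alpha + \epsilon}: `X` holds the factor
#' of interest (the coefficients to be tested) and `Z` the known nuisance
#' covariates, an all-ones intercept by default. The unwanted component
#' \eqn{W\alpha} is never modelled explicitly; the RUV-inverse estimator
#' absorbs it through the control-probe covariance.
#'
#' @param X Factor of interest: a numeric vector, a two-level factor
#'   (converted to a 0/1 indicator), or a numeric matrix with one column
#'   per coefficient of interest.
#' @param Z Known covariates as a numeric matrix, or `NULL` for an
#'   intercept-only `Z`. Pass a zero-column matrix to fit with no
#'   nuisance covariates at all.
#' @param coef_names Names for the columns of `X`.
#' @return An object of class `"design_spec"` with elements `X`, `Z` and
#'   `coef_names`.
#' @examples
#' design_spec(rep(0:1, each = 5))
#' @export
design_spec <- function(X, Z = NULL, coef_names = NULL) {
  if (is.factor(X)) {
    if (nlevels(X) != 2L)
      fail("factor `X` must have exactly 2 levels; use a model matrix otherwise")
    X <- as.numeric(X == levels(X)[2L])
  }
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, ncol = 1L)
  if (!is.matrix(X) || !is.numeric(X) || ncol(X) < 1L)
    fail("`X` must be a numeric vector or matrix with at least one column")
  n <- nrow(X)
  if (is.null(Z)) {
    Z <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  if (!is.matrix(Z) || !is.numeric(Z))
    fail("`Z` must be a numeric matrix (or NULL for an intercept)")
  if (nrow(Z) != n)
    fail("`Z` has ", nrow(Z), " rows but `X` has ", n)
  if (is.null(coef_names)) {
    coef_names <- colnames(X)
    if (is.null(coef_names)) coef_names <- paste0("X", seq_len(ncol(X)))
  }
  if (length(coef_names) != ncol(X))
    fail("`coef_names` must have one name per column of `X`")
  colnames(X) <- coef_names
  M <- cbind(Z, X)
  if (n <= ncol(M))
    fail("need more samples (", n, ") than design columns (", ncol(M), ")")
  if (qr(M)$rank < ncol(M))
    fail("design matrix [Z X] is rank deficient")
  structure(list(X = X, Z = Z, coef_names = coef_names),
            class = "design_spec")
}

check_design <- function(design) {
  if (!inherits(design, "design_spec"))
    fail("`design` must be created with design_spec()")
  invisible(design)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("design_spec:", nrow(x$X), "samples,",
      ncol(x$Z), "known covariate(s),",
      ncol(x$X), "coefficient(s) of interest:",
      paste(x$coef_names, collapse = ", "), "\n")
  invisible(x)
}

#' Define a set of negative-control features
#'
#' Negative controls are features believed to carry no signal from the
#' factor of interest while still being affected by unwanted variation.
#' Stage 1 of the two-stage pipeline uses the platform negative controls
#' (on 450k arrays, the 613 randomly permuted probe sequences); Stage 2
#' uses empirical control probes (ECPs) selected from the least
#' associated CpGs.
#'
#' @param feature_ids Character vector of feature identifiers; duplicates
#'   are removed, order is preserved.
#' @param origin One of `"user"`, `"platform_negative"`, `"empirical"`.
#' @return An object of class `"control_set"`.
#' @export
control_set <- function(feature_ids,
                        origin = c("user", "platform_negative", "empirical")) {
  origin <- match.arg(origin)
  feature_ids <- unique(as.character(feature_ids))
  if (length(feature_ids) == 0L)
    fail("control set must be nonempty")
  structure(list(feature_ids = feature_ids, origin = origin),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat("control_set:", length(x$feature_ids), "features, origin =",
      x$origin, "\n")
  invisible(x)
}

# Accept either a control_set or a bare character vector of ids.
control_ids <- function(controls) {
  if (inherits(controls, "control_set")) return(controls$feature_ids)
  if (is.character(controls) && length(controls) > 0L) return(controls)
  fail("`controls` must be a control_set or a character vector of feature ids")
}

#' Define a truth set for ranking evaluation
#'
#' @param positives Character vector of feature ids regarded as truly
#'   differentially methylated.
#' @param negatives Character vector of feature ids regarded as truly
#'   unassociated. Must be disjoint from `positives`.
#' @return An object of class `"truth_set"`.
#' @export
truth_set <- function(positives, negatives) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  if (length(positives) == 0L || length(negatives) == 0L)
    fail("both positives and negatives must be nonempty")
  both <- intersect(positives, negatives)
  if (length(both) > 0L)
    fail("truth sets overlap: ", paste(utils::head(both, 5L), collapse = ", "))
  structure(list(positives = positives, negatives = negatives),
            class = "truth_set")
}
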