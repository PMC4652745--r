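# M-value computation and sample/probe filtering.
#
# All downstream analysis operates on M-values, M = log2(meth/unmeth).
# Filtering follows standard 450k practice: drop poor-quality samples by
# mean detection p-value, then drop probes that fail detection in any
# remaining sample, sit on the sex chromosomes, overlap a SNP at the CpG
# or single-base-extension site, or are known to cross-hybridize.

#' M-values from methylated/unmethylated intensities
#'
#' `M = log2((meth + offset) / (unmeth + offset))`. With the default
#' offset of 0 both channels must be strictly positive.
#'
#' @param methylated,unmethylated Nonnegative numeric matrices of equal
#'   shape (samples x features) with matching dimnames.
#' @param offset Nonnegative value added to both channels before the
#'   ratio; guards against zero intensities.
#' @return A methylation matrix of M-values.
#' @export
m_from_intensities <- function(methylated, unmethylated, offset = 0) {
  if (!is.matrix(methylated) || !is.matrix(unmethylated) ||
      !identical(dim(methylated), dim(unmethylated)))
    fail("channels must be matrices of identical shape")
  if (!all(is.finite(methylated)) || !all(is.finite(unmethylated)) ||
      any(methylated < 0) || any(unmethylated < 0))
    fail("intensities must be finite and nonnegative")
  if (!is.numeric(offset) || length(offset) != 1L || offset < 0)
    fail("`offset` must be a nonnegative number")
  if (offset == 0 && (any(methylated == 0) || any(unmethylated == 0)))
    fail("zero intensities present; use a positive offset")
  M <- log2((methylated + offset) / (unmethylated + offset))
  dimnames(M) <- dimnames(methylated)
  M
}

#' Beta-value to M-value (logit2) transform
#'
#' @param beta Numeric vector/matrix with entries strictly in (0, 1).
#' @return `log2(beta / (1 - beta))`, matching the M-value definition when
#'   `beta = meth / (meth + unmeth)`.
#' @export
beta_to_m <- function(beta) {
  if (!is.numeric(beta)) fail("`beta` must be numeric")
  if (any(!is.finite(beta)) || any(beta <= 0 | beta >= 1))
    fail("beta values must lie strictly in (0, 1); clip boundary values upstream")
  log2(beta / (1 - beta))
}

#' M-value to beta-value transform
#'
#' Inverse of [beta_to_m()]; handy for writing simulated data on the
#' familiar 0-1 scale.
#'
#' @param m Numeric vector/matrix of M-values.
#' @return `2^m / (1 + 2^m)`.
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) fail("`m` must be numeric")
  1 / (1 + 2^(-m))
}

#' Drop poor-quality samples by mean detection p-value
#'
#' @param detp Detection p-value matrix (samples x features), entries in
#'   \[0, 1\].
#' @param threshold Samples whose mean detection p-value across features
#'   exceeds this are discarded (default 0.01).
#' @return List with `retained` and `dropped` sample ids and the
#'   per-sample `means`.
#' @export
filter_samples <- function(detp, threshold = 0.01) {
  check_detp(detp)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    fail("`threshold` must lie strictly in (0, 1)")
  means <- rowMeans(detp)
  drop <- means > threshold
  if (all(drop))
    fail("all samples exceed the mean detection p-value threshold")
  if (any(drop))
    log_info("dropping ", sum(drop), " sample(s): ",
             paste(rownames(detp)[drop], collapse = ", "))
  list(retained = rownames(detp)[!drop],
       dropped = rownames(detp)[drop],
       means = stats::setNames(means, rownames(detp)))
}

check_detp <- function(detp) {
  if (!is.matrix(detp) || !is.numeric(detp))
    fail("`detp` must be a numeric matrix (samples x features)")
  if (is.null(rownames(detp)) || is.null(colnames(detp)))
    fail("`detp` must carry sample and feature ids")
  if (any(!is.finite(detp)) || any(detp < 0 | detp > 1))
    fail("detection p-values must lie in [0, 1]")
  invisible(detp)
}

#' Build a probe annotation table
#'
#' @param feature_id Character vector of probe ids.
#' @param chromosome Chromosome labels (`"X"`/`"chrX"` etc. accepted,
#'   case-insensitive).
#' @param is_negative_control,has_snp_at_cpg_or_sbe,is_cross_reactive
#'   Logical flags per probe.
#' @return A data frame of class `"probe_annotation"`.
#' @export
probe_annotation <- function(feature_id, chromosome,
                             is_negative_control = FALSE,
                             has_snp_at_cpg_or_sbe = FALSE,
                             is_cross_reactive = FALSE) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id)) fail("duplicated feature ids in annotation")
  chromosome <- as.character(chromosome)
  if (any(is.na(chromosome) | chromosome == ""))
    fail("chromosome must be nonempty for every probe")
  ann <- data.frame(feature_id = feature_id,
                    chromosome = chromosome,
                    is_negative_control =
                      rep_len(as.logical(is_negative_control), length(feature_id)),
                    has_snp_at_cpg_or_sbe =
                      rep_len(as.logical(has_snp_at_cpg_or_sbe), length(feature_id)),
                    is_cross_reactive =
                      rep_len(as.logical(is_cross_reactive), length(feature_id)),
                    stringsAsFactors = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

is_sex_chromosome <- function(chr) {
  tolower(chr) %in% c("x", "y", "chrx", "chry")
}

#' Filter probes by detection quality and annotation
#'
#' A probe is discarded if any of the following holds: its detection
#' p-value exceeds `threshold` in at least one (retained) sample; it maps
#' to chromosome X or Y; it has a SNP at the CpG or single-base-extension
#' site; it is cross-reactive. Negative-control probes have no genomic
#' locus and bypass the annotation rules, but are still subject to the
#' detection rule when detection values are provided for them. A probe
#' failing several rules is removed once but counted in every rule's tally.
#'
#' @param detp Detection p-value matrix restricted to retained samples,
#'   or `NULL` to skip the detection rule.
#' @param annotation A [probe_annotation()] covering every tested probe.
#' @param feature_ids Probe ids to filter; defaults to `colnames(detp)`.
#' @param threshold Detection p-value cut-off (default 0.01).
#' @return List with `retained`, `removed` and a named `counts` vector
#'   (`detection`, `sex_chromosome`, `snp`, `cross_reactive`, `total_removed`).
#' @export
filter_probes <- function(detp, annotation, feature_ids = NULL,
                          threshold = 0.01) {
  if (!inherits(annotation, "probe_annotation"))
    fail("`annotation` must be a probe_annotation")
  if (is.null(feature_ids)) {
    if (is.null(detp)) fail("supply feature_ids when detp is NULL")
    feature_ids <- colnames(detp)
  }
  if (!is.null(detp)) check_detp(detp)
  idx <- match(feature_ids, annotation$feature_id)
  neg <- rep(FALSE, length(feature_ids))
  known <- !is.na(idx)
  neg[known] <- annotation$is_negative_control[idx[known]]
  missing_ann <- feature_ids[!known & !neg]
  if (length(missing_ann) > 0L)
    fail("annotation missing for probe(s): ",
         paste(utils::head(missing_ann, 10L), collapse = ", "),
         if (length(missing_ann) > 10L) ", ...")

  fail_det <- rep(FALSE, length(feature_ids))
  if (!is.null(detp)) {
    have_det <- feature_ids %in% colnames(detp)
    maxp <- apply(detp[, feature_ids[have_det], drop = FALSE], 2, max)
    fail_det[have_det] <- maxp > threshold
  }
  chr <- annotation$chromosome[idx]
  fail_sex <- !neg & known & is_sex_chromosome(chr)
  fail_snp <- !neg & known & annotation$has_snp_at_cpg_or_sbe[idx]
  fail_xr <- !neg & known & annotation$is_cross_reactive[idx]
  fail_any <- fail_det | fail_sex | fail_snp | fail_xr

  counts <- c(detection = sum(fail_det),
              sex_chromosome = sum(fail_sex),
              snp = sum(fail_snp),
              cross_reactive = sum(fail_xr),
              total_removed = sum(fail_any))
  log_info("probe filter removed ", counts[["total_removed"]], "/",
           length(feature_ids), " probes")
  list(retained = feature_ids[!fail_any],
       removed = feature_ids[fail_any],
       counts = counts)
}
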