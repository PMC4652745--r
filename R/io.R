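# Tab-delimited readers and writers.
#
# On disk, matrices follow the conventional methylation layout:
# features x samples, first column `feature_id`, header row of sample
# ids. Internally everything is samples x features; readers transpose.
# NA cells are rejected: the pipeline requires complete matrices.

read_tsv_table <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                      colClasses = "character", quote = "",
                      comment.char = "", fill = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) fail("cannot parse ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) fail(path, ": expected feature_id plus sample columns")
  df
}

#' Read a methylation (or intensity / detection p-value) matrix
#'
#' Expects a UTF-8 tab-delimited file laid out features x samples: first
#' column holds feature ids, the header row holds sample ids, the body is
#' numeric. The matrix is transposed to the internal samples x features
#' convention.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix (samples x features) with dimnames.
#' @export
read_meth_matrix <- function(path) {
  df <- read_tsv_table(path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    fail(path, ": duplicate feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    fail(path, ": non-numeric or missing cell at line ", bad[1L, 1L] + 1L,
         " (feature ", ids[bad[1L, 1L]], "), column '",
         colnames(body)[bad[1L, 2L]], "'")
  samp <- colnames(df)[-1L]
  if (anyDuplicated(samp))
    fail(path, ": duplicate sample id(s) in header")
  meth_matrix(t(num), sample_ids = samp, feature_ids = ids)
}

#' Read a detection p-value matrix
#'
#' Same layout as [read_meth_matrix()], with entries restricted to \[0, 1\].
#' @param path Path to the TSV file.
#' @return A numeric matrix (samples x features).
#' @export
read_detection_p <- function(path) {
  detp <- read_meth_matrix(path)
  if (any(detp < 0 | detp > 1))
    fail(path, ": detection p-values must lie in [0, 1]")
  detp
}

#' Read a methylated/unmethylated intensity pair
#'
#' @param meth_path,unmeth_path Paths to the two channel TSVs (same layout
#'   as [read_meth_matrix()]); ids must match.
#' @return List with matrices `methylated` and `unmethylated`.
#' @export
read_intensity_pair <- function(meth_path, unmeth_path) {
  meth <- read_meth_matrix(meth_path)
  unmeth <- read_meth_matrix(unmeth_path)
  if (!identical(dimnames(meth), dimnames(unmeth)))
    fail("intensity channels disagree on sample/feature ids")
  if (any(meth < 0) || any(unmeth < 0))
    fail("intensities must be nonnegative")
  list(methylated = meth, unmethylated = unmeth)
}

#' Write a matrix in the features x samples TSV layout
#'
#' @param Y Matrix, samples x features (internal convention).
#' @param path Output path.
#' @export
write_meth_matrix <- function(Y, path) {
  check_meth(Y)
  df <- data.frame(feature_id = colnames(Y), t(Y),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", rownames(Y))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with a `sample_id` column plus arbitrary covariate columns.
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    fail(path, ": sample sheet needs a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    fail(path, ": duplicate sample ids")
  df
}

#' Read a probe annotation table
#'
#' TSV with columns `feature_id`, `chromosome`, `is_negative_control`,
#' `has_snp_at_cpg_or_sbe`, `is_cross_reactive` (logical or 0/1).
#'
#' @param path Path to the TSV file.
#' @return A [probe_annotation()].
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("feature_id", "chromosome", "is_negative_control",
            "has_snp_at_cpg_or_sbe", "is_cross_reactive")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    fail(path, ": missing annotation column(s): ", paste(miss, collapse = ", "))
  to_flag <- function(x) {
    if (is.logical(x)) return(x)
    as.logical(as.integer(x))
  }
  probe_annotation(df$feature_id, df$chromosome,
                   to_flag(df$is_negative_control),
                   to_flag(df$has_snp_at_cpg_or_sbe),
                   to_flag(df$is_cross_reactive))
}

#' Read a truth set
#'
#' Two-column TSV: `feature_id` and `label` in `{positive, negative}`.
#'
#' @param path Path to the TSV file.
#' @return A [truth_set()].
#' @export
read_truth_set <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  if (!all(c("feature_id", "label") %in% names(df)))
    fail(path, ": truth set needs columns feature_id and label")
  if (!all(df$label %in% c("positive", "negative")))
    fail(path, ": labels must be 'positive' or 'negative'")
  truth_set(df$feature_id[df$label == "positive"],
            df$feature_id[df$label == "negative"])
}

#' Write a truth set
#'
#' @param truth A [truth_set()].
#' @param path Output path.
#' @export
write_truth_set <- function(truth, path) {
  df <- data.frame(feature_id = c(truth$positives, truth$negatives),
                   label = c(rep("positive", length(truth$positives)),
                             rep("negative", length(truth$negatives))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_fit_tsv <- function(fit, path) {
  df <- as.data.frame(fit)[, c("feature_id", "coef", "se", "t",
                               "pvalue", "fdr", "rank")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to a stage TSV.
#' @return A data frame with the fit columns.
#' @export
read_fit_tsv <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("feature_id", "coef", "se", "t", "pvalue", "fdr", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    fail(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write analysis results
#'
#' For a single `ruv_fit`, writes `<name>.tsv` with columns `feature_id`,
#' `coef`, `se`, `t`, `pvalue`, `fdr`, `rank`. For a [ruvm()] result,
#' writes `stage1.tsv`, `stage2.tsv`, an `ecps.txt` id list (final
#' iteration; earlier iterations as `ecps_iter<i>.txt`) and a
#' `run_info.txt` recording package version, seed, B, the ECP rule and
#' input checksums. No timestamps are written, so identical runs produce
#' byte-identical output.
#'
#' @param x A `ruv_fit` or `ruvm_result`.
#' @param dir Output directory (created if needed).
#' @param name Base name used for a single fit (default `"fit"`).
#' @param input_checksums Optional named character vector of md5 sums of
#'   the input files, recorded in `run_info.txt`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, dir, name = "fit", input_checksums = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) fail("cannot create output directory: ", dir)
  paths <- character(0)
  info <- c(paste0("package_version=", as.character(utils::packageVersion("ruvm"))))
  if (inherits(x, "ruvm_result")) {
    p1 <- file.path(dir, "stage1.tsv")
    p2 <- file.path(dir, "stage2.tsv")
    write_fit_tsv(x$stage1, p1)
    write_fit_tsv(x$stage2, p2)
    paths <- c(paths, p1, p2)
    for (i in seq_along(x$ecps)) {
      pe <- if (i == length(x$ecps)) file.path(dir, "ecps.txt")
            else file.path(dir, sprintf("ecps_iter%d.txt", i))
      writeLines(x$ecps[[i]]$feature_ids, pe)
      paths <- c(paths, pe)
    }
    info <- c(info,
              paste0("seed=", x$seed),
              paste0("replicates_B=", x$B),
              paste0("ecp_method=", x$rule$method),
              paste0("ecp_threshold=", x$rule$threshold),
              paste0("iterations=", x$n_stage2_iterations))
  } else if (inherits(x, "ruv_fit")) {
    p1 <- file.path(dir, paste0(name, ".tsv"))
    write_fit_tsv(x, p1)
    paths <- c(paths, p1)
    info <- c(info,
              paste0("method=", attr(x, "method")),
              paste0("seed=", attr(x, "seed")),
              paste0("replicates_B=", attr(x, "B")),
              paste0("df=", attr(x, "df")))
  } else {
    fail("`x` must be a ruv_fit or ruvm_result")
  }
  if (!is.null(input_checksums))
    info <- c(info, paste0("md5_", names(input_checksums), "=",
                           input_checksums))
  pinfo <- file.path(dir, "run_info.txt")
  writeLines(info, pinfo)
  invisible(c(paths, pinfo))
}

#' Read a flat key-value run configuration
#'
#' Lines of the form `key = value` (or `key<TAB>value`); blank lines and
#' `#` comments are ignored. Keys mirror the CLI flag names without the
#' leading `--`; CLI flags override configuration values.
#'
#' @param path Path to the configuration file.
#' @return Named character vector.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) fail("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- character(0)
  for (ln in lines) {
    parts <- if (grepl("=", ln, fixed = TRUE)) {
      c(sub("=.*$", "", ln), sub("^[^=]*=", "", ln))
    } else {
      strsplit(ln, "[\t ]+")[[1L]][1:2]
    }
    key <- trimws(parts[1L])
    val <- trimws(parts[2L])
    if (!nzchar(key) || is.na(val))
      fail("malformed config line: '", ln, "'")
    out[key] <- val
  }
  out
}

#' Write the full simulated-data bundle
#'
#' Writes `cpg_matrix.tsv`, `inc_matrix.tsv` (features x samples),
#' `samples.tsv` (sample sheet with observed and true group),
#' `truth.tsv` (positive/negative labels, consumable by the evaluate
#' step) and `truth_beta.tsv` (per-CpG true effect and noise sd).
#'
#' @param sim A [simulate_methylation()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_sim_bundle <- function(sim, dir) {
  if (!inherits(sim, "sim_dataset")) fail("`sim` must be a sim_dataset")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(cpg = file.path(dir, "cpg_matrix.tsv"),
         inc = file.path(dir, "inc_matrix.tsv"),
         samples = file.path(dir, "samples.tsv"),
         truth = file.path(dir, "truth.tsv"),
         beta = file.path(dir, "truth_beta.tsv"))
  write_meth_matrix(sim$Y_cpg, p[["cpg"]])
  write_meth_matrix(sim$Y_inc, p[["inc"]])
  sheet <- data.frame(sample_id = rownames(sim$Y_cpg),
                      group = as.integer(sim$design$X[, 1L]),
                      true_group = as.integer(sim$truth$true_labels),
                      stringsAsFactors = FALSE)
  utils::write.table(sheet, p[["samples"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # written directly so null datasets (no true positives) still get a file
  lab <- data.frame(feature_id = colnames(sim$Y_cpg),
                    label = ifelse(colnames(sim$Y_cpg) %in%
                                     sim$truth$true_positives,
                                   "positive", "negative"),
                    stringsAsFactors = FALSE)
  utils::write.table(lab, p[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tb <- data.frame(feature_id = colnames(sim$Y_cpg),
                   beta = as.numeric(sim$truth$beta),
                   noise_sd = as.numeric(sim$truth$noise_sd_cpg),
                   stringsAsFactors = FALSE)
  utils::write.table(tb, p[["beta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(p)
}
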