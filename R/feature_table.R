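#' Lipid feature table
#'
#' The container passed between all pipeline stages: a samples x lipids
#' matrix of relative concentrations plus aligned sample and lipid
#' metadata. Values are on the linear concentration scale unless
#' `log_flag` is set, in which case they are log2 concentrations.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample ids),
#'   lipids in columns (colnames = lipid ids). All values finite;
#'   non-negative when on the linear scale.
#' @param sample_meta Data frame with one row per sample: columns
#'   `sample_id`, `subject_id`, `group` (`"control"`/`"cancer"`, `NA` for
#'   QC), `cohort`, `batch`, `qc` (logical), `sample_type`
#'   (`"ev"`/`"plasma"`).
#' @param lipid_meta Data frame with one row per lipid: columns
#'   `lipid_id`, `lipid_class`, `annotation`, `mz`, `isomer_group` (see
#'   [build_lipid_schema()]).
#' @param log_flag Logical; `TRUE` when `values` hold log2 concentrations.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, sample_meta, lipid_meta, log_flag = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry sample rownames and lipid colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ",
         rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicate lipid id: ",
         colnames(values)[duplicated(colnames(values))][1])
  if (!all(is.finite(values)))
    stop("non-finite value at row ",
         rownames(values)[which(!is.finite(values), arr.ind = TRUE)[1, 1]])
  if (!log_flag && any(values < 0))
    stop("negative concentration on the linear scale")
  sample_meta <- as.data.frame(sample_meta)
  lipid_meta <- as.data.frame(lipid_meta)
  need_s <- c("sample_id", "subject_id", "group", "cohort", "batch", "qc",
              "sample_type")
  miss <- setdiff(need_s, names(sample_meta))
  if (length(miss)) stop("sample_meta missing column(s): ",
                         paste(miss, collapse = ", "))
  need_l <- c("lipid_id", "lipid_class", "annotation", "mz", "isomer_group")
  miss <- setdiff(need_l, names(lipid_meta))
  if (length(miss)) stop("lipid_meta missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!setequal(sample_meta$sample_id, rownames(values)) ||
      nrow(sample_meta) != nrow(values)) {
    bad <- setdiff(rownames(values), sample_meta$sample_id)
    stop("sample metadata does not match value rows",
         if (length(bad)) paste0("; no metadata for sample_id ", bad[1]))
  }
  if (!setequal(lipid_meta$lipid_id, colnames(values)) ||
      nrow(lipid_meta) != ncol(values)) {
    bad <- setdiff(colnames(values), lipid_meta$lipid_id)
    stop("lipid metadata does not match value columns",
         if (length(bad)) paste0("; no metadata for lipid_id ", bad[1]))
  }
  sample_meta <- sample_meta[match(rownames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  lipid_meta <- lipid_meta[match(colnames(values), lipid_meta$lipid_id), ,
                           drop = FALSE]
  rownames(lipid_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta,
                 lipid_meta = lipid_meta, log_flag = isTRUE(log_flag)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d samples x %d lipids (%s scale)\n",
    nrow(x$values), ncol(x$values), if (x$log_flag) "log2" else "linear"))
  grp <- table(x$sample_meta$group, useNA = "ifany")
  cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  cat("  qc samples:", sum(x$sample_meta$qc), "| batches:",
      length(unique(x$sample_meta$batch)), "\n")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Subset a feature table
#'
#' @param x A [feature_table()].
#' @param samples,lipids Indices, logical masks, or id character vectors.
#' @return A `feature_table` with metadata kept in step.
#' @export
ft_subset <- function(x, samples = NULL, lipids = NULL) {
  stopifnot(inherits(x, "feature_table"))
  v <- x$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(lipids)) v <- v[, lipids, drop = FALSE]
  feature_table(v,
                x$sample_meta[match(rownames(v), x$sample_meta$sample_id), ],
                x$lipid_meta[match(colnames(v), x$lipid_meta$lipid_id), ],
                log_flag = x$log_flag)
}

#' @rdname ft_subset
#' @details `ft_study()` returns the non-QC study samples — the
#'   modelling universe.
#' @export
ft_study <- function(x) ft_subset(x, samples = !x$sample_meta$qc)

#' Write / read a feature table as plain CSV
#'
#' Serializes to three CSV files: `<base>_values.csv` (first column
#' `sample_id`, remaining columns one per lipid), `<base>_samples.csv`
#' and `<base>_lipids.csv`. The round trip preserves values to full
#' double precision.
#'
#' @param x A [feature_table()].
#' @param base Path prefix for the three files.
#' @return `write_feature_table` returns `base` invisibly;
#'   `read_feature_table` returns a `feature_table`.
#' @export
write_feature_table <- function(x, base) {
  stopifnot(inherits(x, "feature_table"))
  dir.create(dirname(base), recursive = TRUE, showWarnings = FALSE)
  vals <- data.frame(sample_id = rownames(x$values), x$values,
                     check.names = FALSE)
  utils::write.csv(format_num_df(vals), paste0(base, "_values.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- x$sample_meta
  meta$log_flag <- x$log_flag
  utils::write.csv(meta, paste0(base, "_samples.csv"), row.names = FALSE)
  utils::write.csv(format_num_df(x$lipid_meta), paste0(base, "_lipids.csv"),
                   row.names = FALSE)
  invisible(base)
}

# full-precision decimal rendering for CSV round trips
format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(base) {
  fv <- paste0(base, "_values.csv")
  for (f in c(fv, paste0(base, "_samples.csv"), paste0(base, "_lipids.csv")))
    if (!file.exists(f)) stop("missing file: ", f)
  vals <- utils::read.csv(fv, check.names = FALSE)
  if (names(vals)[1] != "sample_id")
    stop("first column of ", fv, " must be sample_id")
  for (j in seq(2L, ncol(vals))) {
    if (!is.numeric(vals[[j]]))
      stop("non-numeric cell in lipid column '", names(vals)[j], "'")
  }
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$sample_id
  smeta <- utils::read.csv(paste0(base, "_samples.csv"))
  lmeta <- utils::read.csv(paste0(base, "_lipids.csv"))
  log_flag <- isTRUE(all(smeta$log_flag))
  smeta$log_flag <- NULL
  smeta$qc <- as.logical(smeta$qc)
  feature_table(m, smeta, lmeta, log_flag = log_flag)
}
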