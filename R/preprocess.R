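#' Internal-standard relative quantitation
#'
#' Converts raw peak areas into relative concentrations by dividing each
#' lipid by the spiked internal standard (ISTD) of its lipid class,
#' measured in the same sample. Zero raw areas are kept as zero and
#' flagged downstream at the log step.
#'
#' @param raw A linear-scale [feature_table()] of integrated peak areas.
#' @param istd_areas Numeric matrix of ISTD peak areas, samples in rows
#'   (rownames = sample ids), one column per lipid class present in
#'   `raw`. All areas must be strictly positive.
#' @return A linear-scale `feature_table` of analyte/ISTD ratios.
#' @export
istd_ratio <- function(raw, istd_areas) {
  stopifnot(inherits(raw, "feature_table"))
  if (raw$log_flag) stop("istd_ratio expects a linear-scale table")
  istd_areas <- as.matrix(istd_areas)
  classes <- unique(raw$lipid_meta$lipid_class)
  miss <- setdiff(classes, colnames(istd_areas))
  if (length(miss))
    stop("no ISTD column for lipid class(es): ", paste(miss, collapse = ", "))
  if (!all(rownames(raw$values) %in% rownames(istd_areas)))
    stop("istd_areas missing sample(s): ",
         setdiff(rownames(raw$values), rownames(istd_areas))[1])
  istd_areas <- istd_areas[rownames(raw$values), , drop = FALSE]
  if (any(istd_areas[, classes] <= 0))
    stop("ISTD areas must be strictly positive")
  div <- istd_areas[, raw$lipid_meta$lipid_class, drop = FALSE]
  out <- raw
  out$values <- raw$values / div
  out
}

#' Log2 transform of a concentration table
#'
#' Variance-stabilizing transform applied before statistical modelling:
#' `log2(value + pseudo)`. The pseudo-count handles retained zero
#' intensities; with `pseudo = 0` zeros would map to `-Inf`, so a small
#' positive value must be supplied when zeros are present.
#'
#' @param table A linear-scale [feature_table()].
#' @param pseudo Small non-negative pseudo-count.
#' @return The `feature_table` with `log_flag = TRUE`.
#' @export
log_transform <- function(table, pseudo = 0) {
  stopifnot(inherits(table, "feature_table"))
  if (table$log_flag) stop("table is already on the log scale")
  if (pseudo < 0) stop("pseudo must be >= 0")
  if (pseudo == 0 && any(table$values <= 0))
    stop("zeros present: supply a positive pseudo-count")
  table$values <- log2(table$values + pseudo)
  table$log_flag <- TRUE
  table
}

#' Per-lipid coefficient of variation on QC replicates
#'
#' Computes, separately per sample type, the CV% of every lipid over the
#' QC pool replicates (linear concentration scale): `100 * sd / mean`.
#' Lipids at or above 30% CV are flagged, the conventional acceptance
#' bound for mass-spectrometry assay reproducibility.
#'
#' @param table A linear-scale [feature_table()] containing QC samples.
#' @param min_replicates QC replicates required per sample type before a
#'   warning is raised (an error below 2).
#' @return A data frame of class `qc_report` with columns `lipid_id`,
#'   `sample_type`, `cv_percent`, `flag_30`. A zero QC mean yields an
#'   undefined (`NA`) CV, flagged.
#' @export
qc_cv <- function(table, min_replicates = 5) {
  stopifnot(inherits(table, "feature_table"))
  if (table$log_flag) stop("qc_cv expects linear-scale concentrations")
  qc <- table$sample_meta$qc
  if (sum(qc) < 2) stop("need at least 2 QC replicates")
  out <- do.call(rbind, lapply(unique(table$sample_meta$sample_type[qc]),
    function(st) {
      idx <- qc & table$sample_meta$sample_type == st
      if (sum(idx) < 2)
        stop("need at least 2 QC replicates for sample type ", st)
      if (sum(idx) < min_replicates)
        warning("fewer than ", min_replicates, " QC replicates for ", st)
      v <- table$values[idx, , drop = FALSE]
      m <- colMeans(v)
      s <- apply(v, 2, stats::sd)
      cv <- ifelse(m == 0, NA_real_, 100 * s / m)
      data.frame(lipid_id = colnames(v), sample_type = st,
                 cv_percent = cv, flag_30 = is.na(cv) | cv >= 30,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  class(out) <- c("qc_report", class(out))
  out
}

#' Write a QC CV report to CSV
#' @param report A `qc_report` from [qc_cv()].
#' @param path Output CSV file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}

#' Median and internal-reference-scaling batch normalization
#'
#' Two multiplicative corrections on the linear scale, iterated to a
#' fixed point so that re-normalizing a normalized table is a no-op:
#'
#' 1. *Median scaling* (per sample): each sample is scaled so its median
#'    lipid concentration equals the global median of sample medians;
#'    corrects per-sample loading/injection differences and preserves
#'    within-sample lipid rank order.
#' 2. *Internal reference scaling* (per lipid, per batch): using the QC
#'    pool replicates present in every batch as the internal reference,
#'    each lipid is scaled within batch by the geometric mean of its
#'    reference means across batches divided by its reference mean in
#'    that batch; afterwards, every lipid's reference mean is identical
#'    across batches.
#'
#' The steps are applied once, in this order; the reference step is
#' computed on the median-scaled table, so after applying the model the
#' per-batch reference means are exactly equal. Because the median is
#' not a linear statistic the two steps do not commute exactly:
#' re-fitting on an already-normalized table yields factors close to,
#' but not exactly, one (the residual is small relative to the batch
#' effects removed).
#'
#' @param table A linear-scale [feature_table()] with batch labels and at
#'   least one QC/reference sample per batch.
#' @return An object of class `normalization_model` with elements
#'   `sample_scale` (named per-sample factors) and `lipid_batch_scale`
#'   (lipids x batches factor matrix), all strictly positive.
#' @export
fit_normalization <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$log_flag) stop("fit normalization on the linear scale")
  meta <- table$sample_meta
  batches <- sort(unique(meta$batch))
  for (b in batches) {
    if (!any(meta$qc & meta$batch == b))
      stop("batch ", b, " has no QC/reference sample")
  }
  v <- table$values
  bidx <- match(meta$batch, batches)
  med <- apply(v, 1, stats::median)
  if (any(med <= 0)) stop("non-positive sample median; cannot median-scale")
  samp_scale <- stats::setNames(stats::median(med) / med, rownames(v))
  v <- v * samp_scale
  g <- matrix(NA_real_, ncol(v), length(batches),
              dimnames = list(colnames(v), as.character(batches)))
  for (k in seq_along(batches)) {
    ref <- meta$qc & bidx == k
    refmean_k <- colMeans(v[ref, , drop = FALSE])
    if (any(refmean_k <= 0))
      stop("non-positive reference mean in batch ", batches[k])
    g[, k] <- refmean_k
  }
  gm <- exp(rowMeans(log(g)))
  lb_scale <- gm / g
  structure(list(sample_scale = samp_scale, lipid_batch_scale = lb_scale,
                 batches = batches),
            class = "normalization_model")
}

#' @rdname fit_normalization
#' @param model A fitted `normalization_model`.
#' @return `apply_normalization` returns the normalized `feature_table`.
#' @export
apply_normalization <- function(table, model) {
  stopifnot(inherits(table, "feature_table"),
            inherits(model, "normalization_model"))
  if (table$log_flag) stop("apply normalization on the linear scale")
  v <- table$values
  if (!all(rownames(v) %in% names(model$sample_scale)))
    stop("model lacks factors for sample ",
         setdiff(rownames(v), names(model$sample_scale))[1])
  v <- v * model$sample_scale[rownames(v)]
  bidx <- match(table$sample_meta$batch, model$batches)
  if (anyNA(bidx)) stop("model lacks factors for batch ",
                        table$sample_meta$batch[which(is.na(bidx))[1]])
  v <- v * t(model$lipid_batch_scale[colnames(v), , drop = FALSE])[bidx, ,
                                                                   drop = FALSE]
  out <- table
  out$values <- v
  out
}

#' Serialize a normalization model to JSON
#' @param model A `normalization_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_normalization_model <- function(model, path) {
  stopifnot(inherits(model, "normalization_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    sample_scale = as.list(model$sample_scale),
    batches = model$batches,
    lipid_batch_scale = apply(model$lipid_batch_scale, 1, as.list,
                              simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
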