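#' Render the pipeline summary report
#'
#' Collects the artifacts of a pipeline output directory into one
#' markdown document with embedded CSV-style tables: QC reproducibility,
#' normalization, the differential-abundance panel with its confusion
#' matrix (index test rows x reference test columns), the
#' selection-frequency top list with the signature cutoff marked, final
#' ensemble performance with the certainty breakdown, and the
#' signature-size sensitivity summary. Stages whose artifacts are
#' absent get an explicit "missing stage" section rather than failing.
#'
#' @param output_dir Directory holding pipeline artifacts.
#' @param path Output markdown file.
#' @param signature_size Cutoff marked in the selection-frequency list.
#' @param top_n Length of the selection-frequency list shown.
#' @return `path`, invisibly.
#' @export
render_report <- function(output_dir, path = file.path(output_dir,
                                                       "report.md"),
                          signature_size = 20, top_n = 30) {
  L <- character(0)
  add <- function(...) L <<- c(L, ...)
  has <- function(f) file.exists(file.path(output_dir, f))
  rd <- function(f) utils::read.csv(file.path(output_dir, f))
  md_table <- function(df, digits = 3) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                      " |")))
  }
  add("# Lipid biomarker discovery report", "")

  add("## 1. Quality control")
  if (has("qc_report.csv")) {
    qc <- rd("qc_report.csv")
    agg <- do.call(rbind, lapply(split(qc, qc$sample_type), function(d)
      data.frame(sample_type = d$sample_type[1],
                 median_cv_percent = stats::median(d$cv_percent,
                                                   na.rm = TRUE),
                 n_flagged_over_30 = sum(d$flag_30))))
    add("", md_table(agg), "")
  } else add("", "*missing stage: preprocess*", "")

  add("## 2. Batch normalization")
  if (has("ev_normalization.json")) {
    add("", "Median + internal reference scaling factors fitted per",
        "sample and per (lipid, batch); see `*_normalization.json`.", "")
  } else add("", "*missing stage: preprocess*", "")

  add("## 3. Differential-abundance panel")
  if (has("da_panel.csv")) {
    panel <- rd("da_panel.csv")
    add("", sprintf("Panel of %d lipids (%d direct, %d isomer-included).",
                    nrow(panel), sum(panel$da_selected),
                    sum(panel$isomer_included)), "")
    if (has("da_loocv.json")) {
      cv <- jsonlite::read_json(file.path(output_dir, "da_loocv.json"),
                                simplifyVector = TRUE)
      add(sprintf(
        "LOOCV logistic model: accuracy %.2f, sensitivity %.2f, specificity %.2f, AUC %.3f (threshold %.3f).",
        cv$accuracy, cv$sensitivity, cv$specificity, cv$auc,
        cv$threshold), "")
      cm <- cv$confusion
      add("Confusion matrix (index test rows, reference test columns):", "",
          "| | reference cancer | reference control |",
          "|---|---|---|",
          sprintf("| index cancer | %d | %d |", cm$TP, cm$FP),
          sprintf("| index control | %d | %d |", cm$FN, cm$TN), "")
    }
  } else add("", "*missing stage: discover_da*", "")

  add("## 4. Selection-frequency ranking")
  if (has("selection_frequency.csv")) {
    freq <- rd("selection_frequency.csv")
    show <- utils::head(freq[, c("lipid_id", "selections", "proportion",
                                 "rank")], top_n)
    show$in_signature <- ifelse(show$rank <= signature_size, "*", "")
    add("", sprintf(
      "Top %d lipids by Boruta selection frequency; `*` marks the top-%d signature cutoff.",
      nrow(show), signature_size), "", md_table(show), "")
  } else add("", "*missing stage: discover_ml*", "")

  add("## 5. Final ensemble performance")
  if (has("final_performance.json")) {
    perf <- jsonlite::read_json(file.path(output_dir,
                                          "final_performance.json"),
                                simplifyVector = TRUE)
    add("", sprintf(
      "Ensemble (majority vote): accuracy %.1f +/- %.1f%%, sensitivity %.1f +/- %.1f%%, specificity %.1f +/- %.1f%%, mean AUC %.3f.",
      100 * perf$metrics_mean$accuracy, 100 * perf$metrics_sd$accuracy,
      100 * perf$metrics_mean$sensitivity,
      100 * perf$metrics_sd$sensitivity,
      100 * perf$metrics_mean$specificity,
      100 * perf$metrics_sd$specificity, perf$mean_auc), "",
      "Prediction certainty (model agreement) by outcome:", "",
      md_table(perf$certainty_breakdown), "")
  } else add("", "*missing stage: finalize*", "")

  add("## 6. Signature-size sensitivity and panel overlap")
  if (has("sensitivity.csv")) {
    sens <- rd("sensitivity.csv")
    add("", md_table(sens), "")
  } else add("", "*missing stage: finalize (sensitivity)*", "")
  if (has("panel_overlap.csv")) {
    add(md_table(rd("panel_overlap.csv")), "")
  } else add("*missing stage: compare*", "")

  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(L, path)
  invisible(path)
}
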