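#' Run pipeline stages
#'
#' Executes the pipeline stages in order, writing every artifact into
#' `config$output_dir` and appending to the run manifest. Stages:
#'
#' * `simulate` — synthetic matched EV/plasma cohort + planted truth;
#' * `preprocess` — QC CV report, batch normalization, log2 transform;
#' * `discover_da` — differential abundance, FC/FDR panel with isomer
#'   inclusion and stepwise m/z restriction, LOOCV logistic evaluation,
#'   per-subject EV/plasma correlation;
#' * `discover_ml` — repeated LGOCV with in-fold Boruta and nested
#'   tuning; selection-frequency ranking;
#' * `finalize` — fixed-signature final ensemble evaluation plus
#'   signature-size sensitivity analysis;
#' * `compare` — overlap of the DA panel and the ML signature;
#' * `report` — human-readable markdown summary.
#'
#' Later stages read the artifacts of earlier ones from the output
#' directory, so stages can be run one at a time (e.g. from the command
#' line); a missing upstream artifact raises a dependency error.
#'
#' @param config A [pipeline_config()] (or list / file path coercible to
#'   one).
#' @param stages Character vector of stages to run, in order.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "preprocess",
                                    "discover_da", "discover_ml",
                                    "finalize", "compare", "report")) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (st in stages) {
    switch(st,
           simulate = stage_simulate(cfg),
           preprocess = stage_preprocess(cfg),
           discover_da = stage_discover_da(cfg),
           discover_ml = stage_discover_ml(cfg),
           finalize = stage_finalize(cfg),
           compare = stage_compare(cfg),
           report = stage_report(cfg))
  }
  invisible(cfg$output_dir)
}

out_file <- function(cfg, ...) file.path(cfg$output_dir, ...)

need_artifact <- function(cfg, file, stage) {
  path <- out_file(cfg, file)
  if (!file.exists(path))
    stop("missing upstream artifact '", file, "' required by stage '",
         stage, "'; run the earlier stages first")
  path
}

stage_simulate <- function(cfg) {
  gen <- do.call(generator_config,
                 c(cfg$generator,
                   list(seed = substream_seed(cfg$seed, "generator"))))
  sim <- simulate_matched_pair(gen)
  write_feature_table(sim$ev, out_file(cfg, "ev"))
  write_feature_table(sim$plasma, out_file(cfg, "plasma"))
  write_truth(sim$truth, out_file(cfg, "truth.json"))
  manifest_append(cfg, "simulate",
                  c(out_file(cfg, "ev_values.csv"),
                    out_file(cfg, "plasma_values.csv"),
                    out_file(cfg, "truth.json")))
}

load_raw_tables <- function(cfg, stage) {
  base <- cfg$input_base
  if (!is.null(base)) {
    list(ev = read_feature_table(paste0(base, "_ev")),
         plasma = read_feature_table(paste0(base, "_plasma")))
  } else {
    need_artifact(cfg, "ev_values.csv", stage)
    list(ev = read_feature_table(out_file(cfg, "ev")),
         plasma = read_feature_table(out_file(cfg, "plasma")))
  }
}

stage_preprocess <- function(cfg) {
  tabs <- load_raw_tables(cfg, "preprocess")
  qc <- rbind(qc_cv(tabs$ev), qc_cv(tabs$plasma))
  write_qc_report(qc, out_file(cfg, "qc_report.csv"))
  files <- out_file(cfg, "qc_report.csv")
  for (nm in c("ev", "plasma")) {
    tab <- tabs[[nm]]
    if (isTRUE(cfg$preprocess$normalize)) {
      model <- fit_normalization(tab)
      tab <- apply_normalization(tab, model)
      write_normalization_model(
        model, out_file(cfg, paste0(nm, "_normalization.json")))
      files <- c(files, out_file(cfg, paste0(nm, "_normalization.json")))
    }
    tab <- log_transform(tab, pseudo = cfg$preprocess$pseudo)
    write_feature_table(tab, out_file(cfg, paste0(nm, "_log2")))
    files <- c(files, out_file(cfg, paste0(nm, "_log2_values.csv")))
  }
  manifest_append(cfg, "preprocess", files)
}

stage_discover_da <- function(cfg) {
  need_artifact(cfg, "ev_log2_values.csv", "discover_da")
  ev <- read_feature_table(out_file(cfg, "ev_log2"))
  plasma <- read_feature_table(out_file(cfg, "plasma_log2"))
  da <- da_test(ev, blocking = cfg$da_panel$blocking)
  utils::write.csv(da, out_file(cfg, "da_results.csv"), row.names = FALSE)
  panel <- select_panel(da, ev$lipid_meta, fc_min = cfg$da_panel$fc_min,
                        q_max = cfg$da_panel$q_max)
  if (nrow(panel) > 0 && isTRUE(cfg$da_panel$stepwise))
    panel <- stepwise_restrict(ev, panel)
  utils::write.csv(panel, out_file(cfg, "da_panel.csv"), row.names = FALSE)
  files <- out_file(cfg, c("da_results.csv", "da_panel.csv"))
  if (nrow(panel) > 0 && nrow(panel) < nrow(ft_study(ev)$values) - 1) {
    cv <- loocv_logistic(ev, panel)
    jsonlite::write_json(list(
      threshold = cv$threshold, accuracy = cv$accuracy,
      sensitivity = unname(cv$sensitivity),
      specificity = unname(cv$specificity),
      auc = cv$auc, confusion = as.list(cv$confusion),
      scores = as.list(cv$scores)),
      out_file(cfg, "da_loocv.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    utils::write.csv(cv$roc, out_file(cfg, "da_roc.csv"), row.names = FALSE)
    files <- c(files, out_file(cfg, c("da_loocv.json", "da_roc.csv")))
  }
  if (nrow(panel) >= 3) {
    sc <- subject_correlation(ev, plasma, panel)
    utils::write.csv(sc$per_subject,
                     out_file(cfg, "subject_correlation.csv"),
                     row.names = FALSE)
    files <- c(files, out_file(cfg, "subject_correlation.csv"))
  }
  manifest_append(cfg, "discover_da", files)
}

ml_components <- function(cfg) {
  list(
    classifiers = default_classifiers(cfg$classifiers),
    boruta = boruta_config(
      n_iter = cfg$boruta$n_iter, n_trees = cfg$boruta$n_trees,
      alpha = cfg$boruta$alpha,
      importance_kind = cfg$boruta$importance_kind,
      mtry = cfg$boruta$mtry, max_depth = cfg$boruta$max_depth))
}

stage_discover_ml <- function(cfg) {
  need_artifact(cfg, "ev_log2_values.csv", "discover_ml")
  ev <- read_feature_table(out_file(cfg, "ev_log2"))
  comp <- ml_components(cfg)
  y <- ft_study(ev)$sample_meta$group
  plan <- make_splits(y, n_iter = cfg$splits$n_iter,
                      test_fraction = cfg$splits$test_fraction,
                      stratified = cfg$splits$stratified,
                      seed = substream_seed(cfg$seed, "discovery_splits"))
  records <- discovery_run(ev, classifiers = comp$classifiers,
                           boruta_cfg = comp$boruta, plan = plan,
                           tune_len = cfg$tuning$tune_len,
                           n_nested = cfg$tuning$n_nested)
  write_iteration_records(records, out_file(cfg, "discovery_records.ndjson"))
  freq <- selection_frequency(records)
  utils::write.csv(freq, out_file(cfg, "selection_frequency.csv"),
                   row.names = FALSE)
  params <- lapply(stats::setNames(nm = names(comp$classifiers)),
                   function(m) pick_final_hyperparams(records, m))
  jsonlite::write_json(params, out_file(cfg, "final_hyperparams.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # per-sample per-model average prediction matrix across iterations
  avg <- average_prediction_matrix(records, ft_study(ev))
  utils::write.csv(avg, out_file(cfg, "average_predictions.csv"),
                   row.names = FALSE)
  manifest_append(cfg, "discover_ml",
                  out_file(cfg, c("discovery_records.ndjson",
                                  "selection_frequency.csv",
                                  "final_hyperparams.json",
                                  "average_predictions.csv")))
}

average_prediction_matrix <- function(records, tab) {
  ids <- tab$sample_meta$sample_id
  first <- records[[which(vapply(records, function(r)
    !is.null(r$probs), logical(1)))[1]]]
  models <- rownames(first$probs)
  s <- matrix(0, length(ids), length(models),
              dimnames = list(ids, models))
  cnt <- matrix(0L, length(ids), length(models))
  for (r in records) {
    if (is.null(r$probs)) next
    cols <- colnames(r$probs)
    s[cols, ] <- s[cols, ] + t(r$probs)
    cnt[match(cols, ids), ] <- cnt[match(cols, ids), ] + 1L
  }
  avg <- ifelse(cnt > 0, s / cnt, NA_real_)
  data.frame(sample_id = ids, group = tab$sample_meta$group, avg,
             check.names = FALSE)
}

stage_finalize <- function(cfg) {
  need_artifact(cfg, "selection_frequency.csv", "finalize")
  ev <- read_feature_table(out_file(cfg, "ev_log2"))
  freq <- utils::read.csv(out_file(cfg, "selection_frequency.csv"))
  params <- jsonlite::read_json(
    need_artifact(cfg, "final_hyperparams.json", "finalize"),
    simplifyVector = TRUE)
  params <- lapply(params, as.list)
  comp <- ml_components(cfg)
  k <- min(cfg$signature_size, sum(freq$selections > 0))
  if (k < 1) stop("no lipid was ever selected; cannot build a signature")
  signature <- freq$lipid_id[seq_len(k)]
  y <- ft_study(ev)$sample_meta$group
  plan <- make_splits(y, n_iter = cfg$splits$n_iter,
                      test_fraction = cfg$splits$test_fraction,
                      stratified = cfg$splits$stratified,
                      seed = substream_seed(cfg$seed, "final_splits"))
  perf <- final_evaluation(ev, signature = signature,
                           classifiers = comp$classifiers,
                           fixed_params = params, plan = plan)
  write_performance_summary(perf, out_file(cfg, "final_performance"))
  files <- out_file(cfg, c("final_performance.json",
                           "final_performance_roc.csv"))
  sizes <- cfg$sensitivity_sizes[cfg$sensitivity_sizes <=
                                   sum(freq$selections > 0)]
  if (length(sizes) >= 1) {
    sens <- sensitivity_analysis(ev, ranked_lipids = freq$lipid_id,
                                 sizes = sizes,
                                 classifiers = comp$classifiers,
                                 fixed_params = params, plan = plan)
    utils::write.csv(cbind(sens$summary, chosen_k = sens$chosen_k),
                     out_file(cfg, "sensitivity.csv"), row.names = FALSE)
    files <- c(files, out_file(cfg, "sensitivity.csv"))
  }
  manifest_append(cfg, "finalize", files)
}

#' Serialize a performance summary (JSON + ROC CSV)
#' @param perf A `performance_summary`.
#' @param base Output path prefix.
#' @return `base`, invisibly.
#' @export
write_performance_summary <- function(perf, base) {
  stopifnot(inherits(perf, "performance_summary"))
  dir.create(dirname(base), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    metrics_mean = as.list(perf$metrics_mean),
    metrics_sd = as.list(perf$metrics_sd),
    mean_auc = perf$mean_auc,
    certainty_breakdown = perf$certainty_breakdown,
    model_mean_metrics = as.data.frame(perf$model_mean_metrics),
    signature = perf$signature),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(perf$roc, paste0(base, "_roc.csv"), row.names = FALSE)
  invisible(base)
}

stage_compare <- function(cfg) {
  need_artifact(cfg, "da_panel.csv", "compare")
  need_artifact(cfg, "selection_frequency.csv", "compare")
  da_panel <- utils::read.csv(out_file(cfg, "da_panel.csv"))
  freq <- utils::read.csv(out_file(cfg, "selection_frequency.csv"))
  k <- min(cfg$signature_size, sum(freq$selections > 0))
  panels <- list(da_panel = da_panel$lipid_id,
                 ml_signature = freq$lipid_id[seq_len(k)])
  ov <- compare_panels(panels)
  utils::write.csv(ov, out_file(cfg, "panel_overlap.csv"),
                   row.names = FALSE)
  manifest_append(cfg, "compare", out_file(cfg, "panel_overlap.csv"))
}

stage_report <- function(cfg) {
  path <- render_report(cfg$output_dir,
                        out_file(cfg, "report.md"),
                        signature_size = cfg$signature_size)
  manifest_append(cfg, "report", path)
}
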