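# Shared fixtures, built in code at test time.

# small two-group cohort with a clear planted signal
tiny_config <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(n_control = 30, n_cancer = 30, n_lipids = 50, n_classes = 5,
         n_informative = 5, effect_log2fc = 1.5, within_class_corr = 0.2,
         sigma_bio = 1, sigma_tech_plasma = 0.1, sigma_tech_ev = 0.25,
         n_batches = 2, batch_sd = 0.2, n_qc_replicates_per_batch = 3,
         isomer_rate = 0, seed = seed),
    list(...))
  do.call(generator_config, args)
}

# log2 study table + truth for the tiny cohort
tiny_cohort <- function(seed = 3, ...) {
  sim <- simulate_cohort(tiny_config(seed, ...))
  list(log2 = log_transform(sim$table), truth = sim$truth)
}

# quick Boruta profile for small fixtures
fast_boruta <- function(seed = 1, n_iter = 20, n_trees = 40, mtry = 30,
                        ...) {
  boruta_config(n_iter = n_iter, n_trees = n_trees, mtry = mtry,
                max_depth = 4, importance_kind = "impurity", seed = seed,
                ...)
}

# hand-built feature table: values matrix + minimal metadata
mini_table <- function(values, group = NULL, batch = 1, qc = NULL,
                       sample_type = "ev", mz = NULL, lipid_class = NULL,
                       isomer_group = NULL, log_flag = FALSE,
                       subject_id = NULL) {
  n <- nrow(values); p <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("S%02d", 1:n)
  if (is.null(colnames(values))) colnames(values) <- sprintf("L%02d", 1:p)
  if (is.null(qc)) qc <- rep(FALSE, n)
  if (is.null(group)) group <- rep(c("control", "cancer"), length.out = n)
  group[qc] <- NA
  smeta <- data.frame(
    sample_id = rownames(values),
    subject_id = subject_id %||% rownames(values),
    group = group, cohort = "C1",
    batch = rep(batch, length.out = n), qc = qc,
    sample_type = rep(sample_type, length.out = n))
  lmeta <- data.frame(
    lipid_id = colnames(values),
    lipid_class = lipid_class %||% rep("PC", p),
    annotation = paste0("PC 34:", seq_len(p)),
    mz = mz %||% (700 + seq_len(p)),
    isomer_group = isomer_group %||% paste0("IG", seq_len(p)))
  feature_table(values, smeta, lmeta, log_flag = log_flag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a fixed RNG state
with_rng_test <- function(seed, expr) {
  set.seed(seed)
  expr
}
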