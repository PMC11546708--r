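#' Repeated leave-group-out split plan
#'
#' Draws `n_iter` independent random train/test partitions of the
#' non-QC samples, each holding out `round(test_fraction * n)` samples.
#' With `stratified = TRUE` (default) the held-out set preserves the
#' class proportions to within one sample.
#'
#' @param labels Class labels of the samples to split.
#' @param n_iter Number of iterations (reference protocol: 2000).
#' @param test_fraction Held-out fraction (reference protocol: 0.2).
#' @param stratified Stratify the test set by class.
#' @param seed Integer seed; the plan is reproducible.
#' @return A list of class `split_plan` with elements `splits` (each a
#'   list of integer `train` / `test` indices), `n_iter`,
#'   `test_fraction`, `stratified`, `seed`, `n`.
#' @export
make_splits <- function(labels, n_iter = 2000, test_fraction = 0.2,
                        stratified = TRUE, seed = 1) {
  n <- length(labels)
  if (n < 10) stop("need at least 10 samples")
  if (min(table(labels)) < 2) stop("each class needs >= 2 samples")
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n)
    stop("test_fraction yields an empty test or train set")
  cls <- unique(labels)
  # per-class test counts: floor of the proportional share, remainder
  # assigned by largest fractional part (deterministic order)
  share <- n_test * table(factor(labels, levels = cls)) / n
  base <- floor(share)
  rem <- n_test - sum(base)
  if (rem > 0) {
    ord <- order(-(share - base), seq_along(cls))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  splits <- with_rng(seed, {
    lapply(seq_len(n_iter), function(i) {
      test <- if (stratified) {
        unlist(lapply(seq_along(cls), function(k) {
          idx <- which(labels == cls[k])
          sample(idx, base[k])
        }), use.names = FALSE)
      } else sample.int(n, n_test)
      test <- sort(test)
      list(train = setdiff(seq_len(n), test), test = test)
    })
  })
  structure(list(splits = splits, n_iter = n_iter,
                 test_fraction = test_fraction, stratified = stratified,
                 seed = seed, n = n), class = "split_plan")
}

# standardize by train statistics, fit, predict held-out probabilities
fit_predict <- function(spec, params, Xtr, ytr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0] <- 1
  Xtr <- scale(Xtr, mu, sd)
  Xte <- scale(Xte, mu, sd)
  model <- spec$fit(Xtr, ytr, params)
  pr <- spec$predict(model, Xte)
  pmin(pmax(as.numeric(pr), 0), 1)
}

#' Random-search hyperparameter tuning over nested LGOCV
#'
#' Draws `tune_len` hyperparameter candidates from the classifier's
#' space and scores each by its mean accuracy (0.5 vote threshold) over
#' `n_nested` stratified 80/20 splits of the training set. All
#' candidates see the same nested splits. Ties go to the first-drawn
#' candidate. The winning configuration is returned for refitting on
#' the full training set. With a single candidate no nested fits are
#' run.
#'
#' @param X Training design matrix (samples x features).
#' @param y Integer 0/1 training labels.
#' @param spec A [classifier_spec()].
#' @param n_nested Nested split count (reference protocol: 50).
#' @param tune_len Candidates drawn (reference protocol: 10).
#' @return A list: `params` (best candidate), `mean_acc` (per-candidate
#'   nested accuracies, `NA` when tuning was skipped).
#' @export
nested_tune <- function(X, y, spec, n_nested = 50, tune_len = 10) {
  cands <- spec$sample_params(tune_len)
  cands <- cands[!vapply(cands, is.null, logical(1))]
  if (length(cands) == 0) stop("classifier space yielded no candidate")
  cands <- cands[!duplicated(vapply(cands, function(p)
    paste(deparse(p), collapse = ""), character(1)))]
  if (length(cands) == 1L)
    return(list(params = cands[[1]], mean_acc = NA_real_))
  plan <- make_splits(y, n_iter = n_nested, test_fraction = 0.2,
                      stratified = TRUE,
                      seed = sample.int(.Machine$integer.max, 1))
  acc <- vapply(cands, function(par) {
    mean(vapply(plan$splits, function(s) {
      pr <- fit_predict(spec, par, X[s$train, , drop = FALSE], y[s$train],
                        X[s$test, , drop = FALSE])
      mean((pr >= 0.5) == y[s$test])
    }, numeric(1)))
  }, numeric(1))
  list(params = cands[[which.max(acc)]], mean_acc = acc)
}

#' Majority vote, vote fraction and certainty of an ensemble
#'
#' `ensemble_vote` labels a sample cancer when cancer votes are at least
#' as many as control votes (ties go to cancer, the clinically
#' conservative direction). `ensemble_score` is the fraction of cancer
#' votes, the ensemble's continuous score. `certainty` bins the
#' agreement (majority share): `high` = complete agreement, `medium` =
#' at least 80%, `low` otherwise.
#'
#' @param votes Binary vector, one vote per model (1 = cancer).
#' @return `ensemble_vote`: 0/1 label; `ensemble_score`: fraction in
#'   `[0, 1]`; `certainty`: one of `"high"`, `"medium"`, `"low"`.
#' @export
ensemble_vote <- function(votes) {
  stopifnot(length(votes) >= 1)
  as.integer(mean(votes) >= 0.5)
}

#' @rdname ensemble_vote
#' @export
ensemble_score <- function(votes) {
  stopifnot(length(votes) >= 1)
  mean(votes)
}

#' @rdname ensemble_vote
#' @export
certainty <- function(votes) {
  stopifnot(length(votes) >= 1)
  agreement <- max(mean(votes), 1 - mean(votes))
  if (agreement == 1) "high" else if (agreement >= 0.8) "medium" else "low"
}

binary_metrics <- function(pred, y) {
  c(accuracy = mean(pred == y),
    sensitivity = if (any(y == 1)) mean(pred[y == 1] == 1) else NA_real_,
    specificity = if (any(y == 0)) mean(pred[y == 0] == 0) else NA_real_)
}

#' Discovery engine: repeated LGOCV with in-fold feature selection
#'
#' For every iteration of the split plan: run Boruta on the training
#' split only; tune each classifier by nested random search on the
#' training split restricted to the confirmed lipids; refit on the full
#' training split; evaluate the individual models and the majority-vote
#' ensemble on the held-out split. Nothing derived from a test sample
#' ever enters selection, tuning or fitting; every record stores the
#' sample ids its selection consumed so the audit can verify this.
#'
#' When Boruta confirms nothing in an iteration, the iteration falls
#' back to all features and is flagged (`fallback = TRUE`).
#'
#' With `classifiers = list()` the engine records feature selections
#' only — the cheap mode for selection-frequency stability studies.
#'
#' @param table A log2-scale [feature_table()] (QC samples ignored).
#' @param labels Optional labels; defaults to group metadata.
#' @param classifiers Named list of [classifier_spec()]s.
#' @param boruta_cfg A [boruta_config()]; its seed is re-derived per
#'   iteration.
#' @param plan A [make_splits()] plan over the non-QC samples.
#' @param tune_len,n_nested Passed to [nested_tune()].
#' @return A list of class `iteration_records`; each element holds
#'   `iteration`, `train`, `test`, `selected`, `fallback`,
#'   `selected_importance`, `consumed_ids`, and (with classifiers)
#'   per-model `params`, `probs`, metrics, and the ensemble's
#'   `vote_fraction`, metrics and per-sample certainty.
#' @export
discovery_run <- function(table, labels = NULL,
                          classifiers = default_classifiers(),
                          boruta_cfg = boruta_config(), plan,
                          tune_len = 10, n_nested = 50) {
  stopifnot(inherits(table, "feature_table"), inherits(plan, "split_plan"))
  tab <- ft_study(table)
  y <- binary_labels(labels %||% tab$sample_meta$group)
  if (plan$n != length(y)) stop("split plan does not match sample count")
  X <- tab$values
  records <- vector("list", plan$n_iter)
  for (i in seq_len(plan$n_iter)) {
    s <- plan$splits[[i]]
    Xtr <- X[s$train, , drop = FALSE]
    ytr <- y[s$train]
    cfg_i <- boruta_cfg
    cfg_i$seed <- substream_seed(plan$seed, sprintf("boruta_%d", i))
    br <- boruta_run(Xtr, ytr, cfg_i)
    fallback <- length(br$selected) == 0
    feats <- if (fallback) colnames(X) else br$selected
    rec <- list(iteration = i, train = s$train, test = s$test,
                selected = br$selected, fallback = fallback,
                selected_importance = br$mean_importance[br$selected],
                consumed_ids = rownames(Xtr),
                all_features = colnames(X))
    if (length(classifiers)) {
      rec <- c(rec, eval_models_on_split(
        X, y, s, feats, classifiers, tune_len, n_nested,
        seed = substream_seed(plan$seed, sprintf("models_%d", i)),
        fixed_params = NULL))
    }
    records[[i]] <- rec
  }
  structure(records, class = "iteration_records",
            n_iter = plan$n_iter, labels = y)
}

# Tune (or take fixed), fit and evaluate all classifiers on one split.
eval_models_on_split <- function(X, y, s, feats, classifiers, tune_len,
                                 n_nested, seed, fixed_params = NULL) {
  Xtr <- X[s$train, feats, drop = FALSE]
  Xte <- X[s$test, feats, drop = FALSE]
  ytr <- y[s$train]
  yte <- y[s$test]
  nm <- names(classifiers)
  probs <- matrix(NA_real_, length(nm), length(s$test),
                  dimnames = list(nm, rownames(Xte)))
  params <- stats::setNames(vector("list", length(nm)), nm)
  with_rng(seed, {
    for (m in nm) {
      spec <- classifiers[[m]]
      par <- if (is.null(fixed_params)) {
        nested_tune(Xtr, ytr, spec, n_nested = n_nested,
                    tune_len = tune_len)$params
      } else fixed_params[[m]]
      params[[m]] <- par
      probs[m, ] <- fit_predict(spec, par, Xtr, ytr, Xte)
    }
  })
  votes <- probs >= 0.5
  model_metrics <- t(apply(votes, 1, function(v)
    binary_metrics(as.integer(v), yte)))
  vote_fraction <- colMeans(votes)
  ens_pred <- as.integer(vote_fraction >= 0.5)
  list(params = params, probs = probs,
       model_metrics = model_metrics,
       vote_fraction = vote_fraction,
       ensemble_metrics = binary_metrics(ens_pred, yte),
       ensemble_auc = if (length(unique(yte)) == 2)
         auc_mw(vote_fraction, yte) else NA_real_,
       certainty = apply(votes, 2, certainty),
       correct = ens_pred == yte)
}

#' Selection frequency of lipids across discovery iterations
#'
#' The robustness ranking behind the final signature: for every lipid,
#' the proportion of iterations in which Boruta confirmed it. Sorted
#' descending; ties broken by mean Boruta importance, then lipid id.
#'
#' @param records An `iteration_records` from [discovery_run()].
#' @return A data frame of class `selection_frequency` with columns
#'   `lipid_id`, `selections`, `proportion`, `mean_importance`, `rank`.
#' @export
selection_frequency <- function(records) {
  stopifnot(inherits(records, "iteration_records"), length(records) > 0)
  universe <- records[[1]]$all_features
  n_iter <- attr(records, "n_iter")
  counts <- stats::setNames(integer(length(universe)), universe)
  imp_sum <- stats::setNames(numeric(length(universe)), universe)
  for (r in records) {
    counts[r$selected] <- counts[r$selected] + 1L
    imp_sum[r$selected] <- imp_sum[r$selected] + r$selected_importance
  }
  mean_imp <- ifelse(counts > 0, imp_sum / pmax(counts, 1L), -Inf)
  ord <- order(-counts, -mean_imp, universe)
  out <- data.frame(lipid_id = universe[ord], selections = counts[ord],
                    proportion = counts[ord] / n_iter,
                    mean_importance = mean_imp[ord],
                    rank = seq_along(universe), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("selection_frequency", class(out))
  out
}

#' @rdname selection_frequency
#' @param freq A `selection_frequency` table.
#' @param k Signature size (reference protocol: 20).
#' @return `top_k` returns the first `k` lipid ids.
#' @export
top_k <- function(freq, k = 20) {
  stopifnot(inherits(freq, "selection_frequency"))
  if (k > sum(freq$selections > 0))
    stop("k exceeds the number of ever-selected lipids")
  freq$lipid_id[seq_len(k)]
}

#' Fix final hyperparameters from discovery records
#'
#' For one classifier: rank all classifiers within each iteration by
#' held-out accuracy (rank 1 = best; ties share the minimum rank). Let
#' R* be the best rank this classifier ever achieved. Among the
#' iterations where it achieved R*, take the run with the median
#' accuracy (lower median for even counts) and return the
#' hyperparameters tuned in that run — the median run avoids anchoring
#' the choice to unusually easy or hard test draws.
#'
#' @param records An `iteration_records` with fitted models.
#' @param classifier_name Name of the classifier.
#' @return The selected hyperparameter list.
#' @export
pick_final_hyperparams <- function(records, classifier_name) {
  stopifnot(inherits(records, "iteration_records"))
  if (!classifier_name %in% rownames(records[[1]]$model_metrics))
    stop("classifier not present in records: ", classifier_name)
  acc <- vapply(records, function(r)
    r$model_metrics[classifier_name, "accuracy"], numeric(1))
  rk <- vapply(records, function(r) {
    a <- r$model_metrics[, "accuracy"]
    rank(-a, ties.method = "min")[classifier_name]
  }, numeric(1))
  best <- min(rk)
  cand <- which(rk == best)
  cand <- cand[order(acc[cand], cand)]
  pick <- cand[ceiling(length(cand) / 2)]  # lower median for even counts
  records[[pick]]$params[[classifier_name]]
}

#' Final fixed-signature ensemble evaluation
#'
#' Repeats the LGOCV loop with the feature set and all hyperparameters
#' held constant: per iteration, every classifier is fit on the training
#' split restricted to the signature and votes on the held-out split.
#' Reports mean and SD of ensemble accuracy/sensitivity/specificity
#' across iterations, the mean ensemble AUC (vote fraction as the
#' score), a vertically averaged ROC curve on a fixed false-positive-
#' rate grid, per-classifier mean metrics, and the certainty breakdown
#' of correctly and incorrectly classified test samples.
#'
#' @inheritParams discovery_run
#' @param signature Character vector of lipid ids (the fixed panel).
#' @param fixed_params Named list (per classifier) of hyperparameter
#'   lists, e.g. from [pick_final_hyperparams()]; defaults per family
#'   when `NULL`.
#' @param fpr_grid Grid for ROC vertical averaging.
#' @return A list of class `performance_summary`.
#' @export
final_evaluation <- function(table, labels = NULL, signature,
                             classifiers = default_classifiers(),
                             fixed_params = NULL, plan,
                             fpr_grid = seq(0, 1, 0.02)) {
  stopifnot(inherits(table, "feature_table"), inherits(plan, "split_plan"))
  tab <- ft_study(table)
  y <- binary_labels(labels %||% tab$sample_meta$group)
  if (plan$n != length(y)) stop("split plan does not match sample count")
  miss <- setdiff(signature, colnames(tab$values))
  if (length(miss)) stop("signature lipid absent from table: ", miss[1])
  if (is.null(fixed_params))
    fixed_params <- lapply(classifiers, function(s) s$sample_params(1)[[1]])
  X <- tab$values
  iters <- vector("list", plan$n_iter)
  for (i in seq_len(plan$n_iter)) {
    s <- plan$splits[[i]]
    iters[[i]] <- eval_models_on_split(
      X, y, s, signature, classifiers, tune_len = 1, n_nested = 1,
      seed = substream_seed(plan$seed, sprintf("final_%d", i)),
      fixed_params = fixed_params)
    iters[[i]]$test <- s$test
  }
  ens <- t(vapply(iters, function(r) r$ensemble_metrics, numeric(3)))
  aucs <- vapply(iters, function(r) r$ensemble_auc, numeric(1))
  tpr_mat <- t(vapply(iters, function(r) {
    yte <- y[r$test]
    roc <- roc_points(r$vote_fraction, yte)
    vapply(fpr_grid, function(f) max(roc$tpr[roc$fpr <= f]), numeric(1))
  }, numeric(length(fpr_grid))))
  cert <- unlist(lapply(iters, function(r) r$certainty))
  corr <- unlist(lapply(iters, function(r) r$correct))
  breakdown <- do.call(rbind, lapply(c(TRUE, FALSE), function(ok) {
    tab_c <- table(factor(cert[corr == ok],
                          levels = c("high", "medium", "low")))
    n <- sum(tab_c)
    data.frame(outcome = if (ok) "correct" else "incorrect",
               certainty = names(tab_c), n = as.integer(tab_c),
               percent = if (n > 0) 100 * as.integer(tab_c) / n else 0)
  }))
  model_mean <- Reduce(`+`, lapply(iters, function(r) r$model_metrics)) /
    length(iters)
  structure(list(
    metrics_mean = colMeans(ens), metrics_sd = apply(ens, 2, stats::sd),
    mean_auc = mean(aucs, na.rm = TRUE),
    roc = data.frame(fpr = fpr_grid, tpr = colMeans(tpr_mat)),
    per_iteration = data.frame(iteration = seq_len(plan$n_iter), ens,
                               auc = aucs),
    certainty_breakdown = breakdown,
    model_mean_metrics = model_mean,
    signature = signature, fixed_params = fixed_params),
    class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  m <- 100 * x$metrics_mean; s <- 100 * x$metrics_sd
  cat(sprintf(
    "<performance_summary> accuracy %.1f +/- %.1f%%, sensitivity %.1f +/- %.1f%%, specificity %.1f +/- %.1f%%, AUC %.3f\n",
    m["accuracy"], s["accuracy"], m["sensitivity"], s["sensitivity"],
    m["specificity"], s["specificity"], x$mean_auc))
  invisible(x)
}

#' Signature-size sensitivity analysis
#'
#' Re-runs the fixed-signature evaluation for nested signature sizes
#' (top-k prefixes of the robustness ranking) and summarizes the
#' distribution of per-iteration ensemble accuracy at each size with
#' its 0.05/0.5/0.95 quantiles. The chosen size is the smallest whose
#' median accuracy is within `tol` of the best median — the smallest
#' panel that does not cost accuracy.
#'
#' @inheritParams final_evaluation
#' @param ranked_lipids Lipid ids in rank order (length >= max(sizes)).
#' @param sizes Signature sizes to evaluate (reference protocol 14:30).
#' @param tol Accuracy tolerance for the chosen size (fraction, default
#'   0.005 = 0.5 percentage points).
#' @return A list of class `sensitivity_result`: `summary` (per size:
#'   quantiles), `accuracy` (size x iteration matrix), `chosen_k`.
#' @export
sensitivity_analysis <- function(table, labels = NULL, ranked_lipids,
                                 sizes = 14:30,
                                 classifiers = default_classifiers(),
                                 fixed_params = NULL, plan, tol = 0.005) {
  if (length(ranked_lipids) < max(sizes))
    stop("ranked_lipids shorter than max(sizes)")
  acc <- matrix(NA_real_, length(sizes), plan$n_iter,
                dimnames = list(paste0("k", sizes), NULL))
  for (j in seq_along(sizes)) {
    perf <- final_evaluation(table, labels,
                             ranked_lipids[seq_len(sizes[j])],
                             classifiers, fixed_params, plan)
    acc[j, ] <- perf$per_iteration$accuracy
  }
  qs <- t(apply(acc, 1, stats::quantile, probs = c(0.05, 0.5, 0.95)))
  summary <- data.frame(k = sizes, q05 = qs[, 1], median = qs[, 2],
                        q95 = qs[, 3], row.names = NULL)
  chosen <- sizes[which(summary$median >= max(summary$median) - tol)[1]]
  structure(list(summary = summary, accuracy = acc, chosen_k = chosen,
                 tol = tol), class = "sensitivity_result")
}

#' Overlap report for named lipid panels
#'
#' Computes every intersection region of two or more panels (the Venn
#' regions) with the member lipids of each region.
#'
#' @param panels Named list of character vectors of lipid ids.
#' @param annotations Optional named vector mapping lipid id to
#'   annotation, echoed in the report.
#' @return A data frame of class `panel_overlap`: one row per region
#'   (`in_panels`, `n`, `lipid_ids`).
#' @export
compare_panels <- function(panels, annotations = NULL) {
  if (length(panels) < 2 || is.null(names(panels)))
    stop("need >= 2 named panels")
  all_ids <- sort(unique(unlist(panels)))
  member <- vapply(panels, function(p) all_ids %in% p,
                   logical(length(all_ids)))
  key <- apply(member, 1, function(m)
    paste(names(panels)[m], collapse = " & "))
  regions <- lapply(split(all_ids, key), sort)
  out <- data.frame(
    in_panels = names(regions),
    n = vapply(regions, length, integer(1)),
    lipid_ids = vapply(regions, paste, character(1), collapse = ";"),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    out$annotations <- vapply(regions, function(r)
      paste(annotations[r], collapse = ";"), character(1))
  }
  # order: most panels first, then alphabetically
  out <- out[order(-vapply(strsplit(out$in_panels, " & "), length,
                           integer(1)), out$in_panels), ]
  rownames(out) <- NULL
  class(out) <- c("panel_overlap", class(out))
  out
}

#' Leakage audit over discovery records
#'
#' Verifies, for every iteration, that the sample ids consumed by
#' feature selection and tuning are exactly the training split, that
#' train and test are disjoint and cover all samples, and that the
#' confusion identities hold. Returns the number of violations
#' (expected: 0).
#'
#' @param records An `iteration_records`.
#' @param n Total number of samples in the modelling universe.
#' @param sample_ids Sample ids in table order.
#' @return Integer count of violations.
#' @export
audit_leakage <- function(records, n, sample_ids) {
  stopifnot(inherits(records, "iteration_records"))
  bad <- 0L
  for (r in records) {
    if (length(intersect(r$train, r$test)) > 0) bad <- bad + 1L
    if (!setequal(c(r$train, r$test), seq_len(n))) bad <- bad + 1L
    if (!setequal(r$consumed_ids, sample_ids[r$train])) bad <- bad + 1L
    if (any(sample_ids[r$test] %in% r$consumed_ids)) bad <- bad + 1L
  }
  bad
}

#' Write iteration records as newline-delimited JSON
#' @param records An `iteration_records`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_iteration_records <- function(records, path) {
  stopifnot(inherits(records, "iteration_records"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    line <- list(iteration = r$iteration, train = r$train, test = r$test,
                 selected = r$selected, fallback = r$fallback)
    if (!is.null(r$ensemble_metrics)) {
      line$ensemble_metrics <- as.list(r$ensemble_metrics)
      line$params <- r$params
      line$vote_fraction <- unname(r$vote_fraction)
    }
    writeLines(as.character(jsonlite::toJSON(line, auto_unbox = TRUE,
                                             digits = NA)), con)
  }
  invisible(path)
}
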