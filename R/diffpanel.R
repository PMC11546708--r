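#' Per-lipid differential abundance between groups
#'
#' Fits, for every lipid, an additive linear model of log2 concentration
#' on group plus optional cohort and batch covariates, and reports the
#' group-effect p-value (F test) together with the fold change
#' `fc = 2^(mean difference)`, the linear-scale ratio of group geometric
#' means. With `method = "mixed"`, batch enters as a random intercept
#' fitted by REML ([nlme::lme()]) instead of a fixed effect.
#'
#' @param table A log2-scale [feature_table()]; QC samples are excluded.
#' @param blocking Character vector of covariates to adjust for, any of
#'   `"cohort"`, `"batch"`. Terms constant across samples are dropped.
#' @param method `"fixed"` (default) or `"mixed"` (random batch
#'   intercept; requires `"batch"` blocking).
#' @return A data frame of class `da_result` with one row per lipid:
#'   `lipid_id`, `fc`, `log2fc`, `p`, `q` (Benjamini-Hochberg adjusted).
#'   Constant lipids get `p = 1`, `fc = 1` with a warning.
#' @export
da_test <- function(table, blocking = "cohort",
                    method = c("fixed", "mixed")) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  if (!table$log_flag) stop("da_test expects a log2-scale table")
  tab <- ft_study(table)
  meta <- tab$sample_meta
  if (length(unique(meta$group)) != 2)
    stop("need exactly two groups")
  if (min(table(meta$group)) < 2) stop("need >= 2 samples per group")
  grp <- factor(meta$group, levels = c("control", "cancer"))
  covars <- list()
  for (b in intersect(blocking, c("cohort", "batch"))) {
    v <- meta[[b]]
    if (length(unique(v)) > 1) covars[[b]] <- factor(v)
  }
  Y <- tab$values
  const <- apply(Y, 2, function(y) stats::var(y) == 0)
  if (any(const))
    warning(sum(const), " constant lipid column(s): p = 1, fc = 1")
  if (method == "mixed") {
    if (length(unique(meta$batch)) < 2)
      stop("mixed model needs >= 2 batches")
    dat0 <- data.frame(grp = grp, batch = factor(meta$batch))
    if (!is.null(covars$cohort)) dat0$cohort <- covars$cohort
    fixed_rhs <- if (is.null(covars$cohort)) "grp" else "grp + cohort"
    res <- t(vapply(seq_len(ncol(Y)), function(j) {
      if (const[j]) return(c(0, 1))
      dat0$y <- Y[, j]
      fit <- nlme::lme(stats::as.formula(paste("y ~", fixed_rhs)),
                       random = ~ 1 | batch, data = dat0, method = "REML")
      an <- stats::anova(fit)
      c(nlme::fixef(fit)[["grpcancer"]], an["grp", "p-value"])
    }, numeric(2)))
  } else {
    dat <- data.frame(grp = grp)
    for (nm in names(covars)) dat[[nm]] <- covars[[nm]]
    X <- stats::model.matrix(~ ., data = dat)
    qrX <- qr(X)
    coefs <- qr.coef(qrX, Y)
    fitted <- qr.fitted(qrX, Y)
    rss1 <- colSums((Y - fitted)^2)
    # null model: drop the group column
    X0 <- X[, colnames(X) != "grpcancer", drop = FALSE]
    qr0 <- qr(X0)
    rss0 <- colSums((Y - qr.fitted(qr0, Y))^2)
    df1 <- nrow(X) - qrX$rank
    Fstat <- (rss0 - rss1) / (rss1 / df1)
    pval <- stats::pf(Fstat, 1, df1, lower.tail = FALSE)
    res <- cbind(coefs["grpcancer", ], pval)
    res[const, 1] <- 0
    res[const, 2] <- 1
  }
  out <- data.frame(lipid_id = colnames(Y), fc = 2^res[, 1],
                    log2fc = res[, 1], p = res[, 2],
                    q = bh_adjust(res[, 2]), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("da_result", class(out))
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement; order-preserving.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select a differential-abundance panel
#'
#' A lipid enters the panel when its FDR-adjusted q-value passes `q_max`
#' and its fold change passes `fc_min` in either direction (the filter
#' uses `max(fc, 1/fc)`, so depleted and enriched lipids both qualify).
#' Isomer inclusion: every isomer-group mate of a selected lipid is then
#' added, since co-eluting isomers cannot be quantified independently.
#'
#' @param da A `da_result` from [da_test()].
#' @param schema Lipid schema aligned with `da` (see
#'   [build_lipid_schema()]).
#' @param fc_min Linear fold-change threshold (exclusive).
#' @param q_max FDR threshold (exclusive).
#' @return A data frame of class `panel_spec` with columns `lipid_id`,
#'   `da_selected`, `isomer_included`, ordered by q-value.
#' @export
select_panel <- function(da, schema, fc_min = 1.2, q_max = 0.05) {
  stopifnot(inherits(da, "da_result"))
  if (!all(da$lipid_id %in% schema$lipid_id))
    stop("da and schema are not aligned")
  hit <- da$q < q_max & pmax(da$fc, 1 / da$fc) > fc_min
  sel <- da$lipid_id[hit]
  groups <- schema$isomer_group[match(sel, schema$lipid_id)]
  mates <- schema$lipid_id[schema$isomer_group %in% groups]
  ids <- union(sel, mates)
  ord <- order(da$q[match(ids, da$lipid_id)])
  ids <- ids[ord]
  out <- data.frame(lipid_id = ids,
                    da_selected = ids %in% sel,
                    isomer_included = !(ids %in% sel),
                    stringsAsFactors = FALSE)
  class(out) <- c("panel_spec", class(out))
  out
}

#' Restrict a panel by m/z via forward stepwise logistic regression
#'
#' Lipids sharing one m/z value form a group (isomers are
#' indistinguishable by mass); groups are added greedily to a logistic
#' model of group membership, each step adding the m/z group that most
#' lowers AIC, stopping when no addition lowers it. The returned panel
#' is the union of the retained groups' lipids.
#'
#' @param table A log2-scale [feature_table()].
#' @param panel A `panel_spec` from [select_panel()].
#' @param labels Optional factor/character of sample labels; defaults to
#'   the table's group metadata.
#' @return A `panel_spec` restricted to retained lipids, with a
#'   `stepwise_retained` column.
#' @export
stepwise_restrict <- function(table, panel, labels = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(panel) == 0) stop("panel is empty")
  tab <- ft_study(table)
  y <- binary_labels(labels %||% tab$sample_meta$group)
  ids <- intersect(panel$lipid_id, colnames(tab$values))
  mz <- tab$lipid_meta$mz[match(ids, tab$lipid_meta$lipid_id)]
  mzg <- match(mz, unique(mz))
  X <- tab$values[, ids, drop = FALSE]
  retained <- integer(0)
  candidates <- unique(mzg)
  aic_of <- function(groups) {
    if (length(groups) == 0) {
      fit <- suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
      return(stats::AIC(fit))
    }
    cols <- ids[mzg %in% groups]
    # duplicate columns (shared values) carry no extra information;
    # drop exact duplicates so the fit and AIC are invariant to them
    Xg <- X[, cols, drop = FALSE]
    Xg <- Xg[, !duplicated(t(Xg)), drop = FALSE]
    fit <- suppressWarnings(stats::glm(y ~ Xg, family = stats::binomial()))
    if (fit$converged && all(abs(stats::coef(fit)) < 1e3))
      return(stats::AIC(fit))
    # separation: penalized (ridge) deviance with the same 2k penalty
    warning("separation in stepwise fit; using penalized deviance")
    rf <- glmnet::glmnet(cbind(Xg, 0), y, family = "binomial", alpha = 0,
                         lambda = 1e-2)
    dev <- (1 - rf$dev.ratio) * rf$nulldev
    dev + 2 * (ncol(Xg) + 1)
  }
  cur <- aic_of(retained)
  repeat {
    if (length(candidates) == 0) break
    trials <- vapply(candidates, function(g) aic_of(c(retained, g)),
                     numeric(1))
    if (min(trials) >= cur) break
    best <- candidates[which.min(trials)]
    cur <- min(trials)
    retained <- c(retained, best)
    candidates <- setdiff(candidates, best)
  }
  keep <- ids[mzg %in% retained]
  out <- panel[panel$lipid_id %in% keep, , drop = FALSE]
  out$stepwise_retained <- TRUE
  rownames(out) <- NULL
  class(out) <- c("panel_spec", class(out))
  out
}

binary_labels <- function(labels) {
  labels <- as.character(labels)
  lv <- c("control", "cancer")
  if (!all(labels %in% lv))
    lv <- sort(unique(labels))
  if (length(unique(labels)) != 2) stop("need exactly two classes")
  as.integer(labels == lv[2])
}

#' Leave-one-out cross-validated logistic panel evaluation
#'
#' For each sample, a logistic regression over the panel lipids is fit
#' on all other samples and the held-out sample receives a predicted
#' cancer probability in `[0, 1]`. The classification threshold is then
#' chosen on those scores to maximize accuracy
#' ([optimize_threshold()]), the paper-style protocol for this design;
#' note the threshold is optimized on the same scores it is evaluated
#' on, a deliberate reproduction of the reference workflow rather than
#' an unbiased estimate.
#'
#' @param table A log2-scale [feature_table()].
#' @param panel A `panel_spec` (or character vector of lipid ids).
#' @param labels Optional labels; defaults to group metadata.
#' @return A list of class `loocv_result`: per-sample `scores`,
#'   `threshold`, `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (TP/FP/TN/FN), `roc` (data frame), `auc` (Mann-Whitney).
#' @export
loocv_logistic <- function(table, panel, labels = NULL) {
  stopifnot(inherits(table, "feature_table"))
  tab <- ft_study(table)
  ids <- if (is.character(panel)) panel else panel$lipid_id
  ids <- intersect(ids, colnames(tab$values))
  y <- binary_labels(labels %||% tab$sample_meta$group)
  n <- length(y)
  if (n < 10) stop("need at least 10 samples")
  if (length(ids) >= n - 1) stop("panel too large for LOOCV")
  X <- tab$values[, ids, drop = FALSE]
  scores <- vapply(seq_len(n), function(i) {
    fit_logistic_scores(X[-i, , drop = FALSE], y[-i], X[i, , drop = FALSE])
  }, numeric(1))
  thr <- optimize_threshold(scores, y)
  pred <- as.integer(scores > thr)
  conf <- c(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
            TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1))
  structure(list(
    scores = stats::setNames(scores, rownames(X)), threshold = thr,
    accuracy = mean(pred == y),
    sensitivity = conf["TP"] / (conf["TP"] + conf["FN"]),
    specificity = conf["TN"] / (conf["TN"] + conf["FP"]),
    confusion = conf, roc = roc_points(scores, y),
    auc = auc_mw(scores, y)), class = "loocv_result")
}

# Logistic fit returning held-out probabilities; falls back to a small
# ridge penalty when the ML fit fails to converge or separates.
fit_logistic_scores <- function(Xtr, ytr, Xte) {
  fit <- suppressWarnings(stats::glm.fit(cbind(1, Xtr), ytr,
                                         family = stats::binomial()))
  if (!fit$converged || any(abs(fit$coefficients) > 1e3) ||
      anyNA(fit$coefficients)) {
    warning("logistic fit unstable; using ridge-stabilized refit")
    rf <- glmnet::glmnet(Xtr, ytr, family = "binomial", alpha = 0,
                         lambda = 1e-3)
    return(as.numeric(stats::predict(rf, newx = Xte, type = "response")))
  }
  eta <- drop(cbind(1, Xte) %*% fit$coefficients)
  1 / (1 + exp(-eta))
}

#' Accuracy-optimal classification threshold
#'
#' Evaluates accuracy at the midpoints between consecutive sorted unique
#' scores, plus sentinels below the minimum and above the maximum, and
#' returns the midpoint with maximal accuracy ("score > threshold"
#' predicts the positive class). Ties are broken toward the smallest
#' threshold, favouring sensitivity.
#'
#' @param scores Numeric scores (larger = more cancer-like).
#' @param labels Binary labels (0/1 or control/cancer).
#' @return The threshold, a single number.
#' @export
optimize_threshold <- function(scores, labels) {
  y <- if (is.numeric(labels) && all(labels %in% 0:1)) as.integer(labels)
       else binary_labels(labels)
  if (length(unique(y)) != 2) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  acc <- vapply(cand, function(t) mean((scores > t) == y), numeric(1))
  cand[which.max(acc)]  # which.max takes the first (smallest) on ties
}

#' Mann-Whitney AUC of scores against binary labels
#'
#' Rank-statistic AUC: the probability a random positive scores above a
#' random negative, ties counted one half.
#'
#' @inheritParams optimize_threshold
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  y <- if (is.numeric(labels) && all(labels %in% 0:1)) as.integer(labels)
       else binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Empirical ROC points at every distinct score threshold.
roc_points <- function(scores, labels) {
  y <- if (is.numeric(labels) && all(labels %in% 0:1)) as.integer(labels)
       else binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[y == 0] > t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[y == 1] > t), numeric(1)))
}

#' Per-subject EV/plasma correlation over a lipid panel
#'
#' For each subject present in both tables, the Pearson correlation
#' between the EV and plasma log2 concentrations of the panel lipids.
#' Quantifies how faithfully the cheaper plasma measurement mirrors the
#' EV profile.
#'
#' @param ev,plasma [feature_table()]s sharing subject ids.
#' @param panel A `panel_spec` or character vector of lipid ids (at
#'   least 3).
#' @param r_cutoff Threshold for the reported high-correlation count.
#' @return A list of class `subject_correlation`: `per_subject` (data
#'   frame sorted by decreasing r), `n_above`, `r_cutoff`.
#' @export
subject_correlation <- function(ev, plasma, panel, r_cutoff = 0.9) {
  stopifnot(inherits(ev, "feature_table"), inherits(plasma, "feature_table"))
  ids <- if (is.character(panel)) panel else panel$lipid_id
  if (length(ids) < 3) stop("need at least 3 panel lipids")
  miss <- setdiff(ids, intersect(colnames(ev$values), colnames(plasma$values)))
  if (length(miss)) stop("panel lipid absent from a table: ", miss[1])
  e <- ft_study(ev); p <- ft_study(plasma)
  subjects <- intersect(e$sample_meta$subject_id, p$sample_meta$subject_id)
  if (length(subjects) == 0) stop("no shared subject ids")
  le <- if (e$log_flag) e$values else log2(e$values)
  lp <- if (p$log_flag) p$values else log2(p$values)
  r <- vapply(subjects, function(s) {
    i <- match(s, e$sample_meta$subject_id)
    j <- match(s, p$sample_meta$subject_id)
    stats::cor(le[i, ids], lp[j, ids])
  }, numeric(1))
  df <- data.frame(subject_id = subjects, r = r, stringsAsFactors = FALSE)
  df <- df[order(-df$r), ]
  rownames(df) <- NULL
  structure(list(per_subject = df, n_above = sum(r > r_cutoff),
                 r_cutoff = r_cutoff), class = "subject_correlation")
}
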