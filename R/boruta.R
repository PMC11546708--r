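#' Boruta configuration
#'
#' Settings for the all-relevant shadow-feature selection run. The
#' reference protocol uses 100 iterations with 500 trees per random
#' forest and a Bonferroni-adjusted p-value cut-off of 0.01; `n_iter`
#' and `n_trees` scale down for quick profiles without changing the
#' decision rule (the binomial tests account for the number of
#' iterations actually run).
#'
#' @param n_iter Shadow iterations (forests grown).
#' @param n_trees Trees per forest.
#' @param alpha Significance cut-off applied after Bonferroni
#'   adjustment.
#' @param adjust Multiple-testing adjustment; only `"bonferroni"` is
#'   supported. The Bonferroni factor is the *initial* feature count,
#'   the conservative choice, even after features are dropped.
#' @param importance_kind `"impurity"` (Gini, fast) or `"permutation_z"`
#'   (out-of-bag permutation importance scaled by its standard error).
#' @param mtry,max_depth Forest geometry passed to [ranger::ranger()];
#'   `NULL` lets ranger use its defaults.
#' @param burn_in Iterations before the first confirm/reject checkpoint.
#' @param seed Integer seed.
#' @return A list of class `boruta_config`.
#' @export
boruta_config <- function(n_iter = 100, n_trees = 500, alpha = 0.01,
                          adjust = "bonferroni",
                          importance_kind = c("permutation_z", "impurity"),
                          mtry = NULL, max_depth = NULL, burn_in = 5,
                          seed = 1) {
  importance_kind <- match.arg(importance_kind)
  if (n_iter < 1 || n_trees < 1) stop("n_iter and n_trees must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (adjust != "bonferroni") stop("only bonferroni adjustment is supported")
  structure(list(n_iter = as.integer(n_iter), n_trees = as.integer(n_trees),
                 alpha = alpha, adjust = adjust,
                 importance_kind = importance_kind, mtry = mtry,
                 max_depth = max_depth, burn_in = as.integer(burn_in),
                 seed = as.integer(seed)), class = "boruta_config")
}

#' Append shadow features to a design matrix
#'
#' For every original column, appends a shadow column holding an
#' independent row permutation of that column's values: the shadow keeps
#' the marginal distribution but breaks any association with the
#' outcome. Original columns are unchanged; shadow columns are named
#' `shadow_<original>`.
#'
#' @param X Numeric matrix with at least one column.
#' @return The augmented matrix with `2 * ncol(X)` columns.
#' @export
shadow_augment <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("need at least one feature")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  Sh <- X
  for (j in seq_len(ncol(X))) Sh[, j] <- X[sample.int(nrow(X)), j]
  colnames(Sh) <- paste0("shadow_", colnames(X))
  cbind(X, Sh)
}

#' All-relevant feature selection with shadow features (Boruta)
#'
#' Each iteration permutes shadow copies of all still-active features,
#' grows a random forest on the augmented matrix, and scores a "hit" for
#' every real feature whose importance strictly exceeds the maximum
#' shadow importance. After a burn-in, every iteration tests each active
#' feature's hit count against Binomial(k, 1/2), where k is the number
#' of iterations the feature participated in: the upper tail confirms
#' (consistently more important than chance), the lower tail rejects
#' (consistently less), both at the Bonferroni-adjusted `alpha`.
#' Rejected features are dropped from later iterations; features still
#' undecided at the end are tentative. Only confirmed features are
#' selected downstream.
#'
#' @param X Numeric samples x features matrix (no missing values).
#' @param y Binary outcome (two classes).
#' @param config A [boruta_config()].
#' @return A list of class `boruta_result`: `decision` (named factor:
#'   confirmed/tentative/rejected), `hits`, `iterations` (participation
#'   counts), `p_confirm`, `p_reject`, `selected` (confirmed feature
#'   names), `mean_importance`, `importance_history` (iterations x
#'   features, NA once dropped).
#' @export
boruta_run <- function(X, y, config = boruta_config()) {
  stopifnot(inherits(config, "boruta_config"))
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values are not supported")
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must contain exactly two classes")
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  feat <- colnames(X)
  hits <- stats::setNames(integer(p), feat)
  part <- stats::setNames(integer(p), feat)
  active <- rep(TRUE, p)
  rejected <- rep(FALSE, p)
  thr <- config$alpha / p  # Bonferroni over the initial feature count
  history <- matrix(NA_real_, config$n_iter, p,
                    dimnames = list(NULL, feat))
  use_perm <- config$importance_kind == "permutation_z"
  with_rng(config$seed, {
    for (it in seq_len(config$n_iter)) {
      ia <- which(active)
      if (length(ia) == 0) break
      Xa <- shadow_augment(X[, ia, drop = FALSE])
      rf <- ranger::ranger(
        x = Xa, y = y, num.trees = config$n_trees,
        importance = if (use_perm) "permutation" else "impurity",
        scale.permutation.importance = use_perm,
        mtry = if (is.null(config$mtry)) NULL else min(config$mtry, ncol(Xa)),
        max.depth = config$max_depth %||% 0,
        num.threads = 1,
        seed = sample.int(.Machine$integer.max, 1))
      imp <- rf$variable.importance
      real <- imp[seq_along(ia)]
      shadow_max <- max(imp[-seq_along(ia)])
      hits[ia] <- hits[ia] + (real > shadow_max)
      part[ia] <- part[ia] + 1L
      history[it, ia] <- real
      if (it >= config$burn_in) {
        p_rej <- stats::pbinom(hits, pmax(part, 1L), 0.5)
        drop_now <- active & part > 0 & p_rej < thr
        rejected <- rejected | drop_now
        active <- active & !drop_now
      }
    }
  })
  p_confirm <- stats::pbinom(hits - 1L, pmax(part, 1L), 0.5,
                             lower.tail = FALSE)
  p_reject <- stats::pbinom(hits, pmax(part, 1L), 0.5)
  confirmed <- part > 0 & p_confirm < thr & !rejected
  decision <- factor(ifelse(confirmed, "confirmed",
                            ifelse(rejected, "rejected", "tentative")),
                     levels = c("confirmed", "tentative", "rejected"))
  names(decision) <- feat
  structure(list(
    decision = decision, hits = hits, iterations = part,
    p_confirm = stats::setNames(p_confirm, feat),
    p_reject = stats::setNames(p_reject, feat),
    selected = feat[confirmed],
    mean_importance = colMeans(history, na.rm = TRUE),
    importance_history = history,
    config = config), class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat(sprintf(
    "<boruta_result> %d features: %d confirmed, %d tentative, %d rejected\n",
    length(x$decision), tab[["confirmed"]], tab[["tentative"]],
    tab[["rejected"]]))
  invisible(x)
}

#' Serialize a Boruta result
#'
#' Decisions and test statistics go to JSON; the per-iteration
#' importance history to CSV.
#'
#' @param result A `boruta_result`.
#' @param json_path,history_path Output files (either may be `NULL`).
#' @return `result`, invisibly.
#' @export
write_boruta_result <- function(result, json_path = NULL,
                                history_path = NULL) {
  stopifnot(inherits(result, "boruta_result"))
  if (!is.null(json_path)) {
    dir.create(dirname(json_path), recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(
      decision = as.list(stats::setNames(as.character(result$decision),
                                         names(result$decision))),
      hits = as.list(result$hits),
      iterations = as.list(result$iterations),
      p_confirm = as.list(result$p_confirm),
      p_reject = as.list(result$p_reject),
      selected = result$selected), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(history_path)) {
    dir.create(dirname(history_path), recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(result$importance_history), history_path,
                     row.names = FALSE)
  }
  invisible(result)
}
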