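test_that("split plans have the stated sizes and stratification", {
  y10 <- rep(c("control", "cancer"), 5)
  p10 <- make_splits(y10, n_iter = 20, seed = 1)
  expect_true(all(vapply(p10$splits, function(s) length(s$test),
                         integer(1)) == 2))
  # stratified 5+5 with |test| = 2: one of each class
  expect_true(all(vapply(p10$splits, function(s)
    sum(y10[s$test] == "cancer") == 1, logical(1))))

  y256 <- rep(c("control", "cancer"), each = 128)
  p256 <- make_splits(y256, n_iter = 5, seed = 2)
  expect_equal(length(p256$splits[[1]]$test), 51)  # round(51.2)

  # disjoint and exhaustive partitions, reproducible under seed
  for (s in p256$splits) {
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), seq_along(y256))
  }
  expect_identical(make_splits(y256, n_iter = 5, seed = 2), p256)
  expect_error(make_splits(y10, test_fraction = 0.01), "empty test")
})

test_that("majority vote, score and certainty follow the stated rules", {
  expect_equal(ensemble_vote(rep(c(1, 0), each = 9)), 1)  # 9v9 tie: cancer
  expect_equal(ensemble_vote(rep(0, 18)), 0)
  expect_equal(ensemble_score(c(rep(1, 10), rep(0, 8))), 10 / 18)
  expect_equal(ensemble_vote(c(rep(1, 10), rep(0, 8))), 1)
  expect_equal(ensemble_score(rep(0, 18)), 0)

  expect_equal(certainty(rep(1, 18)), "high")
  expect_equal(certainty(c(rep(1, 15), rep(0, 3))), "medium")  # 83.3%
  expect_equal(certainty(c(rep(1, 12), rep(0, 6))), "low")     # 66.7%
  expect_equal(certainty(c(rep(0, 16), rep(1, 4))), "medium")  # 80% exactly
})

test_that("nested tuning returns single candidates untouched and picks
           the better of two planted candidates", {
  # classifier with a fixed projection direction as its hyperparameter
  proj_spec <- classifier_spec(
    "proj",
    sample_params = function(n) list(list(w = "good"), list(w = "bad"))[
      seq_len(n)],
    fit = function(X, y, params) {
      w <- if (params$w == "good") c(1, 0) else c(0, 1)
      mu1 <- mean(X[y == 1, ] %*% w); mu0 <- mean(X[y == 0, ] %*% w)
      list(w = w, thr = (mu1 + mu0) / 2, flip = mu1 < mu0)
    },
    predict = function(model, X) {
      s <- as.numeric(X %*% model$w) - model$thr
      stats::plogis(if (model$flip) -s else s)
    })
  single <- classifier_spec("one", function(n) list(list(k = 42)),
                            function(X, y, p) NULL,
                            function(m, X) rep(0.5, nrow(X)))
  expect_equal(nested_tune(NULL, NULL, single)$params$k, 42)

  set.seed(20)
  n <- 80
  y <- rep(0:1, each = n / 2)
  wins <- replicate(10, {
    X <- cbind(stats::rnorm(n) + 1.5 * y, stats::rnorm(n))
    colnames(X) <- c("signal", "noise")
    nested_tune(X, y, proj_spec, n_nested = 10,
                tune_len = 2)$params$w == "good"
  })
  expect_gte(mean(wins), 0.9)

  # identical RNG stream: identical draws and selection
  X <- cbind(stats::rnorm(n) + y, stats::rnorm(n))
  r1 <- with_rng_test(5, nested_tune(X, y, proj_spec, n_nested = 5,
                                     tune_len = 2))
  r2 <- with_rng_test(5, nested_tune(X, y, proj_spec, n_nested = 5,
                                     tune_len = 2))
  expect_identical(r1, r2)
})

test_that("final hyperparameters come from the lower-median best-rank run", {
  mk_rec <- function(i, accA, accB, par) {
    list(iteration = i,
         model_metrics = rbind(A = c(accuracy = accA, sensitivity = NA,
                                     specificity = NA),
                               B = c(accuracy = accB, sensitivity = NA,
                                     specificity = NA)),
         params = list(A = list(p = par), B = list(p = -par)))
  }
  # A's ranks: iter1 rank 2 (0.8 < 0.9), iters 2 and 3 rank 1
  recs <- structure(list(mk_rec(1, 0.8, 0.9, 101),
                         mk_rec(2, 0.7, 0.6, 102),
                         mk_rec(3, 0.9, 0.8, 103)),
                    class = "iteration_records", n_iter = 3)
  # best rank 1 in iters {2, 3} with accuracies {0.7, 0.9}:
  # lower median 0.7 -> iteration 2's hyperparameters
  expect_equal(pick_final_hyperparams(recs, "A")$p, 102)

  one <- structure(list(mk_rec(1, 0.5, 0.4, 7)),
                   class = "iteration_records", n_iter = 1)
  expect_equal(pick_final_hyperparams(one, "A")$p, 7)

  same <- structure(list(mk_rec(1, 0.6, 0.5, 1), mk_rec(2, 0.6, 0.5, 2),
                         mk_rec(3, 0.6, 0.5, 3), mk_rec(4, 0.6, 0.5, 4)),
                    class = "iteration_records", n_iter = 4)
  # four identical rank-1 runs: lower median is the second
  expect_equal(pick_final_hyperparams(same, "A")$p, 2)
  expect_error(pick_final_hyperparams(recs, "Z"), "not present")
})

test_that("discovery consumes only training data", {
  tc <- tiny_cohort(seed = 70)
  tab <- ft_study(tc$log2)
  y <- tab$sample_meta$group
  plan <- make_splits(y, n_iter = 3, seed = 4)
  rec <- discovery_run(tc$log2, classifiers = list(),
                       boruta_cfg = fast_boruta(), plan = plan)
  expect_equal(audit_leakage(rec, length(y), tab$sample_meta$sample_id), 0)

  # functional check: scrambling an iteration's held-out samples leaves
  # that iteration's selected features unchanged
  for (i in seq_len(plan$n_iter)) {
    tam <- tc$log2
    test_ids <- tab$sample_meta$sample_id[plan$splits[[i]]$test]
    rows <- match(test_ids, rownames(tam$values))
    set.seed(999 + i)
    tam$values[rows, ] <- tam$values[rows, sample(ncol(tam$values))] + 5
    rec2 <- discovery_run(tam, classifiers = list(),
                          boruta_cfg = fast_boruta(), plan = plan)
    expect_identical(rec2[[i]]$selected, rec[[i]]$selected)
  }
})

test_that("selection frequency ranks by count then importance", {
  mk <- function(i, sel, imp) {
    list(iteration = i, selected = sel,
         selected_importance = stats::setNames(imp, sel),
         all_features = paste0("L", 1:6))
  }
  recs <- structure(list(
    mk(1, c("L2", "L3"), c(5, 1)),
    mk(2, c("L2", "L4"), c(6, 9)),
    mk(3, c("L2", "L3"), c(4, 2))),
    class = "iteration_records", n_iter = 3)
  freq <- selection_frequency(recs)
  expect_equal(freq$lipid_id[1:3], c("L2", "L3", "L4"))
  expect_equal(freq$proportion[1:3], c(1, 2 / 3, 1 / 3))
  # never-selected lipids have zero proportion and trail the ranking
  expect_true(all(freq$proportion[4:6] == 0))
  expect_equal(sort(freq$lipid_id[4:6]), c("L1", "L5", "L6"))
  expect_equal(top_k(freq, 2), c("L2", "L3"))
  expect_error(top_k(freq, 4), "ever-selected")

  # arithmetic: 1500 of 2000 iterations -> proportion 0.75
  big <- structure(lapply(1:2000, function(i)
    mk(i, if (i <= 1500) "L1" else character(0),
       if (i <= 1500) 1 else numeric(0))),
    class = "iteration_records", n_iter = 2000)
  expect_equal(selection_frequency(big)$proportion[1], 0.75)
})

test_that("every default classifier is correctly oriented", {
  # an easy two-feature problem: any inverted score orientation would
  # drop accuracy far below chance
  set.seed(33)
  n <- 120
  y <- rep(0:1, each = n / 2)
  X <- cbind(a = stats::rnorm(n) + 2.5 * y, b = stats::rnorm(n) - 2 * y)
  tr <- c(1:40, 61:100); te <- setdiff(seq_len(n), tr)
  for (spec in default_classifiers()) {
    par <- spec$sample_params(1)[[1]]
    pr <- lipidscreen:::fit_predict(spec, par, X[tr, ], y[tr], X[te, ])
    expect_gt(mean((pr >= 0.5) == y[te]), 0.9, label = spec$name)
  }
})

test_that("ensemble agreement collapses to the individual metrics", {
  # three deterministic copies of the same linear model vote identically
  tc <- tiny_cohort(seed = 72)
  lda3 <- default_classifiers(c("lda"))[rep(1, 3)]
  names(lda3) <- c("m1", "m2", "m3")
  plan <- make_splits(ft_study(tc$log2)$sample_meta$group,
                      n_iter = 4, seed = 6)
  perf <- final_evaluation(tc$log2,
                           signature = colnames(tc$log2$values)[1:8],
                           classifiers = lda3, plan = plan)
  for (m in c("m1", "m2", "m3"))
    expect_equal(perf$model_mean_metrics[m, "accuracy"],
                 unname(perf$metrics_mean["accuracy"]))
  # all test votes must then be high-certainty
  expect_true(all(perf$certainty_breakdown$percent[
    perf$certainty_breakdown$certainty != "high"] == 0))
})

test_that("final evaluation is exact on separable data and keeps books", {
  tc <- tiny_cohort(seed = 73, effect_log2fc = 4, n_informative = 4,
                    sigma_tech_ev = 0.05, sigma_tech_plasma = 0.05)
  plan <- make_splits(ft_study(tc$log2)$sample_meta$group,
                      n_iter = 5, seed = 8)
  suite <- default_classifiers(c("lda", "glmnet_logistic", "knn"))
  perf <- final_evaluation(tc$log2,
                           signature = tc$truth$informative_lipids,
                           classifiers = suite, plan = plan)
  expect_equal(unname(perf$metrics_mean["accuracy"]), 1)
  expect_equal(unname(perf$metrics_sd["accuracy"]), 0)
  expect_equal(perf$mean_auc, 1)
  # summary mean equals the arithmetic mean of per-iteration metrics
  expect_equal(unname(perf$metrics_mean["sensitivity"]),
               mean(perf$per_iteration$sensitivity))
  # certainty percentages sum to 100 per outcome class present
  for (oc in unique(perf$certainty_breakdown$outcome)) {
    tot <- sum(perf$certainty_breakdown$percent[
      perf$certainty_breakdown$outcome == oc])
    expect_true(abs(tot - 100) < 0.1 || tot == 0)
  }
})

test_that("sensitivity analysis prefers the smallest adequate panel", {
  tc <- tiny_cohort(seed = 74, effect_log2fc = 4, n_informative = 2,
                    within_class_corr = 0, sigma_tech_ev = 0.1,
                    sigma_tech_plasma = 0.1)
  tab <- ft_study(tc$log2)
  plan <- make_splits(tab$sample_meta$group, n_iter = 4, seed = 10)
  ranked <- c(tc$truth$informative_lipids,
              setdiff(colnames(tab$values),
                      tc$truth$informative_lipids))
  suite <- default_classifiers(c("lda", "glmnet_logistic", "knn"))
  sens <- sensitivity_analysis(tc$log2, ranked_lipids = ranked,
                               sizes = c(2, 4, 6), classifiers = suite,
                               plan = plan)
  expect_equal(sens$chosen_k, 2)  # all signal lives in the top 2
  expect_true(all(sens$summary$q05 <= sens$summary$median &
                    sens$summary$median <= sens$summary$q95))

  one <- sensitivity_analysis(tc$log2, ranked_lipids = ranked,
                              sizes = 4, classifiers = suite, plan = plan)
  expect_equal(nrow(one$summary), 1)
  expect_equal(one$chosen_k, 4)
})

test_that("panel overlap reports every intersection region", {
  same <- compare_panels(list(a = c("x", "y"), b = c("x", "y")))
  expect_equal(nrow(same), 1)
  expect_equal(same$in_panels, "a & b")

  disj <- compare_panels(list(a = c("x"), b = c("y")))
  expect_setequal(disj$in_panels, c("a", "b"))

  three <- compare_panels(list(
    p1 = c("c1", "c2", "u1"), p2 = c("c1", "c2", "u2"),
    p3 = c("c1", "c2", "u3", "u1")))
  centre <- three[three$in_panels == "p1 & p2 & p3", ]
  expect_equal(centre$lipid_ids, "c1;c2")
  expect_equal(three$lipid_ids[three$in_panels == "p1 & p3"], "u1")
})
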