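test_that("lipid schema has the requested shape and isomer structure", {
  s <- build_lipid_schema(454, 15, isomer_rate = 0, seed = 1)
  expect_equal(nrow(s), 454)
  expect_equal(length(unique(s$lipid_class)), 15)
  expect_false(anyDuplicated(s$lipid_id) > 0)
  # no isomers requested: every group is a singleton
  expect_equal(max(table(s$isomer_group)), 1)

  one <- build_lipid_schema(1, 1, seed = 2)
  expect_equal(nrow(one), 1)

  a <- build_lipid_schema(10, 2, isomer_rate = 0.4, seed = 5)
  b <- build_lipid_schema(10, 2, isomer_rate = 0.4, seed = 5)
  expect_identical(a, b)
  # isomer-group mates share class, annotation and m/z
  multi <- names(which(table(a$isomer_group) > 1))
  expect_gt(length(multi), 0)
  for (g in multi) {
    m <- a[a$isomer_group == g, ]
    expect_equal(length(unique(m$mz)), 1)
    expect_equal(length(unique(m$annotation)), 1)
    expect_equal(length(unique(m$lipid_class)), 1)
  }
  expect_error(build_lipid_schema(5, 9), "counts")
  expect_error(build_lipid_schema(10, 2, isomer_rate = 1), "isomer_rate")
})

test_that("generator is deterministic and respects null/batch settings", {
  cfg <- tiny_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$truth, b$truth)

  cfg0 <- tiny_config(seed = 4, batch_sd = 0)
  t0 <- simulate_cohort(cfg0)
  expect_true(all(t0$truth$batch_factors == 1))

  # zero planted effects: group-difference p-values roughly uniform
  cfgn <- tiny_config(seed = 9, n_informative = 0, n_control = 100,
                      n_cancer = 100, n_lipids = 80, batch_sd = 0)
  sim <- simulate_cohort(cfgn)
  lg <- log_transform(sim$table)
  tab <- ft_study(lg)
  grp <- tab$sample_meta$group
  p <- apply(tab$values, 2, function(v)
    stats::t.test(v[grp == "cancer"], v[grp == "control"],
                  var.equal = TRUE)$p.value)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  expect_lt(mean(p < 0.05), 0.15)
})

test_that("planted log2 fold changes are recovered at large n", {
  cfg <- generator_config(n_control = 2000, n_cancer = 2000, n_lipids = 30,
                          n_classes = 3, n_informative = 10,
                          effect_log2fc = 1, within_class_corr = 0,
                          sigma_bio = 1, sigma_tech_ev = 0.2,
                          sigma_tech_plasma = 0.1, batch_sd = 0,
                          n_batches = 1, seed = 21)
  sim <- simulate_cohort(cfg)
  lg <- log_transform(sim$table)
  tab <- ft_study(lg)
  grp <- tab$sample_meta$group
  diffs <- colMeans(tab$values[grp == "cancer", ]) -
    colMeans(tab$values[grp == "control", ])
  inf <- sim$truth$informative_lipids
  expect_true(all(abs(diffs[inf] - 1) < 0.1))
  expect_true(all(abs(diffs[setdiff(colnames(tab$values), inf)]) < 0.1))
})

test_that("matched pair shares biology and differs by scale and noise", {
  cfg0 <- tiny_config(seed = 6, sigma_tech_ev = 0, sigma_tech_plasma = 0,
                      plasma_scale = 2)
  mp <- simulate_matched_pair(cfg0)
  # no technical noise: plasma is exactly scale x EV, per-subject r = 1
  expect_equal(unname(mp$plasma$values), unname(2 * mp$ev$values),
               tolerance = 1e-12)
  sc <- subject_correlation(mp$ev, mp$plasma,
                            colnames(mp$ev$values)[1:10])
  expect_true(all(abs(sc$per_subject$r - 1) < 1e-9))

  # defaults: biology dominates technical noise, median r > 0.9
  mp2 <- simulate_matched_pair(tiny_config(seed = 8, n_lipids = 60,
                                           n_classes = 6))
  sc2 <- subject_correlation(mp2$ev, mp2$plasma,
                             colnames(mp2$ev$values))
  expect_gt(stats::median(sc2$per_subject$r), 0.9)

  # plasma_scale shows up as the ratio of per-lipid means
  ratio <- colMeans(ft_study(mp2$plasma)$values) /
    colMeans(ft_study(mp2$ev)$values)
  expect_equal(unname(stats::median(ratio)), 4, tolerance = 0.2)
})

test_that("analytic Bayes AUC matches its closed forms", {
  base <- list(n_control = 10, n_cancer = 10, n_lipids = 20, n_classes = 4,
               within_class_corr = 0, sigma_bio = 1, sigma_tech_ev = 0,
               sigma_tech_plasma = 0, batch_sd = 0, seed = 5)
  cfg0 <- do.call(generator_config, c(base, list(n_informative = 0)))
  expect_equal(analytic_bayes_auc(cfg0), 0.5)

  cfg1 <- do.call(generator_config,
                  c(base, list(n_informative = 1, effect_log2fc = 1)))
  expect_equal(analytic_bayes_auc(cfg1), stats::pnorm(1 / sqrt(2)),
               tolerance = 1e-12)

  cfg2 <- do.call(generator_config,
                  c(base, list(n_informative = 2, effect_log2fc = 1)))
  expect_equal(analytic_bayes_auc(cfg2), stats::pnorm(1),
               tolerance = 1e-12)

  # explicit covariance route and its error path
  expect_equal(analytic_bayes_auc(delta = c(1, 0),
                                  Sigma = diag(2)),
               stats::pnorm(1 / sqrt(2)))
  expect_error(analytic_bayes_auc(delta = c(1, 1),
                                  Sigma = matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("empirical AUC of the exact Bayes rule matches the oracle", {
  cfg <- generator_config(n_control = 5000, n_cancer = 5000, n_lipids = 40,
                          n_classes = 4, n_informative = 8,
                          effect_log2fc = 0.8, within_class_corr = 0.3,
                          sigma_bio = 1, sigma_tech_ev = 0.3,
                          sigma_tech_plasma = 0.1, batch_sd = 0,
                          n_batches = 1, seed = 17)
  sim <- simulate_cohort(cfg)
  lg <- log_transform(sim$table)
  tab <- ft_study(lg)
  schema <- tab$lipid_meta
  # rebuild the model covariance independently and apply the Bayes rule
  delta <- stats::setNames(numeric(nrow(schema)), schema$lipid_id)
  delta[sim$truth$informative_lipids] <- sim$truth$effect_map
  cls <- schema$lipid_class
  S <- matrix(0, nrow(schema), nrow(schema))
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    S[idx, idx] <- 0.3 * 1
    diag(S)[idx] <- 1 + 0.3^2
  }
  diag(S) <- 1 + 0.3^2
  w <- solve(S, delta)
  scores <- tab$values %*% w
  emp <- auc_mw(as.numeric(scores), tab$sample_meta$group)
  expect_lt(abs(emp - analytic_bayes_auc(cfg)), 0.02)
})

test_that("truth serializes to JSON faithfully", {
  sim <- simulate_cohort(tiny_config(seed = 2))
  path <- tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$informative_lipids, sim$truth$informative_lipids)
  expect_equal(unlist(back$effect_map),
               sim$truth$effect_map[names(unlist(back$effect_map))])
})
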