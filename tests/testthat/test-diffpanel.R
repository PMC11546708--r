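test_that("single-cohort F test equals the squared pooled t test", {
  set.seed(2)
  v <- matrix(stats::rnorm(6 * 4, 10), 6, 4)
  tab <- mini_table(v, group = rep(c("control", "cancer"), 3),
                    log_flag = TRUE)
  da <- da_test(tab, blocking = character(0))
  pt <- apply(v, 2, function(col)
    stats::t.test(col[c(2, 4, 6)], col[c(1, 3, 5)],
                  var.equal = TRUE)$p.value)
  expect_equal(da$p, unname(pt), tolerance = 1e-10)
})

test_that("fold changes are geometric-mean ratios with sane edge cases", {
  v <- rbind(matrix(1, 3, 2), matrix(1, 3, 2))
  v[4:6, 2] <- 2  # +1 on log2 scale for cancer
  tab <- mini_table(log2(matrix(2^v, 6, 2)),
                    group = rep(c("control", "cancer"), each = 3),
                    log_flag = TRUE)
  da <- suppressWarnings(da_test(tab, blocking = character(0)))
  expect_equal(da$fc[2], 2.0)
  expect_equal(da$fc[1], 1.0)  # identical group means, constant column
  expect_equal(da$p[1], 1)

  cfg <- generator_config(n_control = 2000, n_cancer = 2000,
                          n_lipids = 20, n_classes = 2, n_informative = 5,
                          effect_log2fc = 1, within_class_corr = 0,
                          batch_sd = 0, n_batches = 1, seed = 31)
  sim <- simulate_cohort(cfg)
  da2 <- da_test(log_transform(sim$table), blocking = character(0))
  fcs <- da2$fc[match(sim$truth$informative_lipids, da2$lipid_id)]
  expect_true(all(fcs > 1.9 & fcs < 2.1))
})

test_that("mixed-effect variant agrees with the fixed model direction", {
  tc <- tiny_cohort(seed = 40, n_batches = 3)
  fixed <- da_test(tc$log2, blocking = "batch")
  mixed <- da_test(tc$log2, blocking = character(0), method = "mixed")
  inf <- tc$truth$informative_lipids
  expect_gt(stats::cor(fixed$log2fc, mixed$log2fc), 0.99)
  expect_true(all(mixed$q[match(inf, mixed$lipid_id)] < 0.05))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  bh_brute <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      j <- which(o == i)  # rank of p[i]
      q[i] <- min(1, min(p[o][seq(j, m)] * m / seq(j, m)))
    }
    q
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(77)
  for (i in 1:40) {
    p <- stats::runif(25)
    expect_equal(bh_adjust(p), bh_brute(p))
  }
  p_big <- stats::runif(1000)
  expect_equal(bh_adjust(p_big), bh_brute(p_big))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("panel selection honours FC/FDR thresholds and isomers", {
  schema <- data.frame(
    lipid_id = paste0("L", 1:5), lipid_class = "PC",
    annotation = "PC 34:2", mz = c(1, 2, 3, 3, 4),
    isomer_group = c("A", "B", "C", "C", "D"))
  da <- structure(data.frame(
    lipid_id = paste0("L", 1:5),
    fc = c(1.3, 0.70, 1.5, 1.01, 1.19),
    log2fc = log2(c(1.3, 0.70, 1.5, 1.01, 1.19)),
    p = c(0.001, 0.001, 0.001, 0.9, 0.001),
    q = c(0.04, 0.04, 0.04, 0.95, 0.04)),
    class = c("da_result", "data.frame"))
  panel <- select_panel(da, schema)
  expect_true(all(c("L1", "L2", "L3") %in% panel$lipid_id))
  # L2: decreased lipid (1/0.70 > 1.2) selected
  expect_true(panel$da_selected[panel$lipid_id == "L2"])
  # L4 fails both filters but is L3's isomer mate
  expect_true(panel$isomer_included[panel$lipid_id == "L4"])
  # L5 passes FDR but FC 1.19 <= 1.2
  expect_false("L5" %in% panel$lipid_id)

  # monotone: relaxing thresholds never drops a lipid
  relaxed <- select_panel(da, schema, fc_min = 1.1, q_max = 0.2)
  expect_true(all(panel$lipid_id %in% relaxed$lipid_id))
})

test_that("stepwise m/z restriction keeps informative groups", {
  set.seed(8)
  n <- 200
  y <- rep(c("control", "cancer"), each = n / 2)
  strong <- matrix(stats::rnorm(n * 5), n, 5) +
    outer(y == "cancer", rep(1, 5))
  noise <- matrix(stats::rnorm(n * 13), n, 13)
  v <- cbind(strong, noise)
  colnames(v) <- sprintf("L%02d", seq_len(ncol(v)))
  colnames(strong) <- colnames(v)[1:5]
  mz <- c(1:5, 6:18)  # one group per lipid
  tab <- mini_table(v, group = y, mz = mz, log_flag = TRUE)
  panel <- structure(data.frame(
    lipid_id = colnames(v), da_selected = TRUE, isomer_included = FALSE),
    class = c("panel_spec", "data.frame"))
  kept <- stepwise_restrict(tab, panel)
  expect_true(all(colnames(v)[1:5] %in% kept$lipid_id))
  expect_lt(nrow(kept), 12)

  # duplicate lipid sharing values and m/z group: same groups retained
  v2 <- cbind(v, dup = v[, 1])
  tab2 <- mini_table(v2, group = y, mz = c(mz, 1), log_flag = TRUE)
  panel2 <- structure(data.frame(
    lipid_id = colnames(v2), da_selected = TRUE, isomer_included = FALSE),
    class = c("panel_spec", "data.frame"))
  kept2 <- stepwise_restrict(tab2, panel2)
  mzg <- function(k, t) sort(unique(t$lipid_meta$mz[
    match(k$lipid_id, t$lipid_meta$lipid_id)]))
  expect_equal(mzg(kept2, tab2), mzg(kept, tab))

  # a single strongly informative group is retained unchanged
  tab1 <- mini_table(strong, group = y, mz = rep(1, 5), log_flag = TRUE)
  panel1 <- structure(data.frame(
    lipid_id = colnames(strong), da_selected = TRUE,
    isomer_included = FALSE), class = c("panel_spec", "data.frame"))
  expect_setequal(stepwise_restrict(tab1, panel1)$lipid_id,
                  colnames(strong))
})

test_that("Mann-Whitney AUC equals brute-force concordance with ties", {
  auc_brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b)
      (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  s <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.8, 0.2, 0.9, 0.5, 0.4, 0.7, 0.1)
  y <- c(0, 0, 1, 0, 1, 0, 0, 1, 1, 1, 1, 0)
  expect_equal(auc_mw(s, y), auc_brute(s, y))
  set.seed(3)
  for (i in 1:50) {
    y <- sample(0:1, 20, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.1), 20, replace = TRUE)  # forces ties
    expect_equal(auc_mw(s, y), auc_brute(s, y))
  }
})

test_that("threshold optimization matches exhaustive search", {
  thr <- optimize_threshold(c(0.1, 0.9), c(0, 1))
  expect_equal(thr, 0.5)
  expect_equal(mean((c(0.1, 0.9) > thr) == c(0, 1)), 1)

  # all scores equal: sentinel side chosen by the tie rule (smallest),
  # predicting everything cancer; accuracy = prevalence
  s <- rep(0.4, 10); y <- c(rep(1, 7), rep(0, 3))
  thr2 <- optimize_threshold(s, y)
  expect_lt(thr2, 0.4)
  expect_equal(mean((s > thr2) == y), 0.7)

  brute_best <- function(s, y) {
    cand <- c(sort(unique(s)) - 1e-9, sort(unique(s)) + 1e-9)
    max(vapply(cand, function(t) mean((s > t) == y), numeric(1)))
  }
  set.seed(9)
  for (i in 1:500) {
    n <- sample(5:25, 1)
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(stats::runif(n), 2)
    t_opt <- optimize_threshold(s, y)
    expect_equal(mean((s > t_opt) == y), brute_best(s, y))
  }
})

test_that("LOOCV logistic separates a clean fixture and stays honest", {
  tc <- tiny_cohort(seed = 51, effect_log2fc = 3, n_informative = 3)
  panel <- tc$truth$informative_lipids
  res <- suppressWarnings(loocv_logistic(tc$log2, panel))
  expect_equal(res$auc, 1.0)
  expect_equal(res$accuracy, 1.0)
  # confusion identities
  tab <- ft_study(tc$log2)
  expect_equal(unname(res$confusion["TP"] + res$confusion["FN"]),
               sum(tab$sample_meta$group == "cancer"))
  expect_equal(unname(res$confusion["TN"] + res$confusion["FP"]),
               sum(tab$sample_meta$group == "control"))
  expect_true(all(res$scores >= 0 & res$scores <= 1))
})

test_that("LOOCV logistic is calibrated under permuted labels", {
  tc <- tiny_cohort(seed = 52, n_control = 50, n_cancer = 50,
                    n_lipids = 20, n_informative = 0)
  tab <- ft_study(tc$log2)
  set.seed(100)
  aucs <- replicate(60, {
    y <- sample(tab$sample_meta$group)
    suppressWarnings(loocv_logistic(tc$log2, colnames(tab$values)[1:5],
                                    labels = y)$auc)
  })
  expect_gt(mean(aucs), 0.40)
  expect_lt(mean(aucs), 0.60)
})

test_that("per-subject correlation follows closed forms", {
  v <- matrix(c(1, 2, 3,
                4, 5, 7), nrow = 2, byrow = TRUE)
  rownames(v) <- c("S1", "S2")
  colnames(v) <- c("L1", "L2", "L3")
  ev <- mini_table(log2(2^v), log_flag = TRUE)
  pl2 <- mini_table(v + 1, log_flag = TRUE)   # shifted: r = 1
  sc <- subject_correlation(ev, pl2, c("L1", "L2", "L3"))
  expect_true(all(abs(sc$per_subject$r - 1) < 1e-12))

  rev <- mini_table(10 - v, log_flag = TRUE)  # reversed: r = -1
  sc2 <- subject_correlation(ev, rev, c("L1", "L2", "L3"))
  expect_true(all(abs(sc2$per_subject$r + 1) < 1e-12))

  # hand-computed Pearson r for (1,2,3) vs (2,4,7):
  # cov = 2.5, sd_x = 1, sd_y = sqrt(19/3); r = 2.5/sqrt(19/3)
  v3 <- rbind(c(2, 4, 7), c(2, 4, 7))
  dimnames(v3) <- dimnames(v)
  pl3 <- mini_table(v3, log_flag = TRUE)
  sc3 <- subject_correlation(ev, pl3, c("L1", "L2", "L3"))
  expect_equal(sc3$per_subject$r[sc3$per_subject$subject_id == "S1"],
               2.5 / sqrt(19 / 3), tolerance = 1e-12)
  expect_error(subject_correlation(ev, pl3, c("L1", "L2")), "3 panel")
})
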