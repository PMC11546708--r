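#' Build a synthetic lipid annotation schema
#'
#' Creates a table of lipid species spread over lipid classes, with
#' sum-composition annotations, m/z values and isomer groups. Isomeric
#' species (same annotation, same m/z, distinguishable only by
#' chromatography) are emulated by assigning a fraction of lipids to
#' multi-member isomer groups.
#'
#' @param n_lipids Number of lipid species.
#' @param n_classes Number of lipid classes (at most `n_lipids`).
#' @param isomer_rate Fraction in `[0, 1)` of lipids placed in
#'   multi-member isomer groups.
#' @param seed Integer seed; the schema is fully reproducible.
#' @return A data frame with columns `lipid_id`, `lipid_class`,
#'   `annotation`, `mz`, `isomer_group`. Members of an isomer group share
#'   class, annotation and m/z.
#' @export
#' @examples
#' s <- build_lipid_schema(454, 15)
#' table(s$lipid_class)
build_lipid_schema <- function(n_lipids, n_classes, isomer_rate = 0,
                               seed = 1) {
  if (n_lipids < 1 || n_classes < 1 || n_classes > n_lipids)
    stop("invalid counts: need 1 <= n_classes <= n_lipids")
  if (isomer_rate < 0 || isomer_rate >= 1)
    stop("isomer_rate must be in [0, 1)")
  class_pool <- c("TG", "PC", "LPC", "PE", "SM", "DG", "CE", "Cer", "PS",
                  "PG", "PI", "PA", "LPE", "HexCer", "FA")
  cls_names <- if (n_classes <= length(class_pool)) class_pool[seq_len(n_classes)]
               else c(class_pool, paste0("CL", seq_len(n_classes - length(class_pool))))
  # typical plasma class m/z centres (Da), recycled if more classes
  mz_centre <- rep_len(c(850, 780, 510, 740, 760, 600, 650, 560, 790,
                         770, 860, 700, 480, 720, 300), n_classes)
  with_rng(seed, {
    # skewed class sizes (TG/PC dominate a plasma lipidome), each >= 1
    w <- sort(stats::rexp(n_classes) + 0.15, decreasing = TRUE)
    sizes <- pmax(1L, as.integer(round(w / sum(w) * n_lipids)))
    while (sum(sizes) != n_lipids) {
      i <- if (sum(sizes) > n_lipids) which.max(sizes) else which.min(sizes)
      sizes[i] <- sizes[i] + sign(n_lipids - sum(sizes))
    }
    lipid_class <- rep(cls_names, sizes)
    carbons <- 2L * sample(12:30, n_lipids, replace = TRUE)
    dbonds <- sample(0:8, n_lipids, replace = TRUE)
    annotation <- sprintf("%s %d:%d", lipid_class, carbons, dbonds)
    mz <- round(mz_centre[match(lipid_class, cls_names)] +
                  stats::rnorm(n_lipids, 0, 60), 4)
    isomer_group <- sprintf("IG%04d", seq_len(n_lipids))
    n_iso <- round(isomer_rate * n_lipids)
    if (n_iso >= 2) {
      # pair off lipids of the same class into shared groups
      cand <- sample(n_lipids)
      cand <- cand[order(lipid_class[cand])]
      picked <- cand[seq_len(2L * (n_iso %/% 2L))]
      for (k in seq_len(length(picked) %/% 2L)) {
        a <- picked[2L * k - 1L]; b <- picked[2L * k]
        isomer_group[b] <- isomer_group[a]
        annotation[b] <- annotation[a]
        mz[b] <- mz[a]
        lipid_class[b] <- lipid_class[a]
      }
    }
    data.frame(lipid_id = sprintf("LID%04d", seq_len(n_lipids)),
               lipid_class = lipid_class, annotation = annotation, mz = mz,
               isomer_group = isomer_group, stringsAsFactors = FALSE)
  })
}

#' Synthetic cohort generator configuration
#'
#' Bundles and validates the parameters of the synthetic lipidomics
#' cohort: a two-group design with class-correlated log-normal
#' abundances, a planted discriminative lipid subset, per-batch
#' multiplicative effects, pooled-reference QC replicates, and matched
#' EV/plasma measurements differing in concentration scale and technical
#' noise. All effect sizes and standard deviations are on the log2
#' scale; generated tables are on the linear concentration scale.
#'
#' @param n_control,n_cancer Group sizes.
#' @param n_lipids,n_classes,isomer_rate Passed to [build_lipid_schema()].
#' @param n_informative Number of lipids with a planted group effect.
#' @param effect_log2fc Planted log2 fold change (scalar or one value per
#'   informative lipid).
#' @param within_class_corr Correlation in `[0, 1)` between lipids of one
#'   class (one-factor model).
#' @param sigma_bio Biological log2-scale SD shared by both sample types.
#' @param sigma_tech_plasma,sigma_tech_ev Technical log2-scale SDs;
#'   EV measurements are noisier than plasma.
#' @param plasma_scale Multiplicative concentration factor (> 1) applied
#'   to plasma relative to EV.
#' @param n_batches Number of analytical batches.
#' @param batch_sd Log2-scale SD of per-(batch, lipid) multiplicative
#'   factors.
#' @param n_qc_replicates_per_batch QC pool replicates injected per batch.
#' @param seed Integer root seed.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_control = 128, n_cancer = 128,
                             n_lipids = 454, n_classes = 15,
                             n_informative = 10, effect_log2fc = 1,
                             within_class_corr = 0.3, sigma_bio = 1,
                             sigma_tech_plasma = 0.15, sigma_tech_ev = 0.35,
                             plasma_scale = 4, n_batches = 4,
                             batch_sd = 0.2, n_qc_replicates_per_batch = 5,
                             isomer_rate = 0.05, seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_control = n_control, n_cancer = n_cancer,
              n_lipids = n_lipids, n_classes = n_classes,
              n_batches = n_batches,
              n_qc_replicates_per_batch = n_qc_replicates_per_batch)
  if (any(counts < 1)) stop("count fields must be >= 1: ",
                            paste(names(counts)[counts < 1], collapse = ", "))
  if (n_informative > n_lipids) stop("n_informative exceeds n_lipids")
  if (n_informative < 0) stop("n_informative must be >= 0")
  sds <- c(sigma_bio, sigma_tech_plasma, sigma_tech_ev, batch_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (sigma_tech_ev < sigma_tech_plasma)
    stop("sigma_tech_ev must be >= sigma_tech_plasma")
  if (within_class_corr < 0 || within_class_corr >= 1)
    stop("within_class_corr must be in [0, 1)")
  if (plasma_scale <= 0) stop("plasma_scale must be > 0")
  if (!length(effect_log2fc) %in% c(1L, max(1L, n_informative)))
    stop("effect_log2fc must be scalar or length n_informative")
  class(cfg) <- "generator_config"
  cfg
}

# Draw everything shared between the EV and plasma measurements of one
# cohort: design, planted truth, per-sample biological log2 profiles,
# batch factors and the QC pool reference. Deterministic in config$seed.
draw_biology <- function(config, schema) {
  stopifnot(inherits(config, "generator_config"))
  if (nrow(schema) != config$n_lipids)
    stop("schema size does not match config$n_lipids")
  p <- config$n_lipids
  n <- config$n_control + config$n_cancer
  cls <- match(schema$lipid_class, unique(schema$lipid_class))
  with_rng(substream_seed(config$seed, "biology"), {
    informative <- sort(sample.int(p, config$n_informative))
    effects <- rep_len(config$effect_log2fc, length(informative))
    mu_class <- stats::rnorm(max(cls), mean = 6, sd = 1.5)
    mu <- mu_class[cls] + stats::rnorm(p, 0, 1)
    group <- rep(c("control", "cancer"), c(config$n_control, config$n_cancer))
    # round-robin within group => groups balanced per batch
    batch <- integer(n)
    batch[group == "control"] <- rep_len(seq_len(config$n_batches),
                                         config$n_control)
    batch[group == "cancer"] <- rep_len(seq_len(config$n_batches),
                                        config$n_cancer)
    cohort <- paste0("C", 1L + (batch > ceiling(config$n_batches / 2)))
    rho <- config$within_class_corr
    z <- matrix(stats::rnorm(n * max(cls)), n, max(cls))
    eps <- matrix(stats::rnorm(n * p), n, p)
    bio <- matrix(mu, n, p, byrow = TRUE) +
      config$sigma_bio * (sqrt(rho) * z[, cls, drop = FALSE] +
                            sqrt(1 - rho) * eps)
    delta <- numeric(p)
    delta[informative] <- effects
    bio <- bio + outer(group == "cancer", delta)
    batch_log2 <- matrix(stats::rnorm(config$n_batches * p, 0,
                                      config$batch_sd),
                         config$n_batches, p)
    list(informative = informative, effects = effects, mu = mu,
         group = group, batch = batch, cohort = cohort, bio = bio,
         batch_log2 = batch_log2)
  })
}

# Assemble one measured table (EV or plasma) from shared biology plus
# sample-type-specific technical noise and concentration scale.
measure_cohort <- function(config, schema, bio, sample_type) {
  p <- config$n_lipids
  n <- nrow(bio$bio)
  sigma_tech <- switch(sample_type, ev = config$sigma_tech_ev,
                       plasma = config$sigma_tech_plasma,
                       stop("sample_type must be 'ev' or 'plasma'"))
  scale_log2 <- if (sample_type == "plasma") log2(config$plasma_scale) else 0
  nqc <- config$n_qc_replicates_per_batch * config$n_batches
  with_rng(substream_seed(config$seed, paste0("tech_", sample_type)), {
    logx <- bio$bio + bio$batch_log2[bio$batch, , drop = FALSE] +
      matrix(stats::rnorm(n * p, 0, sigma_tech), n, p) + scale_log2
    qc_batch <- rep(seq_len(config$n_batches),
                    each = config$n_qc_replicates_per_batch)
    logq <- matrix(bio$mu, nqc, p, byrow = TRUE) +
      bio$batch_log2[qc_batch, , drop = FALSE] +
      matrix(stats::rnorm(nqc * p, 0, sigma_tech), nqc, p) + scale_log2
    vals <- 2^rbind(logx, logq)
    sample_id <- c(sprintf("S%03d_%s", seq_len(n), sample_type),
                   sprintf("QC%02d_%s", seq_len(nqc), sample_type))
    rownames(vals) <- sample_id
    colnames(vals) <- schema$lipid_id
    smeta <- data.frame(
      sample_id = sample_id,
      subject_id = c(sprintf("SUBJ%03d", seq_len(n)), rep(NA_character_, nqc)),
      group = c(bio$group, rep(NA_character_, nqc)),
      cohort = c(bio$cohort, paste0("C", 1L + (qc_batch >
                                                 ceiling(config$n_batches / 2)))),
      batch = c(bio$batch, qc_batch),
      qc = c(rep(FALSE, n), rep(TRUE, nqc)),
      sample_type = sample_type,
      stringsAsFactors = FALSE)
    feature_table(vals, smeta, schema, log_flag = FALSE)
  })
}

make_truth <- function(config, schema, bio) {
  ids <- schema$lipid_id[bio$informative]
  structure(list(
    informative_lipids = ids,
    effect_map = stats::setNames(bio$effects, ids),
    batch_factors = {
      m <- 2^bio$batch_log2
      dimnames(m) <- list(paste0("batch", seq_len(nrow(m))), schema$lipid_id)
      m
    }), class = "synthetic_truth")
}

#' Simulate one synthetic lipidomics cohort
#'
#' Draws a two-group cohort under a per-class one-factor Gaussian model
#' on the log2 scale: lipids of one class share a latent factor
#' (correlation `within_class_corr`), cancer samples are shifted by the
#' planted log2 fold changes on the informative lipids, per-(batch,
#' lipid) multiplicative factors and technical noise are applied, and QC
#' replicates are re-noised copies of a fixed pooled-reference profile
#' injected into every batch. Groups are balanced within batch.
#'
#' @param config A [generator_config()].
#' @param schema Optional schema from [build_lipid_schema()]; generated
#'   from the config when omitted.
#' @param sample_type `"ev"` or `"plasma"`; plasma is scaled up by
#'   `plasma_scale` and carries lower technical noise.
#' @return A list with elements `table` (a linear-scale
#'   [feature_table()]) and `truth` (the planted ground truth:
#'   `informative_lipids`, `effect_map`, `batch_factors`).
#' @export
#' @examples
#' cfg <- generator_config(n_control = 20, n_cancer = 20, n_lipids = 40,
#'                         n_classes = 5, seed = 7)
#' sim <- simulate_cohort(cfg)
#' sim$table
simulate_cohort <- function(config, schema = NULL,
                            sample_type = c("ev", "plasma")) {
  sample_type <- match.arg(sample_type)
  if (is.null(schema))
    schema <- build_lipid_schema(config$n_lipids, config$n_classes,
                                 config$isomer_rate,
                                 seed = substream_seed(config$seed, "schema"))
  bio <- draw_biology(config, schema)
  list(table = measure_cohort(config, schema, bio, sample_type),
       truth = make_truth(config, schema, bio))
}

#' Simulate matched EV and plasma measurements of one cohort
#'
#' Both tables share the same per-subject biological lipid profiles and
#' batch factors; they differ only by the plasma concentration scale and
#' independent technical noise per sample type, so the per-subject
#' cross-table correlation is high when biological variation dominates
#' technical noise. Subject identifiers match across tables.
#'
#' @inheritParams simulate_cohort
#' @return A list with elements `ev`, `plasma` (both [feature_table()])
#'   and `truth`.
#' @export
simulate_matched_pair <- function(config, schema = NULL) {
  if (is.null(schema))
    schema <- build_lipid_schema(config$n_lipids, config$n_classes,
                                 config$isomer_rate,
                                 seed = substream_seed(config$seed, "schema"))
  bio <- draw_biology(config, schema)
  list(ev = measure_cohort(config, schema, bio, "ev"),
       plasma = measure_cohort(config, schema, bio, "plasma"),
       truth = make_truth(config, schema, bio))
}

#' Closed-form Bayes-optimal AUC of the generator
#'
#' Under the generator's equal-covariance Gaussian model on the log2
#' scale, the optimal classifier is linear and its AUC is
#' `pnorm(Delta / sqrt(2))`, where `Delta` is the Mahalanobis distance
#' between the two group means. The covariance combines the biological
#' one-factor class blocks (equicorrelation `within_class_corr` scaled by
#' `sigma_bio^2`) with diagonal technical and batch variance; the
#' block-diagonal structure lets `Delta` be computed exactly from the
#' classes containing informative lipids.
#'
#' @inheritParams simulate_cohort
#' @param truth Optional planted truth (from [simulate_cohort()]);
#'   re-derived from the config when omitted.
#' @param delta,Sigma Optional explicit mean-difference vector and
#'   covariance matrix, overriding the config-derived model.
#' @return The Bayes AUC, a number in `[0.5, 1]`.
#' @export
#' @examples
#' cfg <- generator_config(n_informative = 1, effect_log2fc = 1,
#'                         sigma_bio = 1, sigma_tech_ev = 0,
#'                         sigma_tech_plasma = 0, batch_sd = 0,
#'                         within_class_corr = 0)
#' analytic_bayes_auc(cfg)  # pnorm(1 / sqrt(2)) ~= 0.7602
analytic_bayes_auc <- function(config = NULL, schema = NULL, truth = NULL,
                               sample_type = c("ev", "plasma"),
                               delta = NULL, Sigma = NULL) {
  sample_type <- match.arg(sample_type)
  if (!is.null(delta) && !is.null(Sigma)) {
    ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("covariance must be positive definite")
    d2 <- drop(crossprod(delta, solve(Sigma, delta)))
    return(stats::pnorm(sqrt(d2) / sqrt(2)))
  }
  stopifnot(inherits(config, "generator_config"))
  if (is.null(schema))
    schema <- build_lipid_schema(config$n_lipids, config$n_classes,
                                 config$isomer_rate,
                                 seed = substream_seed(config$seed, "schema"))
  if (is.null(truth)) {
    bio <- draw_biology(config, schema)
    truth <- make_truth(config, schema, bio)
  }
  if (length(truth$informative_lipids) == 0) return(0.5)
  sigma_tech <- switch(sample_type, ev = config$sigma_tech_ev,
                       plasma = config$sigma_tech_plasma)
  diag_extra <- sigma_tech^2 + config$batch_sd^2
  rho <- config$within_class_corr
  sb2 <- config$sigma_bio^2
  d_all <- stats::setNames(numeric(config$n_lipids), schema$lipid_id)
  d_all[truth$informative_lipids] <- truth$effect_map
  d2 <- 0
  for (cl in unique(schema$lipid_class[d_all[schema$lipid_id] != 0])) {
    idx <- schema$lipid_class == cl
    m <- sum(idx)
    S <- matrix(rho * sb2, m, m)
    diag(S) <- sb2 + diag_extra
    dd <- d_all[schema$lipid_id[idx]]
    d2 <- d2 + drop(crossprod(dd, solve(S, dd)))
  }
  stats::pnorm(sqrt(d2) / sqrt(2))
}

#' Serialize planted ground truth to JSON
#' @param truth A `synthetic_truth` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(
    informative_lipids = truth$informative_lipids,
    effect_map = as.list(truth$effect_map),
    batch_factors = apply(truth$batch_factors, 1, as.list, simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
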