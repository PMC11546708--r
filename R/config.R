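#' Pipeline configuration
#'
#' Builds and validates the single declarative configuration driving the
#' whole pipeline. All randomness flows from the mandatory root `seed`
#' through named per-stage sub-streams ([substream_seed()]), so any
#' stage can be reproduced in isolation.
#'
#' @param config A named list, or a path to a YAML or JSON file holding
#'   one.
#' @return A validated list of class `pipeline_config` with all defaults
#'   filled in.
#' @export
#' @examples
#' cfg <- pipeline_config(list(seed = 1, output_dir = tempfile()))
#' cfg$splits$n_iter
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  defaults <- list(
    seed = NULL,
    output_dir = "lipidscreen_output",
    input_base = NULL,            # read tables instead of simulating
    generator = list(),           # overrides for generator_config()
    preprocess = list(pseudo = 0, normalize = TRUE),
    da_panel = list(fc_min = 1.2, q_max = 0.05, blocking = "cohort",
                    stepwise = TRUE),
    boruta = list(n_iter = 100, n_trees = 500,
                  alpha = 0.01, importance_kind = "permutation_z",
                  mtry = NULL, max_depth = NULL),
    splits = list(n_iter = 2000, test_fraction = 0.2, stratified = TRUE),
    tuning = list(tune_len = 10, n_nested = 50),
    classifiers = names(default_classifiers()),
    signature_size = 20,
    sensitivity_sizes = 14:30)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  check_num <- function(x, key, lo, hi, int = FALSE) {
    if (is.null(x) || !is.numeric(x) || any(x < lo) || any(x > hi) ||
        (int && any(x != round(x))))
      stop("config key '", key, "' must be ",
           if (int) "an integer " else "a number ",
           "in [", lo, ", ", hi, "]")
  }
  if (is.null(cfg$seed)) stop("config key 'seed' is mandatory")
  check_num(cfg$seed, "seed", 0, 2^31 - 1, int = TRUE)
  check_num(cfg$splits$test_fraction, "splits.test_fraction",
            1e-9, 1 - 1e-9)
  check_num(cfg$splits$n_iter, "splits.n_iter", 1, 1e6, int = TRUE)
  check_num(cfg$boruta$n_iter, "boruta.n_iter", 1, 1e5, int = TRUE)
  check_num(cfg$boruta$n_trees, "boruta.n_trees", 1, 1e5, int = TRUE)
  check_num(cfg$boruta$alpha, "boruta.alpha", 1e-12, 1 - 1e-12)
  check_num(cfg$tuning$tune_len, "tuning.tune_len", 1, 1e4, int = TRUE)
  check_num(cfg$tuning$n_nested, "tuning.n_nested", 1, 1e5, int = TRUE)
  check_num(cfg$signature_size, "signature_size", 1, 1e4, int = TRUE)
  check_num(cfg$sensitivity_sizes, "sensitivity_sizes", 1, 1e4, int = TRUE)
  check_num(cfg$da_panel$fc_min, "da_panel.fc_min", 1, 100)
  check_num(cfg$da_panel$q_max, "da_panel.q_max", 1e-12, 1)
  check_num(cfg$preprocess$pseudo, "preprocess.pseudo", 0, Inf)
  bad <- setdiff(cfg$classifiers, names(default_classifiers()))
  if (length(bad)) stop("config key 'classifiers' names unknown model(s): ",
                        paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

# Stable hash of a config, invariant to key order.
config_hash <- function(cfg) {
  fnv1a_hex(canonical_json(unclass(cfg)))
}

manifest_path <- function(cfg) file.path(cfg$output_dir, "run_manifest.json")

# Append a stage entry (files written, timestamp) to the run manifest.
manifest_append <- function(cfg, stage, files) {
  path <- manifest_path(cfg)
  man <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list(config_hash = config_hash(cfg),
         package_version = as.character(utils::packageVersion("lipidscreen")),
         seed = cfg$seed, stages = list())
  }
  man$stages[[stage]] <- list(timestamp = format(Sys.time(), tz = "UTC"),
                              files = as.list(basename(files)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
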