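#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a root seed
#'
#' All randomness in the package flows from one root seed. Each stage
#' (generator, split plan, feature selection, tuning, ...) draws its own
#' seed from the root via a stable string hash, so stages can be re-run
#' in isolation and adding a stage never perturbs the streams of the
#' others.
#'
#' @param seed Integer root seed.
#' @param label Character label naming the sub-stream.
#' @return An integer in `[0, 2^31 - 1)`, usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(1, "splits")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  # polynomial rolling hash over the label bytes, folded with the seed;
  # double arithmetic stays exact (< 2^53), result kept below 2^31
  h <- 2166136261
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2^32
  as.integer((h + abs(seed) * 48271) %% (2^31 - 1))
}

#' Geometric mean
#' @param x Positive numeric vector.
#' @param na.rm Drop missing values first.
#' @return The geometric mean of `x`.
#' @export
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Stable 32-bit rolling hash of a character scalar, as hex. Used for the
# run-manifest config hash; keys are canonicalized (sorted) before hashing
# so the hash is invariant to key order.
fnv1a_hex <- function(txt) {
  h <- 2166136261
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2^32
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Canonical JSON for hashing: keys sorted recursively, no whitespace.
canonical_json <- function(x) {
  sort_keys <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, sort_keys)
    } else if (is.list(v)) {
      lapply(v, sort_keys)
    } else v
  }
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA))
}

# Evaluate expr with a local RNG state: seeds, runs, restores global state.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
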