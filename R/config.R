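#' Analysis configuration
#'
#' Bundles every tunable of the pipeline: the sparsity grid used to binarize
#' connectivity matrices, the null-network ensemble size and rewiring effort,
#' the permutation count and FDR level for group inference, and the temporal
#' cleanup parameters (volumes discarded for magnetization equilibration,
#' band-pass limits, repetition time).
#'
#' Defaults reproduce the canonical resting-state setup: sparsity 0.05 to
#' 0.40 in steps of 0.01 (36 levels), 100 degree-preserving null networks
#' with 10 attempted swaps per edge, 100 permutations, FDR q = 0.01,
#' 10 discarded volumes, band 0.01-0.08 Hz at TR = 2 s.
#'
#' @param sparsity_start,sparsity_stop,sparsity_step sparsity grid (fractions
#'   of possible edges kept).
#' @param n_null_networks null-ensemble size M per graph.
#' @param n_rewire_swaps_per_edge attempted double-edge swaps per edge.
#' @param n_permutations permutation count P for strength tests.
#' @param fdr_q Benjamini-Hochberg level q.
#' @param alpha nominal significance level for unadjusted tests.
#' @param discard_volumes initial volumes dropped from each time series.
#' @param band_low_hz,band_high_hz band-pass limits (exclusive) in Hz.
#' @param tr_seconds repetition time in seconds.
#' @param seed master integer seed; every stage derives its own substream.
#' @return An object of class `analysis_config` (a validated list).
#' @export
analysis_config <- function(sparsity_start = 0.05,
                            sparsity_stop = 0.40,
                            sparsity_step = 0.01,
                            n_null_networks = 100L,
                            n_rewire_swaps_per_edge = 10L,
                            n_permutations = 100L,
                            fdr_q = 0.01,
                            alpha = 0.05,
                            discard_volumes = 10L,
                            band_low_hz = 0.01,
                            band_high_hz = 0.08,
                            tr_seconds = 2.0,
                            seed = 1L) {
  cfg <- list(
    sparsity_start = as.numeric(sparsity_start),
    sparsity_stop = as.numeric(sparsity_stop),
    sparsity_step = as.numeric(sparsity_step),
    n_null_networks = as.integer(n_null_networks),
    n_rewire_swaps_per_edge = as.integer(n_rewire_swaps_per_edge),
    n_permutations = as.integer(n_permutations),
    fdr_q = as.numeric(fdr_q),
    alpha = as.numeric(alpha),
    discard_volumes = as.integer(discard_volumes),
    band_low_hz = as.numeric(band_low_hz),
    band_high_hz = as.numeric(band_high_hz),
    tr_seconds = as.numeric(tr_seconds),
    seed = as.integer(seed)
  )
  class(cfg) <- "analysis_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  with(cfg, {
    if (!(sparsity_start > 0 && sparsity_start <= sparsity_stop &&
          sparsity_stop < 1)) {
      stop("require 0 < sparsity_start <= sparsity_stop < 1", call. = FALSE)
    }
    if (sparsity_step <= 0) stop("sparsity_step must be > 0", call. = FALSE)
    if (!(band_low_hz < band_high_hz &&
          band_high_hz < 1 / (2 * tr_seconds))) {
      stop("require band_low_hz < band_high_hz < Nyquist = 1/(2*tr_seconds)",
           call. = FALSE)
    }
    if (n_permutations < 1L) stop("n_permutations must be >= 1", call. = FALSE)
    if (n_null_networks < 1L) stop("n_null_networks must be >= 1", call. = FALSE)
    if (!(fdr_q > 0 && fdr_q < 1)) stop("require 0 < fdr_q < 1", call. = FALSE)
    if (discard_volumes < 0L) stop("discard_volumes must be >= 0", call. = FALSE)
  })
  invisible(cfg)
}

#' Read an analysis configuration from a JSON file
#'
#' Keys are exactly the field names of [analysis_config()]; missing keys take
#' the defaults.
#'
#' @param path path to a JSON file.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(analysis_config, raw)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Polynomial hash of (stage name, master seed, index), folded into
# [1, 2^31 - 2]. All per-stage RNG substreams are derived this way from the
# master seed so that adding a stage never perturbs another stage's draws.
# Arithmetic stays below 2^52, exact in doubles, so the hash is portable.
stage_seed <- function(seed, stage, index = 0L) {
  p <- 2147483629 # prime below 2^31
  h <- 5381
  bytes <- c(utf8ToInt(stage), 58L,
             as.integer(seed) %% 256L, (as.integer(seed) %/% 256L) %% 256L,
             (as.integer(seed) %/% 65536L) %% 256L,
             abs(as.integer(index)) %% 256L,
             (abs(as.integer(index)) %/% 256L) %% 256L,
             (abs(as.integer(index)) %/% 65536L) %% 256L)
  for (b in bytes) h <- (h * 131 + b) %% p
  as.integer(h %% 2147483645) + 1L
}

# evaluate expr under a temporary RNG state seeded with `seed`;
# the caller's RNG state is untouched
with_stage_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

round_half_up <- function(x) floor(x + 0.5)

log_msg <- function(level, ...) {
  lv <- getOption("fcgraph.log_level", "INFO")
  ranks <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (ranks[[level]] >= ranks[[lv]]) {
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    paste0(..., collapse = "")))
  }
  invisible(NULL)
}
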