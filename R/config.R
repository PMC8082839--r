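#' Pipeline configuration
#'
#' Builds the full configuration for [design_primers()] and the individual
#' pipeline stages. Every field has a default so `pipeline_config()` with no
#' arguments is runnable; any subset can be overridden by name. Defaults
#' follow common qPCR practice (19--23 bp primers, Tm 58--62 degC, GC
#' 40--60%) and are all user-tunable.
#'
#' @param min_len,max_len Candidate primer length range in bp.
#' @param min_tm,max_tm Allowed melting-temperature range in degC
#'   (nearest-neighbor model, see [melting_temperature()]).
#' @param min_gc,max_gc Allowed GC content range in percent.
#' @param max_self_any Maximum self-complementarity score (complementary base
#'   pairs over any ungapped offset, see [comp_any()]).
#' @param max_self_end Maximum 3'-anchored self-complementarity score
#'   (see [comp_end()]).
#' @param max_run Maximum homopolymer (contiguous identical residue) run.
#' @param min_dg3 Minimum Gibbs free energy of the 3'-terminal five bases in
#'   kcal/mol; less negative = less stable end = lower mispriming risk.
#' @param max_mismatch Maximum number of mismatches `k` screened by the
#'   general cross-hybridization filter (rounds run for k = 1..max_mismatch).
#' @param trim_depth Number of 5' bases ignored when forming the 3'-anchored
#'   suffix key; clamped per primer so the suffix is never empty.
#' @param max_len_diff,max_tm_diff Pair bounds: length difference (bp) and
#'   melting temperature difference (degC) between forward and reverse primer.
#' @param min_product,max_product Allowed amplicon (product) size range in bp.
#' @param max_pair_any,max_pair_end Pair-complementarity bounds (cross-dimer
#'   scores between the two primers of a pair).
#' @param opt_len,opt_tm,opt_gc Per-primer optima used by the penalty.
#' @param w_len,w_tm,w_gc Per-primer penalty weights.
#' @param w_tmdiff,w_prod Pair penalty weights (Tm difference, product-size
#'   deviation).
#' @param opt_product Optimal product size in bp (only used when
#'   `w_prod > 0`).
#' @param n_workers Number of parallel work chunks; the output is identical
#'   for every value.
#' @param batch_size Probe rows per streamed batch (`Inf` = one batch).
#' @param percentile_k1,percentile_k2 Workload percentile splitting
#'   small-unit from large-unit key groups in rounds k = 1 and k = 2.
#' @param pair_small_pct,pair_large_pct Workload percentiles for the pairing
#'   stage's three task-granularity classes.
#' @param probe_skip_invalid If `TRUE`, probe rows whose own primer is
#'   already invalid are skipped in the 5' filter (an order-dependent
#'   shortcut; default `FALSE` keeps the result order-independent).
#' @param group_by Pairing group key: `"sid"` (default) groups primers by
#'   target sequence; `"sidset"` groups by identical target sets.
#' @param conc_primer Oligo concentration in M for the Tm model.
#' @param conc_na Monovalent cation concentration in M for the salt
#'   correction.
#' @param seed Integer RNG seed recorded in the config.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config(min_tm = 57, max_tm = 63)
#' cfg$min_tm
pipeline_config <- function(min_len = 19L, max_len = 23L,
                            min_tm = 58, max_tm = 62,
                            min_gc = 40, max_gc = 60,
                            max_self_any = 5L, max_self_end = 3L,
                            max_run = 5L, min_dg3 = -9,
                            max_mismatch = 2L, trim_depth = 4L,
                            max_len_diff = 5L, max_tm_diff = 3,
                            min_product = 100L, max_product = 250L,
                            max_pair_any = 5L, max_pair_end = 3L,
                            opt_len = 21L, opt_tm = 60, opt_gc = 50,
                            w_len = 1, w_tm = 1, w_gc = 0,
                            w_tmdiff = 1, w_prod = 0, opt_product = 175L,
                            n_workers = 1L, batch_size = Inf,
                            percentile_k1 = 85, percentile_k2 = 20,
                            pair_small_pct = 85, pair_large_pct = 99,
                            probe_skip_invalid = FALSE,
                            group_by = c("sid", "sidset"),
                            conc_primer = 5e-8, conc_na = 0.05,
                            seed = 1L) {
  group_by <- match.arg(group_by)
  cfg <- list(
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    min_tm = min_tm, max_tm = max_tm, min_gc = min_gc, max_gc = max_gc,
    max_self_any = as.integer(max_self_any),
    max_self_end = as.integer(max_self_end),
    max_run = as.integer(max_run), min_dg3 = min_dg3,
    max_mismatch = as.integer(max_mismatch),
    trim_depth = as.integer(trim_depth),
    max_len_diff = as.integer(max_len_diff), max_tm_diff = max_tm_diff,
    min_product = as.integer(min_product),
    max_product = as.integer(max_product),
    max_pair_any = as.integer(max_pair_any),
    max_pair_end = as.integer(max_pair_end),
    opt_len = as.integer(opt_len), opt_tm = opt_tm, opt_gc = opt_gc,
    w_len = w_len, w_tm = w_tm, w_gc = w_gc,
    w_tmdiff = w_tmdiff, w_prod = w_prod,
    opt_product = as.integer(opt_product),
    n_workers = as.integer(n_workers), batch_size = batch_size,
    percentile_k1 = percentile_k1, percentile_k2 = percentile_k2,
    pair_small_pct = pair_small_pct, pair_large_pct = pair_large_pct,
    probe_skip_invalid = isTRUE(probe_skip_invalid),
    group_by = group_by,
    conc_primer = conc_primer, conc_na = conc_na,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$min_len >= 1L, cfg$min_len <= cfg$max_len,
    cfg$min_tm <= cfg$max_tm, cfg$min_gc <= cfg$max_gc,
    cfg$min_product <= cfg$max_product,
    cfg$max_mismatch >= 1L, cfg$trim_depth >= 1L,
    cfg$n_workers >= 1L, cfg$batch_size >= 1,
    cfg$percentile_k1 >= 0, cfg$percentile_k1 <= 100,
    cfg$percentile_k2 >= 0, cfg$percentile_k2 <= 100,
    cfg$w_len >= 0, cfg$w_tm >= 0, cfg$w_gc >= 0,
    cfg$w_tmdiff >= 0, cfg$w_prod >= 0,
    cfg$conc_primer > 0, cfg$conc_na > 0
  )
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' The file is a flat key/value mapping whose keys mirror the arguments of
#' [pipeline_config()]; unknown keys are an error. Arguments passed through
#' `...` override file values.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides, as for [pipeline_config()].
#' @return A `pipeline_config` list.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  dots <- list(...)
  vals[names(dots)] <- dots
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  primer length %d-%d bp, Tm %.1f-%.1f degC, GC %.0f-%.0f%%\n",
              x$min_len, x$max_len, x$min_tm, x$max_tm, x$min_gc, x$max_gc))
  cat(sprintf("  cross-hybridization: trim depth %d, max mismatch k = %d\n",
              x$trim_depth, x$max_mismatch))
  cat(sprintf("  product %d-%d bp, pair dTm <= %.1f degC\n",
              x$min_product, x$max_product, x$max_tm_diff))
  cat(sprintf("  scheduler: %d worker(s), batch size %s\n",
              x$n_workers, format(x$batch_size)))
  invisible(x)
}
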