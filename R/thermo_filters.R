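#' Single-primer scores
#'
#' Vectorized compositional and thermodynamic scores for untagged primer
#' strings. `gc_content()` is the GC percentage; `max_homopolymer_run()` the
#' longest run of one repeated base; `melting_temperature()` the
#' nearest-neighbor duplex melting temperature in degC (unified stack table,
#' entropic salt correction, `Tm = 1000 dH / (dS + R ln(C/4)) - 273.15`);
#' `delta_g_3end()` the summed stack free energy (kcal/mol) over the last
#' five bases (four stacks) of the primer -- a stability score for the 3'
#' end, where more negative means a stickier, more misprime-prone end.
#'
#' @param p Character vector of A/C/G/T primer strings.
#' @param params A [thermo_params()] object.
#' @return A numeric (or integer) vector, one score per primer.
#' @export
#' @examples
#' gc_content(c("GCGC", "ACGT"))
#' max_homopolymer_run("AAAT")
gc_content <- function(p) gc_cpp(p)

#' @rdname gc_content
#' @export
max_homopolymer_run <- function(p) maxrun_cpp(p)

#' @rdname gc_content
#' @export
melting_temperature <- function(p, params = thermo_params()) {
  tm_cpp(p, unname(params$dh), unname(params$ds),
         params$init["AT", "dh"], params$init["AT", "ds"],
         params$init["GC", "dh"], params$init["GC", "ds"],
         params$conc_primer, params$conc_na)
}

#' @rdname gc_content
#' @export
delta_g_3end <- function(p, params = thermo_params()) {
  dg3_cpp(p, unname(params$dg), 4L)
}

#' Dimer (complementarity) scores
#'
#' `comp_any(p, q)` is the maximum, over all ungapped offsets of `p` against
#' the reverse of `q`, of the number of Watson-Crick complementary aligned
#' positions -- the classic "any" dimer score. `comp_end(p, q)` restricts to
#' alignments in which the 3'-terminal base of `p` is aligned and paired,
#' and scores the contiguous complementary run ending at that base.
#' `self_any()`/`self_end()` are the self-complementarity specializations.
#'
#' @param p,q Character vectors of equal length (scores are computed
#'   pairwise) of A/C/G/T strings.
#' @return Integer vector of scores.
#' @export
#' @examples
#' comp_any("AAAA", "TTTT")  # 4
#' self_any("ATAT")          # 4
#' comp_end("AAAA", "AAAA")  # 0: A never pairs A
comp_any <- function(p, q) comp_any_cpp(p, q)

#' @rdname comp_any
#' @export
comp_end <- function(p, q) comp_end_cpp(p, q)

#' @rdname comp_any
#' @export
self_any <- function(p) comp_any_cpp(p, p)

#' @rdname comp_any
#' @export
self_end <- function(p) comp_end_cpp(p, p)

#' Apply the six single-primer filtering constraints
#'
#' A primer passes iff its homopolymer run, GC content, melting temperature,
#' self-complementarity ("any" and 3'-anchored) and 3'-end free energy all
#' lie within the configured bounds. Failures report the first violated
#' constraint in a fixed check order (contiguous-residue, GC-content, Tm,
#' self-any, self-end, dG-3end), so the reported reason is deterministic;
#' the pass/fail verdict itself is order-independent.
#'
#' @param p Character vector of untagged primer strings (strip tags first).
#' @param config A [pipeline_config()].
#' @param params Optional [thermo_params()] (derived from `config` when
#'   omitted).
#' @return A tibble with columns `P`, `pass` (logical), `reason` (`NA` when
#'   passing), `tm`, `gc`.
#' @export
single_filter <- function(p, config = pipeline_config(), params = NULL) {
  params <- params %||% params_from_config(config)
  run <- maxrun_cpp(p)
  gc <- gc_cpp(p)
  tm <- melting_temperature(p, params)
  reason <- rep(NA_character_, length(p))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(run > config$max_run, "contiguous-residue")
  reason <- flag(gc < config$min_gc | gc > config$max_gc, "GC-content")
  reason <- flag(tm < config$min_tm | tm > config$max_tm, "Tm")
  # the dimer scores are the expensive predicates; primers already failed
  # above keep their first-violation reason, so scoring only the rest
  # changes nothing observable
  todo <- which(is.na(reason))
  if (length(todo) > 0) {
    sany <- send <- rep(0L, length(p))
    dg3 <- rep(config$min_dg3, length(p))
    sany[todo] <- comp_any_cpp(p[todo], p[todo])
    send[todo] <- comp_end_cpp(p[todo], p[todo])
    # the 3'-stability window spans 5 bases; shorter primers pass vacuously
    long5 <- todo[nchar(p[todo]) >= 5L]
    if (length(long5) > 0)
      dg3[long5] <- dg3_cpp(p[long5], unname(params$dg), 4L)
    reason <- flag(sany > config$max_self_any, "self-any")
    reason <- flag(send > config$max_self_end, "self-end")
    reason <- flag(dg3 < config$min_dg3, "dG-3end")
  }
  tibble(P = p, pass = is.na(reason), reason = reason, tm = tm, gc = gc)
}

#' Build the primer index (single-filter survivors)
#'
#' Keeps the sidset-table rows whose stripped primer passes
#' [single_filter()] and attaches the monotone `valid` flag (initialized
#' `TRUE`; later stages only ever clear it). This is the central index the
#' cross-hybridization filters update in place.
#'
#' @param c1p The sidset table from [aggregate_sidsets()].
#' @param config A [pipeline_config()].
#' @return A tibble (the primer index) with columns `P`, `strip`, `len`,
#'   `sidset`, `valid`, `tm`, `gc`.
#' @export
build_primer_index <- function(c1p, config = pipeline_config()) {
  if (nrow(c1p) == 0) {
    return(tibble(P = character(), strip = character(), len = integer(),
                  sidset = list(), valid = logical(),
                  tm = numeric(), gc = numeric()))
  }
  # score each distinct stripped string once
  us <- unique(c1p$strip)
  sf <- single_filter(us, config)
  idx <- match(c1p$strip, us)
  keep <- sf$pass[idx]
  out <- c1p[keep, , drop = FALSE]
  out$valid <- TRUE
  out$tm <- sf$tm[idx][keep]
  out$gc <- sf$gc[idx][keep]
  out
}

#' Build the 3'-anchored suffix index
#'
#' Keys every primer-index entry by the suffix of its stripped string under
#' the trim rule: the first `t = min(trim_depth, len - 1)` bases are
#' dropped, so the suffix is never empty. Primers sharing a suffix land in
#' one `Pset`, the unit the 5' cross-hybridization filter probes.
#'
#' @param primer_index The index from [build_primer_index()].
#' @param trim_depth Number of 5' bases to drop (clamped per primer).
#' @return A tibble with columns `suffix` and `Pset` (list of tagged keys),
#'   ordered by suffix.
#' @export
build_suffix_index <- function(primer_index, trim_depth = 4L) {
  stopifnot(trim_depth >= 1)
  if (nrow(primer_index) == 0) {
    return(tibble(suffix = character(), Pset = list()))
  }
  suf <- suffix_key(primer_index$strip, trim_depth)
  sp <- split(primer_index$P, suf)
  tibble(suffix = names(sp), Pset = unname(lapply(sp, as.character)))
}

# suffix under the trim rule: drop min(trim, len-1) leading bases
suffix_key <- function(x, trim_depth) {
  n <- nchar(x)
  substring(x, pmin(trim_depth, n - 1L) + 1L, n)
}
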