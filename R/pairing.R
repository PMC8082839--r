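#' Group surviving occurrences by target sequence
#'
#' Splits the surviving occurrence table into per-`sid` groups of forward
#' (untagged) and reverse (tagged) primer occurrences, ordered ascending by
#' forward-primer count (workload order), ties by `sid`.
#'
#' @param c4 Surviving occurrence tibble (`P`, `sid`, `pos`).
#' @return A tibble with columns `sid`, `fwd` and `rev` (list columns of
#'   occurrence tibbles with `P`, `pos`) and `n_fwd`.
#' @export
group_by_sid <- function(c4) {
  if (nrow(c4) == 0) {
    return(tibble(sid = integer(), fwd = list(), rev = list(),
                  n_fwd = integer()))
  }
  tagged <- is_tagged(c4$P)
  sids <- sort(unique(c4$sid))
  fwd <- split(c4[!tagged, c("P", "pos")], factor(c4$sid[!tagged], sids))
  rev <- split(c4[tagged, c("P", "pos")], factor(c4$sid[tagged], sids))
  g <- tibble(sid = sids,
              fwd = lapply(fwd, as_tibble),
              rev = lapply(rev, as_tibble),
              n_fwd = vapply(fwd, nrow, integer(1)))
  g[order(g$n_fwd, g$sid), , drop = FALSE]
}

#' Pair-filtering constraints
#'
#' A forward/reverse combination on the same target passes iff (1) the
#' length difference is within `max_len_diff`, (2) the melting-temperature
#' difference is within `max_tm_diff`, (3) the forward site lies strictly
#' upstream of and non-overlapping with the reverse site, (4) the product
#' size `rp_pos + |RP| - fp_pos` is within the configured range, and (5)
#' the cross-dimer scores `comp_any(FP, RP)`, `comp_end(FP, RP)` and
#' `comp_end(RP, FP)` are within bounds. Failures report the first
#' violated constraint in that fixed order.
#'
#' @param fp,rp Untagged forward primer string and stripped reverse primer
#'   string (the reverse primer's stored sequence, i.e. the oligo itself).
#' @param fp_pos,rp_pos 0-based sense-strand window starts.
#' @param sid_f,sid_r Target sequence IDs (must match).
#' @param config A [pipeline_config()].
#' @param params Optional [thermo_params()].
#' @return A one-row tibble `pass`, `reason`, `product_size`.
#' @export
pair_ok <- function(fp, rp, fp_pos, rp_pos, sid_f = 0L, sid_r = 0L,
                    config = pipeline_config(), params = NULL) {
  if (sid_f != sid_r) abort("forward and reverse occurrences differ in sid")
  params <- params %||% params_from_config(config)
  tm_f <- melting_temperature(fp, params)
  tm_r <- melting_temperature(rp, params)
  v <- pair_ok_vec(fp, rp, fp_pos, rp_pos, tm_f, tm_r, config)
  tibble(pass = v$pass, reason = v$reason, product_size = v$product_size)
}

# vectorized pair constraint evaluation; tms precomputed by the caller
pair_ok_vec <- function(fp, rp, fp_pos, rp_pos, tm_f, tm_r, config) {
  lf <- nchar(fp); lr <- nchar(rp)
  product <- rp_pos + lr - fp_pos
  reason <- rep(NA_character_, length(fp))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  reason <- flag(abs(lf - lr) > config$max_len_diff, "length-difference")
  reason <- flag(abs(tm_f - tm_r) > config$max_tm_diff, "Tm-difference")
  reason <- flag(fp_pos + lf > rp_pos, "geometry")
  reason <- flag(product < config$min_product | product > config$max_product,
                 "product-size")
  todo <- is.na(reason)
  if (any(todo)) {
    pany <- integer(length(fp)); pend_f <- pany; pend_r <- pany
    pany[todo] <- comp_any_cpp(fp[todo], rp[todo])
    pend_f[todo] <- comp_end_cpp(fp[todo], rp[todo])
    pend_r[todo] <- comp_end_cpp(rp[todo], fp[todo])
    reason <- flag(pany > config$max_pair_any, "pair-any")
    reason <- flag(pmax(pend_f, pend_r) > config$max_pair_end, "pair-end")
  }
  list(pass = is.na(reason), reason = reason, product_size = product)
}

#' Primer3-style penalties
#'
#' `primer_penalty()` scores a single primer as the weighted absolute
#' deviation from the configured optima:
#' `w_len*|len - opt_len| + w_tm*|tm - opt_tm| + w_gc*|gc - opt_gc|`.
#' `pair_penalty()` adds the two primer penalties plus
#' `w_tmdiff*|Tm_F - Tm_R| + w_prod*|product - opt_product|`.
#'
#' @param p Primer string(s) (used for length only).
#' @param tm,gc Primer melting temperature and GC content.
#' @param fp_penalty,rp_penalty Single-primer penalties of the pair.
#' @param tm_f,tm_r The two melting temperatures.
#' @param product_size Amplicon size in bp.
#' @param config A [pipeline_config()] carrying optima and weights.
#' @return Non-negative numeric penalty.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' primer_penalty("A", tm = cfg$opt_tm, gc = cfg$opt_gc,
#'                config = pipeline_config(opt_len = 1))  # 0
primer_penalty <- function(p, tm, gc, config = pipeline_config()) {
  config$w_len * abs(nchar(p) - config$opt_len) +
    config$w_tm * abs(tm - config$opt_tm) +
    config$w_gc * abs(gc - config$opt_gc)
}

#' @rdname primer_penalty
#' @export
pair_penalty <- function(fp_penalty, rp_penalty, tm_f, tm_r, product_size,
                         config = pipeline_config()) {
  fp_penalty + rp_penalty +
    config$w_tmdiff * abs(tm_f - tm_r) +
    config$w_prod * abs(product_size - config$opt_product)
}

#' Pair filtering, scoring and ranking
#'
#' Evaluates every forward x reverse occurrence combination per target
#' group, keeps the pairs passing [pair_ok()], scores them with
#' [pair_penalty()], and ranks within each group by ascending penalty (ties
#' by forward string, reverse string, positions). The output is sorted by
#' `sid` then rank and is independent of worker count and group processing
#' order.
#'
#' @param c4 Surviving occurrence tibble.
#' @param config A [pipeline_config()]. With `config$group_by = "sidset"`
#'   pairs are additionally restricted to primers sharing an identical
#'   target set (requires `primer_index`).
#' @param records Optional records tibble; adds an `accession` column.
#' @param primer_index Primer index supplying sidsets; only needed in
#'   `"sidset"` mode.
#' @return The ranked pair tibble (see [write_pairs()] for columns).
#' @export
run_pair_step <- function(c4, config = pipeline_config(), records = NULL,
                          primer_index = NULL) {
  by_sidset <- config$group_by == "sidset"
  if (by_sidset) {
    if (is.null(primer_index))
      abort("group_by = 'sidset' requires the primer index")
    sidkey <- stats::setNames(
      vapply(primer_index$sidset, paste, character(1), collapse = "-"),
      primer_index$P)
  }
  empty <- tibble(
    sid = integer(), rank = integer(),
    forward_primer = character(), reverse_primer = character(),
    fp_pos = integer(), rp_pos = integer(), product_size = integer(),
    fp_tm = numeric(), rp_tm = numeric(),
    fp_gc = numeric(), rp_gc = numeric(), penalty = numeric()
  )
  groups <- group_by_sid(c4)
  # two-threshold workload classification of target groups (small / mid /
  # large task granularity); tunes scheduling only, never the result
  sched <- if (nrow(groups) > 0) {
    lo <- percentile_threshold(groups$n_fwd, config$pair_small_pct)
    hi <- percentile_threshold(groups$n_fwd, config$pair_large_pct)
    tibble(n_groups = nrow(groups), small_boundary = lo,
           large_boundary = hi)
  } else {
    tibble(n_groups = 0L, small_boundary = 0L, large_boundary = 0L)
  }
  params <- params_from_config(config)
  # score each distinct stripped primer once
  all_p <- unique(strip_tag(c4$P))
  if (length(all_p) > 0) {
    ptm <- melting_temperature(all_p, params)
    pgc <- gc_cpp(all_p)
    ppen <- primer_penalty(all_p, ptm, pgc, config)
    lookup <- function(p) match(p, all_p)
  }
  chunks <- partition_at_key_boundaries(groups$n_fwd, config$n_workers)
  res <- vector("list", nrow(groups))
  for (gi in unlist(chunks, use.names = FALSE)) {
    fwd <- groups$fwd[[gi]]
    rev <- groups$rev[[gi]]
    if (nrow(fwd) == 0 || nrow(rev) == 0) next
    co <- tidyr::expand_grid(fi = seq_len(nrow(fwd)), ri = seq_len(nrow(rev)))
    if (by_sidset) {
      same <- sidkey[fwd$P[co$fi]] == sidkey[rev$P[co$ri]]
      same[is.na(same)] <- FALSE
      co <- co[same, , drop = FALSE]
      if (nrow(co) == 0) next
    }
    fp <- fwd$P[co$fi]
    rp <- strip_tag(rev$P[co$ri])
    fpos <- fwd$pos[co$fi]
    rpos <- rev$pos[co$ri]
    fidx <- lookup(fp); ridx <- lookup(rp)
    v <- pair_ok_vec(fp, rp, fpos, rpos, ptm[fidx], ptm[ridx], config)
    keep <- v$pass
    if (!any(keep)) next
    pen <- pair_penalty(ppen[fidx[keep]], ppen[ridx[keep]],
                        ptm[fidx[keep]], ptm[ridx[keep]],
                        v$product_size[keep], config)
    res[[gi]] <- tibble(
      sid = groups$sid[gi],
      forward_primer = fp[keep], reverse_primer = rp[keep],
      fp_pos = fpos[keep], rp_pos = rpos[keep],
      product_size = as.integer(v$product_size[keep]),
      fp_tm = ptm[fidx[keep]], rp_tm = ptm[ridx[keep]],
      fp_gc = pgc[fidx[keep]], rp_gc = pgc[ridx[keep]],
      penalty = pen
    )
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- empty
  } else {
    out <- out %>%
      dplyr::arrange(.data$sid, .data$penalty, .data$forward_primer,
                     .data$reverse_primer, .data$fp_pos, .data$rp_pos) %>%
      dplyr::group_by(.data$sid) %>%
      dplyr::mutate(rank = dplyr::row_number()) %>%
      dplyr::ungroup() %>%
      dplyr::select(dplyr::all_of(names(empty)))
  }
  if (!is.null(records)) {
    out <- dplyr::left_join(
      out, records[, c("sid", "accession")], by = "sid") %>%
      dplyr::relocate("accession", .after = "sid")
  }
  attr(out, "scheduling") <- sched
  out
}
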