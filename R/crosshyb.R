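#' 5' cross-hybridization filtering via the suffix index
#'
#' Invalidates primers that share a 3'-anchored suffix with a subsequence of
#' an off-target sequence. Every sidset-table row is a probe (including
#' rows whose own primer was filtered earlier): its suffix under the trim
#' rule is looked up in the suffix index, and each hit `P` with a different
#' stripped string is invalidated when the probe occurs in some sequence
#' outside `P`'s sidset (`probe sidset` not contained in `P`'s sidset).
#' The result is independent of probe order.
#'
#' @param c1p The full sidset table ([aggregate_sidsets()]).
#' @param primer_index The primer index ([build_primer_index()]).
#' @param suffix_index The suffix index ([build_suffix_index()]), built with
#'   the same `trim_depth`.
#' @param trim_depth The trim depth the indices were built with.
#' @param skip_invalid If `TRUE`, probe rows whose own key is already
#'   invalid in the primer index are skipped -- an order-dependent shortcut,
#'   off by default.
#' @return The primer index with updated `valid` flags.
#' @export
filter_5prime <- function(c1p, primer_index, suffix_index, trim_depth = 4L,
                          skip_invalid = FALSE) {
  if (nrow(primer_index) == 0 || nrow(c1p) == 0) return(primer_index)
  probes <- tibble(
    P_g = c1p$P,
    strip_g = c1p$strip,
    suffix = suffix_key(c1p$strip, trim_depth),
    sidset_g = c1p$sidset
  )
  if (skip_invalid) {
    bad0 <- primer_index$P[!primer_index$valid]
    probes <- probes[!(probes$P_g %in% bad0), , drop = FALSE]
  }
  hits <- tibble(
    suffix = rep(suffix_index$suffix, lengths(suffix_index$Pset)),
    P = unlist(suffix_index$Pset, use.names = FALSE)
  )
  pi_small <- tibble(P = primer_index$P, strip_p = primer_index$strip,
                     sidset_p = primer_index$sidset)
  j <- dplyr::inner_join(probes, hits, by = "suffix",
                         relationship = "many-to-many")
  if (nrow(j) == 0) return(primer_index)
  j <- dplyr::inner_join(j, pi_small, by = "P")
  j <- j[j$strip_p != j$strip_g, , drop = FALSE]
  if (nrow(j) == 0) return(primer_index)
  bad <- unique(j$P[not_subset_cpp(j$sidset_g, j$sidset_p)])
  primer_index$valid[primer_index$P %in% bad] <- FALSE
  primer_index
}

#' Quadratic oracle for the 5' filter (test support)
#'
#' Re-derives the 5' filter verdict without the suffix index: each valid
#' primer is compared against every same-length view in the sidset table by
#' direct suffix comparison (no hashing, plain double loop). Desk-scale
#' only.
#'
#' @inheritParams filter_5prime
#' @return A tibble `P`, `valid` over the currently valid entries.
#' @export
oracle_5prime <- function(c1p, primer_index, trim_depth = 4L) {
  pr <- primer_index[primer_index$valid, , drop = FALSE]
  if (nrow(pr) == 0 || nrow(c1p) == 0)
    return(tibble(P = pr$P, valid = rep(TRUE, nrow(pr))))
  inv <- by_length_scan(pr, c1p, function(p, v)
    oracle_suffix_cpp(p$strip, p$sidset, v$strip, v$sidset,
                      as.integer(trim_depth)))
  tibble(P = pr$P, valid = !inv)
}

#' Pigeonhole seed length
#'
#' For equal-length strings within Hamming distance `k`, at least one of the
#' `k + 1` disjoint seeds of length `floor(plen / (k + 1))` matches exactly
#' at the same offset -- the pigeonhole guarantee the general filter rests
#' on.
#'
#' @param plen Primer length in bp (vectorized).
#' @param k Mismatch tolerance; requires `plen >= k + 1` so the seed is
#'   non-empty.
#' @return Integer seed length.
#' @export
#' @examples
#' seed_length(3, 1)   # 1
#' seed_length(20, 1)  # 10
seed_length <- function(plen, k) {
  stopifnot(k >= 1)
  if (any(plen < k + 1))
    abort("primer length must be at least k + 1 (seed would be empty)")
  as.integer(plen %/% (k + 1L))
}

#' Disjoint seeds of a primer
#'
#' Splits the stripped primer into `k + 1` disjoint seeds of length
#' [seed_length()] at offsets `0, s, ..., k*s`; trailing remainder residues
#' yield no seed.
#'
#' @param p A single (possibly tagged) primer string.
#' @param k Mismatch tolerance.
#' @return A tibble with columns `seed` and `index` (0-based offset).
#' @export
#' @examples
#' extract_seeds("AAC", 1)  # seeds "A"@0 and "A"@1
extract_seeds <- function(p, k) {
  stopifnot(length(p) == 1)
  s <- strip_tag(p)
  sl <- seed_length(nchar(s), k)
  idx <- (0:k) * sl
  tibble(seed = substring(s, idx + 1L, idx + sl), index = as.integer(idx))
}

# vectorized seed extraction: one row per (primer, seed slot), key serialized
# as seed+index+plen
seeds_long <- function(keys, strips, sidsets, k) {
  lens <- nchar(strips)
  sl <- seed_length(lens, k)
  n <- length(keys)
  reps <- k + 1L
  ord <- rep(seq_len(n), each = reps)
  slot <- rep.int(0:k, n)
  start <- slot * sl[ord] + 1L
  tibble(
    key = paste(substring(strips[ord], start, start + sl[ord] - 1L),
                slot, lens[ord], sep = "+"),
    P = keys[ord],
    strip = strips[ord],
    sidset = sidsets[ord]
  )
}

# Internal flat form of the seed index: a row table (gid, P, strip, sidset)
# ordered by workload-ordered group id, plus the key and size per group.
seed_index_flat <- function(primer_index, k) {
  pr <- primer_index[primer_index$valid, , drop = FALSE]
  empty <- list(flat = tibble(gid = integer(), P = character(),
                              strip = character(), sidset = list()),
                keys = character(), sizes = integer())
  if (nrow(pr) == 0) return(empty)
  fl <- seeds_long(pr$P, pr$strip, pr$sidset, k)
  ord <- order(fl$key, fl$P, method = "radix")
  fl <- fl[ord, , drop = FALSE]
  kk <- fl$key
  new_grp <- c(TRUE, kk[-1] != kk[-length(kk)])
  starts <- which(new_grp)
  keys <- kk[starts]
  sizes <- diff(c(starts, length(kk) + 1L))
  wo <- order(sizes, keys, method = "radix")   # workload order
  rank <- integer(length(wo))
  rank[wo] <- seq_along(wo)
  fl$gid <- rank[cumsum(new_grp)]
  fl <- fl[order(fl$gid, fl$P, method = "radix"),
           c("gid", "P", "strip", "sidset")]
  list(flat = fl, keys = keys[wo], sizes = sizes[wo])
}

# Internal flat probe table aligned to a seed index: rows (gid, P, strip,
# sidset) for every sidset-table seed whose key exists in the index.
probe_flat_build <- function(c1p, keys, k) {
  empty <- tibble(gid = integer(), P = character(), strip = character(),
                  sidset = list())
  c1p <- c1p[c1p$len >= k + 1L, , drop = FALSE]
  if (nrow(c1p) == 0 || length(keys) == 0) return(empty)
  lens <- c1p$len
  sl <- lens %/% (k + 1L)
  n <- nrow(c1p)
  ord <- rep(seq_len(n), each = k + 1L)
  slot <- rep.int(0:k, n)
  start <- slot * sl[ord] + 1L
  seed <- substring(c1p$strip[ord], start, start + sl[ord] - 1L)
  # cheap prefilter on the seed string before building composite keys
  key_seed <- sub("\\+.*$", "", keys)
  pre <- seed %in% key_seed
  if (!any(pre)) return(empty)
  ord <- ord[pre]; slot <- slot[pre]; seed <- seed[pre]
  gid <- match(paste(seed, slot, lens[ord], sep = "+"), keys)
  keep <- !is.na(gid)
  if (!any(keep)) return(empty)
  out <- tibble(gid = gid[keep], P = c1p$P[ord][keep],
                strip = c1p$strip[ord][keep],
                sidset = c1p$sidset[ord][keep])
  out[order(out$gid, out$P, method = "radix"), , drop = FALSE]
}

# Core of one round: returns the set of invalidated index-side primers.
# Deterministic and invariant to n_workers and batch_size: chunks never
# split a group, each batch contributes an invalid set, and the merge is a
# union (AND on validity).
round_flat <- function(idx, probes, sizes, k, n_workers = 1L,
                       batch_size = Inf) {
  if (nrow(idx) == 0 || nrow(probes) == 0) return(character(0))
  ngroups <- length(sizes)
  pos_by_gid <- split(seq_len(nrow(idx)),
                      factor(idx$gid, levels = seq_len(ngroups)))
  chunks <- partition_at_key_boundaries(sizes, n_workers)
  bad <- character(0)
  for (ch in chunks) {
    if (length(ch) == 0) next
    pr_c <- probes[probes$gid >= ch[1] & probes$gid <= ch[length(ch)], ,
                   drop = FALSE]
    if (nrow(pr_c) == 0) next
    bad_c <- stream_batches(pr_c, batch_size, function(b) {
      hits <- pos_by_gid[b$gid]
      nh <- lengths(hits)
      if (sum(nh) == 0) return(character(0))
      bi <- rep.int(seq_len(nrow(b)), nh)
      ii <- unlist(hits, use.names = FALSE)
      close <- hamming_le_cpp(idx$strip[ii], b$strip[bi], k)
      if (!any(close)) return(character(0))
      off <- not_subset_cpp(b$sidset[bi][close], idx$sidset[ii][close])
      unique(idx$P[ii][close][off])
    })
    bad <- c(bad, bad_c)
  }
  unique(bad)
}

#' Build the seed index over valid primers
#'
#' Extracts all `k + 1` seeds from every valid primer-index entry and groups
#' primers by the serialized key `seed+index+plen`. Groups are returned in
#' *workload order*: ascending by group size, ties broken lexicographically
#' by key -- the order the scheduler partitions work in.
#'
#' @param primer_index The primer index (a snapshot: only currently valid
#'   entries are indexed).
#' @param k Mismatch tolerance for this round.
#' @return A tibble with columns `key`, `Pset` (list of tagged keys) and
#'   `sidsets` (list of lists of integer vectors, aligned with `Pset`), in
#'   workload order.
#' @export
build_seed_index <- function(primer_index, k) {
  fl <- seed_index_flat(primer_index, k)
  nest_groups(fl$flat, fl$keys)
}

#' Build probe-side key groups
#'
#' Extracts seeds from *every* sidset-table row (valid or not) and keeps
#' only keys present in the seed index, in the same workload order, so a
#' group-aligned binary join against the index side is possible. Rows
#' shorter than `k + 1` bases cannot be seeded and are skipped.
#'
#' @param c1p The full sidset table.
#' @param seed_index The index from [build_seed_index()] for the same round.
#' @param k Mismatch tolerance.
#' @return A tibble shaped like the seed index (`key`, `Pset`, `sidsets`).
#' @export
build_probe_groups <- function(c1p, seed_index, k) {
  probes <- probe_flat_build(c1p, seed_index$key, k)
  nest_groups(probes, seed_index$key, drop_empty = TRUE)
}

# nest a flat (gid, P, strip, sidset) table back into the group form
nest_groups <- function(flat, keys, drop_empty = FALSE) {
  if (length(keys) == 0 || nrow(flat) == 0) {
    return(tibble(key = character(), Pset = list(), sidsets = list()))
  }
  f <- factor(flat$gid, levels = seq_along(keys))
  g <- tibble(
    key = keys,
    Pset = split(flat$P, f),
    sidsets = split(flat$sidset, f)
  )
  if (drop_empty) g <- g[lengths(g$Pset) > 0, , drop = FALSE]
  g
}

# flatten a nested group table back to the internal flat form
unnest_groups <- function(groups) {
  tibble(
    gid = rep(seq_len(nrow(groups)), lengths(groups$Pset)),
    P = unlist(groups$Pset, use.names = FALSE),
    strip = strip_tag(unlist(groups$Pset, use.names = FALSE)),
    sidset = do.call(c, c(groups$sidsets, list(list())))
  )
}

#' One general cross-hybridization round
#'
#' For every key group, every (index primer, probe primer) pair with the
#' probe's sidset not contained in the index primer's sidset and Hamming
#' distance at most `k` marks the index primer invalid. Equal string
#' lengths are guaranteed because the key embeds the primer length. The
#' result is independent of group processing order, worker count and batch
#' size (within-round snapshot semantics: invalidations never remove
#' probes).
#'
#' @param index_groups Valid-primer groups from [build_seed_index()].
#' @param probe_groups Probe groups from [build_probe_groups()], in the same
#'   key order (checked; mismatch is an error).
#' @param k Mismatch tolerance.
#' @param n_workers Number of contiguous key-boundary chunks processed
#'   independently.
#' @param batch_size Probe rows streamed per consumer call.
#' @return A validity tibble with one row per (group, primer): columns
#'   `key`, `P`, `valid`.
#' @export
general_crosshyb_round <- function(index_groups, probe_groups, k,
                                   n_workers = 1L, batch_size = Inf) {
  validity <- tibble(
    key = rep(index_groups$key, lengths(index_groups$Pset)),
    P = unlist(index_groups$Pset, use.names = FALSE),
    valid = TRUE
  )
  if (nrow(index_groups) == 0 || nrow(probe_groups) == 0) return(validity)
  m <- match(probe_groups$key, index_groups$key)
  if (any(is.na(m)) || is.unsorted(m, strictly = TRUE))
    abort("key-order mismatch between index and probe group tables")
  idx <- unnest_groups(index_groups)
  probes <- unnest_groups(probe_groups)
  probes$gid <- m[probes$gid]
  bad <- round_flat(idx, probes, lengths(index_groups$Pset), k,
                    n_workers, batch_size)
  validity$valid <- !(validity$P %in% bad)
  validity
}

#' Run the general cross-hybridization filter
#'
#' Executes rounds k = 1..`max_mismatch`; each round rebuilds the seed
#' index from the current primer-index snapshot, probes it with the full
#' sidset table, and merges the round's invalidations back (monotone: the
#' valid set only shrinks). Finally the surviving occurrence table is
#' emitted by keeping the single-filter occurrence rows whose primer is
#' still valid.
#'
#' @param c1p The full sidset table.
#' @param primer_index The primer index after the 5' filter.
#' @param c2 Occurrence rows of single-filter survivors (columns `P`,
#'   `sid`, `pos`).
#' @param max_mismatch Maximum mismatch count (0 = skip the filter).
#' @param config A [pipeline_config()] (scheduler settings are honored).
#' @return A list with `primer_index` (updated), `c4` (surviving occurrence
#'   tibble) and `rounds` (per-round bookkeeping: number of key groups, the
#'   workload-percentile boundary, invalidation count).
#' @export
run_crosshyb <- function(c1p, primer_index, c2,
                         max_mismatch = 2L, config = pipeline_config()) {
  rounds <- vector("list", max_mismatch)
  for (k in seq_len(max_mismatch)) {
    fl <- seed_index_flat(primer_index, k)
    probes <- probe_flat_build(c1p, fl$keys, k)
    bad <- round_flat(fl$flat, probes, fl$sizes, k,
                      n_workers = config$n_workers,
                      batch_size = config$batch_size)
    pct <- if (k == 1) config$percentile_k1 else config$percentile_k2
    boundary <- percentile_threshold(fl$sizes, pct)
    primer_index$valid[primer_index$P %in% bad] <- FALSE
    rounds[[k]] <- tibble(k = k, n_groups = length(fl$keys),
                          workload_boundary = boundary,
                          n_invalidated = length(bad))
  }
  c4 <- c2[c2$P %in% primer_index$P[primer_index$valid], , drop = FALSE]
  list(primer_index = primer_index, c4 = c4,
       rounds = dplyr::bind_rows(rounds))
}

#' Quadratic cross-hybridization oracle (test support)
#'
#' Independent brute-force verdict for one round: every valid primer is
#' compared against every same-length view in the sidset table (tags
#' stripped, no seeding); a primer is invalid iff some view lies within
#' Hamming distance `k` and occurs in a sequence outside the primer's
#' sidset. Desk-scale only; quadratic.
#'
#' @param c1p The full sidset table.
#' @param primer_index The primer index snapshot.
#' @param k Mismatch tolerance.
#' @return A tibble `P`, `valid` covering the valid entries of the
#'   snapshot.
#' @export
oracle_crosshyb <- function(c1p, primer_index, k) {
  pr <- primer_index[primer_index$valid, , drop = FALSE]
  if (nrow(pr) == 0) return(tibble(P = character(), valid = logical()))
  inv <- by_length_scan(pr, c1p, function(p, v)
    oracle_invalidate_cpp(p$strip, p$sidset, v$strip, v$sidset, k))
  tibble(P = pr$P, valid = !inv)
}

# run a primer-vs-view scan one primer length at a time (views of other
# lengths can never match); fn(primers, views) -> logical
by_length_scan <- function(pr, c1p, fn) {
  out <- logical(nrow(pr))
  vlen <- c1p$len
  for (L in unique(pr$len)) {
    pi <- which(pr$len == L)
    vi <- which(vlen == L)
    if (length(vi) == 0) next
    out[pi] <- fn(pr[pi, , drop = FALSE], c1p[vi, , drop = FALSE])
  }
  out
}
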