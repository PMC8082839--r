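#' Generate a synthetic sequence database
#'
#' Draws i.i.d. random sequences with a configurable GC bias. Desk-scale
#' databases (default 20 sequences of 500 bp) are large enough for every
#' filter to fire yet small enough for the quadratic oracles to run in
#' seconds. Output is byte-identical for a fixed seed.
#'
#' @param n_seqs Number of sequences.
#' @param seq_len Sequence length in bp.
#' @param gc GC bias: probability that a base is G or C.
#' @param seed Integer RNG seed (`NULL` = use the current RNG state).
#' @return A list of class `"synthetic_db"` with `records` (a tibble as
#'   from [read_fasta()]) and an empty `manifest` tibble.
#' @export
#' @examples
#' db <- generate_db(n_seqs = 3, seq_len = 60, seed = 42)
#' db$records
generate_db <- function(n_seqs = 20L, seq_len = 500L, gc = 0.5,
                        seed = NULL) {
  stopifnot(n_seqs >= 1, seq_len >= 1, gc >= 0, gc <= 1)
  if (!is.null(seed)) set.seed(seed)
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sids <- 0:(n_seqs - 1L)
  seqs <- vapply(sids, function(i) {
    paste(sample(c("A", "C", "G", "T"), seq_len, replace = TRUE,
                 prob = prob), collapse = "")
  }, character(1))
  structure(list(
    records = tibble(sid = as.integer(sids),
                     accession = sprintf("synth%03d", sids),
                     seq = seqs),
    manifest = empty_manifest()
  ), class = "synthetic_db")
}

#' Configuration for synthetic benchmark databases
#'
#' The standard [pipeline_config()] targets transcript-like sequence
#' composition. Uniform random sequences run cooler: their 19--23-mers
#' melt around 53 degC at 50 mM monovalent salt, and their unit-weight
#' self-complementarity score centers near 8, so the field defaults leave
#' almost no survivors on a random database and every downstream stage
#' would be tested against an empty set. This configuration widens exactly
#' two bounds -- minimum Tm 54 degC and self-any <= 6 -- so that a few
#' percent of random candidates survive the single filters and every later
#' stage is exercised. It is the fixed configuration of the package's
#' synthetic verification studies.
#'
#' @param ... Further overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
synthetic_benchmark_config <- function(...) {
  pipeline_config(min_tm = 54, max_self_any = 6L, ...)
}

empty_manifest <- function() {
  tibble(primer = character(), host_sid = integer(), host_pos = integer(),
         target_sid = integer(), target_pos = integer(), d = integer())
}

#' Plant off-target sites with known ground truth
#'
#' Copies primer-length windows from a host sequence into another sequence
#' with exactly `d` substitutions, creating controlled near-duplicate
#' off-target sites. With `d = 0` the copy is exact: the host primer's
#' sidset absorbs the off-target sequence, so the general filter must
#' *not* invalidate it. With `1 <= d <= k` the planted view lies within
#' Hamming distance `d` of the host primer but outside its sidset, so the
#' round with mismatch tolerance `k >= d` must invalidate it. The manifest
#' records each event; full expected validity still comes from the oracle,
#' since random sequences can create unplanned near-matches.
#'
#' @param db A `"synthetic_db"` (or a bare records tibble).
#' @param primer_len Length of the copied window.
#' @param d Hamming distance of each planted copy.
#' @param n_events Number of events to plant.
#' @param require_valid_host If `TRUE`, only host windows whose primer
#'   passes [single_filter()] are planted (so the event is observable
#'   downstream).
#' @param config Config used for the host-validity check.
#' @param seed Optional RNG seed.
#' @param max_retries Re-draws allowed when a drawn window collides with a
#'   previous plant before erroring.
#' @return The `"synthetic_db"` with modified records and an extended
#'   manifest.
#' @export
plant_offtarget <- function(db, primer_len = 20L, d = 1L, n_events = 1L,
                            require_valid_host = TRUE,
                            config = pipeline_config(), seed = NULL,
                            max_retries = 200L) {
  if (!inherits(db, "synthetic_db"))
    db <- structure(list(records = db, manifest = empty_manifest()),
                    class = "synthetic_db")
  stopifnot(d >= 0, n_events >= 1, primer_len >= 1)
  if (!is.null(seed)) set.seed(seed)
  records <- db$records
  n <- nrow(records)
  if (n < 2) abort("planting needs at least two sequences")
  if (any(nchar(records$seq) < primer_len))
    abort("sequences too short for the requested primer length")
  # intervals already owned by a plant (host windows and planted copies)
  taken <- db$manifest
  pick1 <- function(x) x[sample.int(length(x), 1)]
  overlaps <- function(sid, pos) {
    any((taken$host_sid == sid & taken$host_pos < pos + primer_len &
           pos < taken$host_pos + primer_len) |
        (taken$target_sid == sid & taken$target_pos < pos + primer_len &
           pos < taken$target_pos + primer_len))
  }
  # enumerate host windows once; restrict to single-filter survivors when a
  # valid (downstream-observable) host is required
  hosts <- dplyr::bind_rows(lapply(seq_len(n), function(r) {
    npos <- nchar(records$seq[r]) - primer_len + 1L
    tibble(sid = records$sid[r], pos = seq_len(npos) - 1L,
           win = substring(records$seq[r], seq_len(npos),
                           seq_len(npos) + primer_len - 1L))
  }))
  hosts <- hosts[!grepl("[^ACGT]", hosts$win), , drop = FALSE]
  if (require_valid_host) {
    uw <- unique(hosts$win)
    ok <- single_filter(uw, config)$pass
    hosts <- hosts[hosts$win %in% uw[ok], , drop = FALSE]
  }
  if (nrow(hosts) == 0)
    abort("no eligible host window for planting")
  for (ev in seq_len(n_events)) {
    placed <- FALSE
    for (try in seq_len(max_retries)) {
      hrow <- hosts[sample.int(nrow(hosts), 1), ]
      host <- hrow$sid
      hpos <- hrow$pos
      win <- hrow$win
      if (overlaps(host, hpos)) next
      tgt <- pick1(setdiff(records$sid, host))
      tpos <- sample.int(nchar(records$seq[records$sid == tgt]) -
                           primer_len + 1L, 1) - 1L
      if (overlaps(tgt, tpos)) next
      copy <- win
      if (d > 0) {
        mut <- sample.int(primer_len, d)
        for (m in mut) {
          old <- substr(copy, m, m)
          substr(copy, m, m) <- pick1(setdiff(c("A", "C", "G", "T"), old))
        }
      }
      ri <- which(records$sid == tgt)
      substr(records$seq[ri], tpos + 1L, tpos + primer_len) <- copy
      taken <- dplyr::bind_rows(taken, tibble(
        primer = win, host_sid = host, host_pos = hpos,
        target_sid = as.integer(tgt), target_pos = tpos, d = as.integer(d)
      ))
      placed <- TRUE
      break
    }
    if (!placed)
      abort("could not place a planted window without collision")
  }
  db$records <- records
  db$manifest <- taken
  db
}

#' @export
print.synthetic_db <- function(x, ...) {
  cat(sprintf("<synthetic_db> %d sequences, %d planted event(s)\n",
              nrow(x$records), nrow(x$manifest)))
  invisible(x)
}

#' Worked-example fixture
#'
#' The tiny published worked example of the hash-map stage: the sidset
#' table holds rows `GCT+3` and `*TCT+4-5`; the primer index contains only
#' `*TCT` (sidset \{4, 5\}, valid) because `GCT` fell to the single
#' filters; the suffix index (trim depth 1) maps `CT` to \{`*TCT`\}.
#' Running [filter_5prime()] on this fixture must invalidate `*TCT`: the
#' probe `GCT` shares the suffix `CT` but occurs in sequence 3, which
#' `*TCT` does not target.
#'
#' @return A list with `c1p`, `primer_index`, `suffix_index` and
#'   `trim_depth` (1).
#' @export
worked_example_fixture <- function() {
  c1p <- tibble(
    P = c("GCT", "*TCT"),
    strip = c("GCT", "TCT"),
    len = c(3L, 3L),
    sidset = list(3L, c(4L, 5L))
  )
  primer_index <- tibble(
    P = "*TCT", strip = "TCT", len = 3L,
    sidset = list(c(4L, 5L)), valid = TRUE,
    tm = NA_real_, gc = gc_cpp("TCT")
  )
  suffix_index <- tibble(suffix = "CT", Pset = list("*TCT"))
  list(c1p = c1p, primer_index = primer_index,
       suffix_index = suffix_index, trim_depth = 1L)
}
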