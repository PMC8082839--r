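#' Reverse complement of a DNA string
#'
#' @param s Character vector of A/C/G/T strings; non-ACGT characters are an
#'   error.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("GCT")  # "AGC"
reverse_complement <- function(s) {
  stopifnot(is.character(s))
  rc_cpp(s)
}

#' Enumerate candidate primer occurrences
#'
#' Extracts every window of length `min_len`..`max_len` from every sequence
#' as a candidate primer occurrence, on both strands. A window on the
#' antisense strand is stored as the reverse complement of the sense window,
#' tagged with a leading `'*'`; its `pos` is the sense-strand window start,
#' so one coordinate system serves both orientations. Windows containing
#' any non-ACGT base are skipped (they cannot be primers and have no
#' nearest-neighbor parameters).
#'
#' @param records A tibble with `sid` and `seq` columns ([read_fasta()]).
#' @param min_len,max_len Primer length range in bp.
#' @return A tibble with columns `P` (tagged primer string), `sid`, `pos`
#'   (0-based sense-strand start).
#' @export
#' @examples
#' db <- tibble::tibble(sid = 0L, accession = "x", seq = "ACGTA")
#' enumerate_candidates(db, 3, 3)
enumerate_candidates <- function(records, min_len, max_len) {
  stopifnot(min_len >= 1, min_len <= max_len)
  min_len <- as.integer(min_len); max_len <- as.integer(max_len)
  pieces <- vector("list", nrow(records) * (max_len - min_len + 1L))
  pi <- 0L
  for (r in seq_len(nrow(records))) {
    s <- records$seq[r]
    n <- nchar(s)
    for (L in min_len:max_len) {
      if (n < L) next
      starts <- seq_len(n - L + 1L)
      win <- substring(s, starts, starts + L - 1L)
      keep <- !grepl("[^ACGT]", win)
      if (!any(keep)) next
      win <- win[keep]
      pos0 <- starts[keep] - 1L
      pi <- pi + 1L
      pieces[[pi]] <- tibble(
        P = c(win, paste0("*", rc_cpp(win))),
        sid = records$sid[r],
        pos = c(pos0, pos0)
      )
    }
  }
  if (pi == 0L) {
    return(tibble(P = character(), sid = integer(), pos = integer()))
  }
  dplyr::bind_rows(pieces[seq_len(pi)])
}

#' Aggregate occurrences into the primer -> sidset table
#'
#' Groups candidate occurrences by tagged primer string and collects the
#' distinct, sorted set of sequence IDs where each occurs. Tagged and
#' untagged forms of the same letters are distinct keys. The result is
#' independent of the occurrence order.
#'
#' @param occurrences The occurrence tibble from [enumerate_candidates()].
#' @return A tibble with columns `P` (tagged key), `strip` (tag removed),
#'   `len` (primer length) and `sidset` (list column of sorted integer
#'   vectors), ordered by `P`.
#' @export
aggregate_sidsets <- function(occurrences) {
  if (nrow(occurrences) == 0) {
    return(tibble(P = character(), strip = character(), len = integer(),
                  sidset = list()))
  }
  ord <- order(occurrences$P, occurrences$sid, method = "radix")
  p <- occurrences$P[ord]
  sid <- as.integer(occurrences$sid[ord])
  new_grp <- c(TRUE, p[-1] != p[-length(p)])
  starts <- which(new_grp)
  ends <- c(starts[-1] - 1L, length(p))
  keys <- p[starts]
  strip <- strip_tag(keys)
  tibble(
    P = keys,
    strip = strip,
    len = nchar(strip),
    sidset = slice_sidsets_cpp(sid, starts, ends)
  )
}

#' Strip the orientation tag from primer keys
#'
#' @param p Character vector of (possibly `'*'`-tagged) primer keys.
#' @return The untagged strings.
#' @export
strip_tag <- function(p) sub("^\\*", "", p)

is_tagged <- function(p) startsWith(p, "*")
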