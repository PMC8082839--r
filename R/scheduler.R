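#' Workload percentile boundary
#'
#' Nearest-rank boundary index splitting an ascending workload list into
#' small-unit work (below the boundary) and large-unit work (at or above).
#' With 100 keys and `pct = 85` the boundary is 85. Small-unit groups are
#' processed one per task; large-unit groups are subdivided -- the CPU
#' analogue of per-thread versus per-block task granularity on skewed key
#' groups.
#'
#' @param workloads Group sizes sorted ascending (workload order).
#' @param pct Percentile in \[0, 100\].
#' @return Integer boundary index in `0..length(workloads)`.
#' @export
#' @examples
#' percentile_threshold(rep(1, 100), 85)  # 85
percentile_threshold <- function(workloads, pct) {
  if (pct < 0 || pct > 100) abort("percentile must be in [0, 100]")
  if (is.unsorted(workloads)) abort("workloads must be sorted ascending")
  as.integer(floor(pct / 100 * length(workloads)))
}

#' Partition groups into contiguous chunks at key boundaries
#'
#' Splits an ordered group table into `n_chunks` contiguous, disjoint,
#' order-preserving slices, never splitting inside a group, with greedy
#' balance on total group size: the boundary of chunk `i` is placed at the
#' first group where the cumulative size reaches `i/n` of the total. The
#' maximum chunk load is at most `ceiling(total/n)` plus the largest single
#' group.
#'
#' @param sizes Integer vector of group sizes, in group order.
#' @param n_chunks Number of chunks (>= 1).
#' @return A list of `n_chunks` integer index vectors (possibly empty)
#'   whose concatenation is `seq_along(sizes)`.
#' @export
#' @examples
#' partition_at_key_boundaries(c(1, 1, 1, 10), 2)
partition_at_key_boundaries <- function(sizes, n_chunks) {
  if (n_chunks < 1) abort("n_chunks must be >= 1")
  n <- length(sizes)
  if (n == 0) return(rep(list(integer(0)), n_chunks))
  cs <- cumsum(as.numeric(sizes))
  total <- cs[n]
  if (total == 0) {
    out <- rep(list(integer(0)), n_chunks)
    out[[1]] <- seq_len(n)
    return(out)
  }
  # chunk i gets the groups whose cumulative load falls in ((i-1)T/n, iT/n]
  assign <- pmax(1L, pmin(n_chunks, as.integer(ceiling(cs / total * n_chunks))))
  lapply(seq_len(n_chunks), function(i) which(assign == i))
}

#' Stream rows through a consumer in batches
#'
#' Splits `rows` into consecutive batches of `batch_size` rows, applies
#' `consumer` to each, and combines the per-batch results. When the
#' consumer is pure and the combine operation is a monotone merge (here:
#' unioning invalid sets, i.e. AND-ing validity), the final result is
#' identical for every batch size.
#'
#' @param rows A data frame of work rows.
#' @param batch_size Rows per batch (`Inf` = a single batch).
#' @param consumer Function of one batch returning a partial result.
#' @param .combine Binary combine function (default `c`).
#' @param .init Initial value (default: empty result of `.combine`).
#' @return The combined result; `.init` when `rows` is empty (the consumer
#'   is never invoked).
#' @export
stream_batches <- function(rows, batch_size, consumer,
                           .combine = c, .init = NULL) {
  if (batch_size < 1) abort("batch_size must be >= 1")
  n <- nrow(rows)
  acc <- .init
  if (n == 0) return(acc)
  starts <- seq(1L, n, by = if (is.finite(batch_size)) batch_size else n)
  for (st in starts) {
    en <- min(n, st + batch_size - 1L)
    part <- consumer(rows[st:en, , drop = FALSE])
    acc <- if (is.null(acc)) part else .combine(acc, part)
  }
  acc
}
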