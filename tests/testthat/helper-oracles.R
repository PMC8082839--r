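# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's kernels: plain R, direct definitions.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

all_strings <- function(L) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), L), stringsAsFactors = FALSE))
  do.call(paste0, g)
}

bf_gc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  100 * sum(ch %in% c("G", "C")) / length(ch)
}

bf_maxrun <- function(s) {
  max(rle(strsplit(s, "")[[1]])$lengths)
}

# comp_any by direct enumeration of ungapped offsets of p against reverse(q)
bf_comp_any <- function(p, q) {
  pc <- strsplit(p, "")[[1]]
  rq <- rev(strsplit(q, "")[[1]])
  lp <- length(pc); lq <- length(rq)
  best <- 0
  for (off in (1 - lq):(lp - 1)) {
    i <- max(0, off):min(lp - 1, off + lq - 1)
    sc <- sum(COMP[pc[i + 1]] == rq[i - off + 1])
    best <- max(best, sc)
  }
  best
}

# comp_end: contiguous complementary run ending at the aligned 3' terminus
bf_comp_end <- function(p, q) {
  pc <- strsplit(p, "")[[1]]
  rq <- rev(strsplit(q, "")[[1]])
  lp <- length(pc); lq <- length(rq)
  best <- 0
  for (off in (lp - lq):(lp - 1)) {
    j <- lp - 1 - off
    if (j < 0 || j > lq - 1) next
    if (COMP[pc[lp]] != rq[j + 1]) next
    run <- 0
    i <- lp - 1
    while (i >= 0 && i >= off && (i - off) <= lq - 1 &&
           COMP[pc[i + 1]] == rq[i - off + 1]) {
      run <- run + 1
      i <- i - 1
    }
    best <- max(best, run)
  }
  best
}

# vectorized self-complementarity scores for ALL strings of length L at
# once (character matrices, one offset at a time) -- independent of the
# per-string loop above and of the package kernels
bf_self_scores_all <- function(L) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), L), stringsAsFactors = FALSE))
  m <- as.matrix(g)                      # m[, j] = j-th character
  strings <- do.call(paste0, g)
  cm <- matrix(COMP[m], nrow(m), L)      # complement of each position
  rv <- m[, L:1, drop = FALSE]           # reverse of the string
  n <- nrow(m)
  any_sc <- rep(0L, n)
  for (off in (1 - L):(L - 1)) {
    i <- max(0, off):min(L - 1, off + L - 1)
    eq <- cm[, i + 1, drop = FALSE] == rv[, i - off + 1, drop = FALSE]
    any_sc <- pmax(any_sc, rowSums(eq))
  }
  end_sc <- rep(0L, n)
  for (off in 0:(L - 1)) {
    run <- rep(0L, n)
    alive <- rep(TRUE, n)
    for (i in (L - 1):max(0, off)) {
      eq <- cm[, i + 1] == rv[, i - off + 1]
      alive <- alive & eq
      run <- run + alive
    }
    end_sc <- pmax(end_sc, run)
  }
  list(strings = strings, any = as.integer(any_sc),
       end = as.integer(end_sc))
}

# nearest-neighbor Tm recomputed from the shipped parameter file by direct
# summation (independent arithmetic path)
bf_tm <- function(s, conc = 5e-8, na = 0.05) {
  fp <- system.file("extdata", "nn_params.txt", package = "primerscreen")
  tab <- utils::read.table(fp, comment.char = "#",
                           col.names = c("stack", "dh", "ds", "dg"))
  ch <- strsplit(s, "")[[1]]
  stacks <- paste0(ch[-length(ch)], ch[-1])
  H <- sum(tab$dh[match(stacks, tab$stack)])
  S <- sum(tab$ds[match(stacks, tab$stack)])
  for (e in c(ch[1], ch[length(ch)])) {
    row <- if (e %in% c("G", "C")) "INIT_GC" else "INIT_AT"
    H <- H + tab$dh[tab$stack == row]
    S <- S + tab$ds[tab$stack == row]
  }
  S <- S + 0.368 * (length(ch) - 1) * log(na)
  1000 * H / (S + 1.987 * log(conc / 4)) - 273.15
}

# sum of 3'-terminal stack free energies from the parameter file
bf_dg3 <- function(s) {
  fp <- system.file("extdata", "nn_params.txt", package = "primerscreen")
  tab <- utils::read.table(fp, comment.char = "#",
                           col.names = c("stack", "dh", "ds", "dg"))
  ch <- strsplit(s, "")[[1]]
  tail5 <- ch[(length(ch) - 4):length(ch)]
  stacks <- paste0(tail5[-5], tail5[-1])
  sum(tab$dg[match(stacks, tab$stack)])
}

# exhaustive search over all contiguous splits of `sizes` into n chunks,
# returning the minimal achievable maximum chunk load
bf_best_split_maxload <- function(sizes, n) {
  m <- length(sizes)
  best <- Inf
  cuts <- utils::combn(0:m, n - 1, simplify = FALSE)
  if (n == 1) cuts <- list(integer(0))
  for (cut in cuts) {
    b <- c(0, sort(cut), m)
    loads <- vapply(seq_len(n), function(i) {
      if (b[i] == b[i + 1]) 0 else sum(sizes[(b[i] + 1):b[i + 1]])
    }, numeric(1))
    best <- min(best, max(loads))
  }
  best
}

# small random database records for unit tests
random_records <- function(n_seqs, len, seed) {
  generate_db(n_seqs, len, seed = seed)$records
}

# wide-open configuration so toy primers (length 2-5) survive the single
# filters in structural tests
permissive_config <- function(...) {
  base <- list(min_len = 1, max_len = 50, min_tm = -500, max_tm = 500,
               min_gc = 0, max_gc = 100, max_self_any = 99,
               max_self_end = 99, max_run = 99, min_dg3 = -99)
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(pipeline_config, base)
}
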