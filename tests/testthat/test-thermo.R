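test_that("composition scores match their definitions", {
  expect_equal(gc_content(c("GCGC", "ATAT", "ACGT")), c(100, 0, 50))
  expect_error(gc_content(""), "empty")
  expect_equal(max_homopolymer_run(c("AAAT", "ACGT", "AAAAA")), c(3L, 1L, 5L))
})

test_that("melting temperature matches an independent table summation", {
  polyA <- strrep("A", 19)
  expect_equal(melting_temperature(polyA), bf_tm(polyA), tolerance = 1e-10)
  set.seed(31)
  for (i in 1:10) {
    p <- paste(sample(BASES, sample(15:25, 1), TRUE), collapse = "")
    expect_equal(melting_temperature(p), bf_tm(p), tolerance = 1e-10)
  }
})

test_that("Tm is symmetric under reverse complement and rises with GC", {
  set.seed(7)
  ps <- vapply(1:25, function(i)
    paste(sample(BASES, 20, TRUE), collapse = ""), character(1))
  expect_equal(melting_temperature(ps),
               melting_temperature(reverse_complement(ps)),
               tolerance = 1e-12)
  # a single A -> G substitution strengthens the duplex
  p <- "ATGCATGCATTGCAATGCAT"
  stopifnot(substr(p, 10, 10) == "T")
  q <- p
  substr(q, 10, 10) <- "G"
  expect_gt(melting_temperature(q), melting_temperature(p))
})

test_that("dimer scores match brute-force enumeration", {
  expect_equal(comp_any("AAAA", "TTTT"), 4L)
  expect_equal(comp_any("AAAA", "AAAA"), 0L)
  expect_equal(self_any("ATAT"), 4L)
  expect_equal(comp_end("AAAA", "TTTT"), 4L)
  expect_equal(comp_end("AAAA", "AAAA"), 0L)
  expect_equal(self_end("ACGCGT"), bf_comp_end("ACGCGT", "ACGCGT"))
  set.seed(13)
  for (i in 1:40) {
    p <- paste(sample(BASES, sample(2:9, 1), TRUE), collapse = "")
    q <- paste(sample(BASES, sample(2:9, 1), TRUE), collapse = "")
    expect_equal(comp_any(p, q), bf_comp_any(p, q), label = paste(p, q))
    expect_equal(comp_end(p, q), bf_comp_end(p, q), label = paste(p, q))
  }
})

test_that("3'-end free energy sums the terminal stacks", {
  expect_equal(delta_g_3end("ATATAAAAA"), bf_dg3("ATATAAAAA"))
  expect_equal(delta_g_3end("ATATAAAAA"), 4 * -1.00)
  expect_equal(delta_g_3end("ATGCGCGCG"), bf_dg3("ATGCGCGCG"))
  # GC-rich 3' ends are more stable (more negative) than AT-rich ones
  expect_lt(delta_g_3end("AAAAGCGCG"), delta_g_3end("GGGGATATA"))
  expect_error(delta_g_3end("ACG"), "shorter")
})

test_that("single_filter reports the first violated constraint", {
  sf <- single_filter(strrep("A", 21))
  expect_false(sf$pass)
  expect_equal(sf$reason, "contiguous-residue")
  sf <- single_filter(strrep("GC", 10))
  expect_false(sf$pass)
  expect_equal(sf$reason, "GC-content")
  # construct a primer satisfying every default bound by rejection sampling
  # (GC-biased proposals: the joint Tm/GC window is narrow for uniform
  # composition), then verify each predicate individually
  set.seed(42)
  cand <- NULL
  for (b in 1:40) {
    ps <- vapply(1:50000, function(i)
      paste(sample(BASES, 21, TRUE, prob = c(.21, .29, .29, .21)),
            collapse = ""), character(1))
    hit <- ps[single_filter(ps)$pass]
    if (length(hit) > 0) { cand <- hit[1]; break }
  }
  expect_false(is.null(cand))
  expect_true(melting_temperature(cand) >= 58 &&
                melting_temperature(cand) <= 62)
  expect_true(gc_content(cand) >= 40 && gc_content(cand) <= 60)
  expect_lte(self_any(cand), 5)
  expect_lte(self_end(cand), 3)
  expect_lte(max_homopolymer_run(cand), 5)
  expect_gte(delta_g_3end(cand), -9)
})

test_that("verdict is order-free: pass iff every predicate holds", {
  set.seed(8)
  cfg <- pipeline_config()
  ps <- vapply(1:300, function(i)
    paste(sample(BASES, 20, TRUE), collapse = ""), character(1))
  sf <- single_filter(ps, cfg)
  manual <- melting_temperature(ps) >= cfg$min_tm &
    melting_temperature(ps) <= cfg$max_tm &
    gc_content(ps) >= cfg$min_gc & gc_content(ps) <= cfg$max_gc &
    self_any(ps) <= cfg$max_self_any & self_end(ps) <= cfg$max_self_end &
    max_homopolymer_run(ps) <= cfg$max_run &
    delta_g_3end(ps) >= cfg$min_dg3
  expect_equal(sf$pass, manual)
})

test_that("primer index keeps only single-filter survivors", {
  c1p <- aggregate_sidsets(tibble::tibble(
    P = c("GCT", "*TCT"), sid = c(3L, 4L), pos = c(0L, 0L)))
  # a GC-content window that excludes GCT (67%) but admits TCT (33%)
  cfg <- permissive_config(min_gc = 0, max_gc = 50)
  idx <- build_primer_index(c1p, cfg)
  expect_false("GCT" %in% idx$P)
  expect_true("*TCT" %in% idx$P)
  expect_true(all(idx$valid))
  # empty input and all-pass input
  expect_equal(nrow(build_primer_index(c1p[0, ], cfg)), 0)
  idx_all <- build_primer_index(c1p, permissive_config())
  expect_equal(nrow(idx_all), nrow(c1p))
})

test_that("suffix index applies the clamped trim rule", {
  idx <- tibble::tibble(P = "*TCT", strip = "TCT", len = 3L,
                        sidset = list(c(4L, 5L)), valid = TRUE,
                        tm = NA_real_, gc = NA_real_)
  s1 <- build_suffix_index(idx, trim_depth = 1)
  expect_equal(s1$suffix, "CT")
  expect_equal(s1$Pset[[1]], "*TCT")
  # deep trim clamps to leave a single-base suffix
  s4 <- build_suffix_index(idx, trim_depth = 4)
  expect_equal(s4$suffix, "T")
  # two primers sharing a suffix share a Pset
  idx2 <- tibble::tibble(P = c("AACT", "GGCT"),
                         strip = c("AACT", "GGCT"), len = 4L,
                         sidset = list(1L, 2L), valid = TRUE,
                         tm = NA_real_, gc = NA_real_)
  s2 <- build_suffix_index(idx2, trim_depth = 2)
  expect_equal(s2$Pset[[which(s2$suffix == "CT")]], c("AACT", "GGCT"))
  # a length-1 primer keys on itself
  idx3 <- tibble::tibble(P = "A", strip = "A", len = 1L, sidset = list(0L),
                         valid = TRUE, tm = NA_real_, gc = NA_real_)
  expect_equal(build_suffix_index(idx3, trim_depth = 4)$suffix, "A")
})
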