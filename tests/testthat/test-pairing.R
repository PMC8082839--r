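test_that("sid groups are ordered by forward-primer count", {
  c4 <- tibble::tibble(
    P = c("CGT", "*CAA", "*GAC", "ATG", "AAC", "*TCA", "*TCG"),
    sid = c(7L, 7L, 7L, 2L, 2L, 2L, 2L),
    pos = c(0L, 10L, 20L, 0L, 5L, 30L, 40L)
  )
  g <- group_by_sid(c4)
  expect_equal(g$sid, c(7L, 2L))          # 1 forward < 2 forwards
  expect_equal(g$fwd[[1]]$P, "CGT")
  expect_equal(sort(g$fwd[[2]]$P), c("AAC", "ATG"))
  expect_equal(nrow(g$rev[[1]]), 2)
  # a sid with only forward primers still forms a (pairless) group
  g2 <- group_by_sid(tibble::tibble(P = "AAC", sid = 0L, pos = 0L))
  expect_equal(nrow(g2), 1)
  expect_equal(nrow(g2$rev[[1]]), 0)
  expect_equal(nrow(group_by_sid(c4[0, ])), 0)
})

test_that("pair constraints follow geometry and dimer bounds", {
  cfg <- pipeline_config()
  # reverse site upstream of the forward site
  r <- pair_ok("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA",
               fp_pos = 100L, rp_pos = 10L, config = cfg)
  expect_false(r$pass)
  expect_equal(r$reason, "geometry")
  # full-length complementary primers fail the pair-dimer screen
  fp <- strrep("A", 20)
  rp <- strrep("T", 20)
  r <- pair_ok(fp, rp, 0L, 150L,
               config = permissive_config(max_tm_diff = 100,
                                          min_product = 1,
                                          max_product = 1000))
  expect_false(r$pass)
  expect_equal(r$reason, "pair-any")
  # differing sids are a caller error
  expect_error(pair_ok("ACGT", "ACGT", 0L, 50L, sid_f = 0L, sid_r = 1L),
               "sid")
})

test_that("penalties equal the stated formulas", {
  cfg <- pipeline_config(opt_len = 21, opt_tm = 60, opt_gc = 50,
                         w_len = 1, w_tm = 1, w_gc = 0, w_tmdiff = 1)
  p21 <- strrep("A", 21)
  expect_equal(primer_penalty(p21, tm = 60, gc = 10, cfg), 0)
  expect_equal(primer_penalty(strrep("A", 23), tm = 60, gc = 50, cfg), 2)
  expect_equal(pair_penalty(0, 0, tm_f = 60, tm_r = 60,
                            product_size = 170, cfg), 0)
  expect_equal(pair_penalty(0, 0, tm_f = 61, tm_r = 59,
                            product_size = 170, cfg), 2)
  set.seed(99)
  for (i in 1:50) {
    len <- sample(19:23, 1)
    tm <- runif(1, 50, 70); gc <- runif(1, 30, 70)
    w <- pipeline_config(w_len = runif(1, 0, 2), w_tm = runif(1, 0, 2),
                         w_gc = runif(1, 0, 2))
    expect_equal(primer_penalty(strrep("C", len), tm, gc, w),
                 w$w_len * abs(len - w$opt_len) +
                   w$w_tm * abs(tm - w$opt_tm) +
                   w$w_gc * abs(gc - w$opt_gc))
  }
})

test_that("pairing evaluates all combinations and ranks by penalty", {
  cfg <- synthetic_benchmark_config()
  db <- generate_db(12, 400, seed = 61)
  fit <- design_primers(db, cfg)
  pairs <- tidy(fit)
  expect_gt(nrow(pairs), 0)
  # recompute every surviving pair's penalty independently
  params <- thermo_params()
  expect_equal(
    pairs$penalty,
    (cfg$w_len * abs(nchar(pairs$forward_primer) - cfg$opt_len) +
       cfg$w_tm * abs(pairs$fp_tm - cfg$opt_tm) +
       cfg$w_gc * abs(pairs$fp_gc - cfg$opt_gc)) +
      (cfg$w_len * abs(nchar(pairs$reverse_primer) - cfg$opt_len) +
         cfg$w_tm * abs(pairs$rp_tm - cfg$opt_tm) +
         cfg$w_gc * abs(pairs$rp_gc - cfg$opt_gc)) +
      cfg$w_tmdiff * abs(pairs$fp_tm - pairs$rp_tm),
    tolerance = 1e-12
  )
  # ranks are 1..n within each sid, ascending in penalty
  for (s in unique(pairs$sid)) {
    sub <- pairs[pairs$sid == s, ]
    expect_equal(sub$rank, seq_len(nrow(sub)))
    expect_true(all(diff(sub$penalty) >= -1e-12))
  }
  # every pair satisfies the five constraints
  expect_true(all(abs(nchar(pairs$forward_primer) -
                        nchar(pairs$reverse_primer)) <= cfg$max_len_diff))
  expect_true(all(abs(pairs$fp_tm - pairs$rp_tm) <= cfg$max_tm_diff))
  expect_true(all(pairs$fp_pos + nchar(pairs$forward_primer) <=
                    pairs$rp_pos))
  expect_true(all(pairs$product_size >= cfg$min_product &
                    pairs$product_size <= cfg$max_product))
  expect_equal(pairs$product_size,
               pairs$rp_pos + nchar(pairs$reverse_primer) - pairs$fp_pos)
  expect_true(all(comp_any(pairs$forward_primer, pairs$reverse_primer) <=
                    cfg$max_pair_any))
  expect_true(all(pmax(
    comp_end(pairs$forward_primer, pairs$reverse_primer),
    comp_end(pairs$reverse_primer, pairs$forward_primer)) <=
      cfg$max_pair_end))
})

test_that("combination counts multiply forwards by reverses", {
  # one forward, two reverse occurrences: two candidate combinations
  fwdp <- "ATGCATGCATGCATGCATGCA"
  revp <- "TGCATGCATGCATGCATGCAT"
  c4 <- tibble::tibble(
    P = c(fwdp, paste0("*", revp), paste0("*", revp)),
    sid = 7L,
    pos = c(0L, 120L, 140L)
  )
  cfg <- permissive_config(max_tm_diff = 100, min_product = 1,
                           max_product = 1000, max_pair_any = 99,
                           max_pair_end = 99, max_len_diff = 50)
  res <- run_pair_step(c4, cfg)
  expect_equal(nrow(res), 2)
  expect_equal(res$rank, 1:2)
})

test_that("sidset grouping restricts pairs to identical target sets", {
  fwdp <- "ATGCATGCATGCATGCATGCA"
  revp <- "TGCATGCATGCATGCATGCAT"
  c4 <- tibble::tibble(
    P = c(fwdp, paste0("*", revp)),
    sid = 0L, pos = c(0L, 120L)
  )
  cfg_ok <- permissive_config(max_tm_diff = 100, min_product = 1,
                              max_product = 1000, max_pair_any = 99,
                              max_pair_end = 99, max_len_diff = 50)
  idx_same <- tibble::tibble(P = c(fwdp, paste0("*", revp)),
                             sidset = list(0L, 0L))
  idx_diff <- tibble::tibble(P = c(fwdp, paste0("*", revp)),
                             sidset = list(0L, c(0L, 3L)))
  cfg_ss <- cfg_ok; cfg_ss$group_by <- "sidset"
  expect_equal(nrow(run_pair_step(c4, cfg_ss, primer_index = idx_same)), 1)
  expect_equal(nrow(run_pair_step(c4, cfg_ss, primer_index = idx_diff)), 0)
  expect_error(run_pair_step(c4, cfg_ss), "primer index")
})
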