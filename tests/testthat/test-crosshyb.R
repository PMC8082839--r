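test_that("the worked example invalidates *TCT through the suffix index", {
  fx <- worked_example_fixture()
  after <- filter_5prime(fx$c1p, fx$primer_index, fx$suffix_index,
                         fx$trim_depth)
  expect_false(after$valid[after$P == "*TCT"])
  # the suffix index regenerated from the primer index matches the stored one
  rebuilt <- build_suffix_index(fx$primer_index, fx$trim_depth)
  expect_equal(rebuilt, fx$suffix_index)
  # without the off-target probe row, nothing is invalidated
  no_probe <- fx$c1p[fx$c1p$P != "GCT", ]
  after2 <- filter_5prime(no_probe, fx$primer_index, fx$suffix_index,
                          fx$trim_depth)
  expect_true(after2$valid[after2$P == "*TCT"])
})

test_that("the 5' filter is probe-order independent and matches its oracle", {
  for (seed in c(1, 2, 3)) {
    db <- generate_db(10, 120, seed = seed)
    db <- plant_offtarget(db, primer_len = 12, d = 2, n_events = 2,
                          require_valid_host = FALSE, seed = seed + 50)
    c1p <- aggregate_sidsets(enumerate_candidates(db$records, 10, 12))
    idx <- build_primer_index(c1p, permissive_config())
    sfx <- build_suffix_index(idx, 4)
    got <- filter_5prime(c1p, idx, sfx, 4)
    got_rev <- filter_5prime(c1p[rev(seq_len(nrow(c1p))), ], idx, sfx, 4)
    expect_equal(got$valid, got_rev$valid)
    oracle <- oracle_5prime(c1p, idx, 4)
    expect_equal(got$valid[match(oracle$P, got$P)], oracle$valid)
    expect_gt(sum(!got$valid), 0)  # plants (d inside trim region) do fire
  }
})

test_that("seed length follows the pigeonhole rule", {
  expect_equal(seed_length(3, 1), 1L)
  expect_equal(seed_length(20, 1), 10L)
  expect_equal(seed_length(23, 2), 7L)
  expect_error(seed_length(2, 2), "k \\+ 1")
})

test_that("seed extraction yields k+1 disjoint seeds at fixed offsets", {
  expect_equal(extract_seeds("AAC", 1),
               tibble::tibble(seed = c("A", "A"), index = c(0L, 1L)))
  expect_equal(extract_seeds("ATG", 1),
               tibble::tibble(seed = c("A", "T"), index = c(0L, 1L)))
  s <- extract_seeds(strrep("ACGTT", 4), 1)
  expect_equal(nchar(s$seed), c(10L, 10L))
  expect_equal(s$index, c(0L, 10L))
  # tagged primers are stripped before seeding
  expect_equal(extract_seeds("*ATG", 1), extract_seeds("ATG", 1))
})

test_that("seed index groups primers by seed/offset/length in workload order", {
  idx <- tibble::tibble(
    P = c("AAC", "ATG", "CGT"),
    strip = c("AAC", "ATG", "CGT"),
    len = 3L,
    sidset = list(c(2L, 3L, 4L), c(2L, 3L, 4L), c(1L, 2L)),
    valid = TRUE, tm = NA_real_, gc = NA_real_
  )
  si <- build_seed_index(idx, 1)
  expect_equal(si$Pset[[which(si$key == "A+0+3")]], c("AAC", "ATG"))
  # workload order: singleton groups precede the size-2 group, ties by key
  expect_equal(lengths(si$Pset), sort(lengths(si$Pset)))
  singles <- si$key[lengths(si$Pset) == 1]
  expect_equal(singles, sort(singles))
  # all-invalid index is empty
  idx$valid <- FALSE
  expect_equal(nrow(build_seed_index(idx, 1)), 0)
})

test_that("probe groups cover the index side and follow its order", {
  db <- generate_db(6, 80, seed = 4)
  c1p <- aggregate_sidsets(enumerate_candidates(db$records, 8, 9))
  idx <- build_primer_index(c1p, permissive_config())
  si <- build_seed_index(idx, 1)
  pg <- build_probe_groups(c1p, si, 1)
  m <- match(pg$key, si$key)
  expect_false(any(is.na(m)))
  expect_false(is.unsorted(m, strictly = TRUE))
  # probe groups restricted to valid primers equal the index groups
  for (i in seq_len(nrow(si))) {
    j <- which(pg$key == si$key[i])
    expect_equal(intersect(pg$Pset[[j]], idx$P), si$Pset[[i]])
  }
})

test_that("a round never invalidates on equal sidsets or universal primers", {
  # every primer occurs in every sequence: no off-target sid can exist
  idx <- tibble::tibble(
    P = c("AAC", "ATG"), strip = c("AAC", "ATG"), len = 3L,
    sidset = list(0:2, 0:2), valid = TRUE, tm = NA_real_, gc = NA_real_
  )
  c1p <- idx[, c("P", "strip", "len", "sidset")]
  si <- build_seed_index(idx, 1)
  pg <- build_probe_groups(c1p, si, 1)
  vv <- general_crosshyb_round(si, pg, 1)
  expect_true(all(vv$valid))
})

test_that("rounds error on key-order mismatch between the two tables", {
  idx <- tibble::tibble(
    P = c("AAC", "CGT"), strip = c("AAC", "CGT"), len = 3L,
    sidset = list(0L, 1L), valid = TRUE, tm = NA_real_, gc = NA_real_
  )
  c1p <- idx[, c("P", "strip", "len", "sidset")]
  si <- build_seed_index(idx, 1)
  pg <- build_probe_groups(c1p, si, 1)
  expect_error(general_crosshyb_round(si, pg[rev(seq_len(nrow(pg))), ], 1),
               "key-order")
})

test_that("seed filtering equals the quadratic oracle, round by round", {
  for (seed in c(11, 12, 13, 14)) {
    db <- generate_db(10, 150, seed = seed)
    db <- plant_offtarget(db, primer_len = 11, d = 1, n_events = 1,
                          require_valid_host = FALSE, seed = seed + 70)
    db <- plant_offtarget(db, primer_len = 11, d = 2, n_events = 1,
                          require_valid_host = FALSE, seed = seed + 90)
    c1p <- aggregate_sidsets(enumerate_candidates(db$records, 10, 12))
    idx <- build_primer_index(c1p, permissive_config())
    for (k in 1:2) {
      oracle <- oracle_crosshyb(c1p, idx, k)
      si <- build_seed_index(idx, k)
      pg <- build_probe_groups(c1p, si, k)
      vv <- general_crosshyb_round(si, pg, k)
      bad <- unique(vv$P[!vv$valid])
      impl <- !(oracle$P %in% bad)
      expect_identical(impl, oracle$valid,
                       label = paste("seed", seed, "k", k))
      idx$valid[idx$P %in% bad] <- FALSE
    }
    expect_gt(sum(!idx$valid), 0)
  }
})

test_that("run_crosshyb is monotone and respects snapshot semantics", {
  db <- generate_db(8, 120, seed = 33)
  db <- plant_offtarget(db, primer_len = 10, d = 1, n_events = 2,
                        require_valid_host = FALSE, seed = 77)
  c1 <- enumerate_candidates(db$records, 9, 11)
  c1p <- aggregate_sidsets(c1)
  idx <- build_primer_index(c1p, permissive_config())
  c2 <- c1[c1$P %in% idx$P, ]
  # k = 0: vacuous loop, everything passes through
  ch0 <- run_crosshyb(c1p, idx, c2, 0, permissive_config())
  expect_equal(ch0$c4, c2)
  ch1 <- run_crosshyb(c1p, idx, c2, 1, permissive_config())
  ch2 <- run_crosshyb(c1p, idx, c2, 2, permissive_config())
  # a primer invalidated at k=1 stays invalid after k=2
  bad1 <- ch1$primer_index$P[!ch1$primer_index$valid]
  expect_true(all(!ch2$primer_index$valid[match(bad1, ch2$primer_index$P)]))
  # C4 rows are exactly the C2 rows of still-valid primers
  expect_true(all(ch2$c4$P %in% ch2$primer_index$P[ch2$primer_index$valid]))
  expect_true(nrow(ch2$c4) <= nrow(c2))
})

test_that("round results are invariant to workers and batch sizes", {
  db <- generate_db(8, 140, seed = 55)
  db <- plant_offtarget(db, primer_len = 11, d = 1, n_events = 2,
                        require_valid_host = FALSE, seed = 56)
  c1p <- aggregate_sidsets(enumerate_candidates(db$records, 10, 12))
  idx <- build_primer_index(c1p, permissive_config())
  si <- build_seed_index(idx, 1)
  pg <- build_probe_groups(c1p, si, 1)
  ref <- general_crosshyb_round(si, pg, 1)
  for (w in c(2L, 3L, 8L)) {
    for (b in c(1, 37, Inf)) {
      expect_identical(general_crosshyb_round(si, pg, 1,
                                              n_workers = w,
                                              batch_size = b),
                       ref, label = paste("w", w, "b", b))
    }
  }
})
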