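test_that("recurrence steps count each patient once and match the per-base oracle", {
  calls <- mk_calls(c("A", "B"), "1", c(1, 3), c(5, 8), "loss")
  steps <- build_recurrence_profile(calls, "loss")
  expect_equal(steps$start, c(1e6, 3e6, 5e6))
  expect_equal(steps$end, c(3e6, 5e6, 8e6))
  expect_equal(steps$depth, c(1, 2, 1))

  single <- build_recurrence_profile(mk_calls("A", "1", 1, 5, "loss"), "loss")
  expect_equal(nrow(single), 1)
  expect_equal(single$depth, 1)

  dup <- build_recurrence_profile(mk_calls(c("A", "A"), "1", c(1, 1),
                                           c(5, 5), "loss"), "loss")
  expect_true(all(dup$depth == 1))

  set.seed(23)
  rnd <- mk_calls(sample(LETTERS[1:4], 12, replace = TRUE), "1",
                  s <- sample(0:40, 12, replace = TRUE),
                  s + sample(1:15, 12, replace = TRUE), "loss")
  steps <- build_recurrence_profile(rnd, "loss")
  mids <- (steps$start + steps$end) / 2
  expect_equal(steps$depth, brute_depth(rnd, mids))
})

test_that("recurrence depth conserves per-patient covered length", {
  set.seed(31)
  for (rep in 1:10) {
    rnd <- mk_calls(sample(LETTERS[1:5], 10, replace = TRUE), "1",
                    s <- sample(0:40, 10, replace = TRUE),
                    s + sample(1:10, 10, replace = TRUE), "loss")
    steps <- build_recurrence_profile(rnd, "loss")
    per_patient_union <- sum(vapply(split(rnd, rnd$patient), function(p) {
      covered <- unique(unlist(lapply(seq_len(nrow(p)),
                                      function(k) cells(p$start[k] / 1e6,
                                                        p$end[k] / 1e6))))
      length(covered) * 1e6
    }, numeric(1)))
    expect_equal(sum(steps$depth * (steps$end - steps$start)),
                 per_patient_union)
  }
})

test_that("seeded intersection recovers the published recurrent-loss regions", {
  t4 <- flag_ig(load_fixture("table4"))
  losses <- derive_mcr_candidates(t4, "loss")
  q33 <- losses[losses$chrom == "7" & losses$start == 135.74e6, ]
  expect_equal(q33$end, 137.48e6)
  expect_equal(q33$size_mb, 1.74)
  expect_gte(q33$n_support, 6)
  expect_true(all(c("t-2", "t-5", "t-6", "t-7", "t-8", "t-9") %in%
                  strsplit(q33$patients, ",")[[1]]))

  runx1 <- losses[losses$chrom == "21" & losses$start == 35.11e6, ]
  expect_equal(runx1$end, 35.15e6)
  expect_equal(runx1$n_support, 4)
  expect_identical(strsplit(runx1$patients, ",")[[1]],
                   c("t-11", "t-29", "t-7", "t-8"))

  none <- derive_mcr_candidates(mk_calls(c("A", "B"), "1", c(1, 10),
                                         c(5, 20), "loss"), "loss")
  expect_equal(nrow(none), 0)
})

test_that("every MCR is contained in a call of each supporting patient", {
  t4 <- flag_ig(load_fixture("table4"))
  for (dir in c("loss", "gain")) {
    cands <- derive_mcr_candidates(t4, dir)
    for (k in seq_len(nrow(cands))) {
      pats <- strsplit(cands$patients[k], ",")[[1]]
      for (p in pats) {
        calls <- t4[!t4$ig_flag & t4$patient == p & t4$direction == dir &
                    t4$chrom == cands$chrom[k], , drop = FALSE]
        expect_true(any(calls$start <= cands$start[k] &
                        calls$end >= cands$end[k]),
                    info = paste(dir, cands$chrom[k], cands$start[k], p))
      }
    }
  }
})

test_that("candidate derivation is invariant to input row order", {
  t4 <- flag_ig(load_fixture("table4"))
  ref <- derive_mcr_candidates(t4, "loss")
  set.seed(3)
  shuf <- derive_mcr_candidates(t4[sample(nrow(t4)), ], "loss")
  expect_equal(shuf, ref)
})

test_that("catalog matching requires identical bounds at 10 kb resolution", {
  cands <- data.frame(chrom = "7", start = 27.15e6, end = 27.18e6,
                      direction = "gain", size_mb = 0.03, n_support = 4L,
                      patients = "a,b,c,d", amplified = FALSE)
  catalog <- data.frame(chrom = "7", start = 27.15e6, end = 27.18e6,
                        direction = "gain")
  expect_equal(match_catalog(cands, catalog)$matched, 1L)
  off <- catalog; off$end <- off$end + 1e4
  expect_true(is.na(match_catalog(cands, off)$matched))
  wrongdir <- catalog; wrongdir$direction <- "loss"
  expect_true(is.na(match_catalog(cands, wrongdir)$matched))
  expect_true(all(is.na(match_catalog(cands[0, ], catalog)$matched)))
})

test_that("catalog merge computes group percentages against supplied totals", {
  s1 <- data.frame(chrom = "17", start = 26.49e6, end = 27.52e6,
                   direction = "loss", n_p = 39L, n_t = 5L)
  merged <- merge_mcr_catalogs(list(lit = s1), c(p = 550L, t = 50L))
  expect_equal(merged$pct_p, 7.1)
  expect_equal(merged$pct_t, 10)
  expect_equal(merged$n_p, 39L)

  # two studies with overlapping entries: counts accumulate, location is
  # the intersection
  s2 <- data.frame(chrom = "17", start = 26.9e6, end = 28.1e6,
                   direction = "loss", n_p = 11L, n_t = 0L)
  m2 <- merge_mcr_catalogs(list(a = s1, b = s2), c(p = 550L, t = 50L))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$start, 26.9e6)
  expect_equal(m2$end, 27.52e6)
  expect_equal(m2$n_p, 50L)
  expect_false(m2$spanned)

  expect_error(merge_mcr_catalogs(list(a = s1), c(p = 0L)), "positive")
})
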