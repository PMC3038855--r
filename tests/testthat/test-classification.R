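test_that("classify_ratio maps published ratios to their copy states", {
  expect_identical(classify_ratio(0.16), "DEEP_LOSS")
  expect_identical(classify_ratio(5.46), "HIGH_AMP")
  expect_identical(classify_ratio(3.00), "LOW_AMP")
  expect_identical(classify_ratio(1.0), "NEUTRAL")
  expect_error(classify_ratio(0), "positive")
  expect_error(classify_ratio(-1), "positive")
})

test_that("state boundaries sit exactly at 0.25/0.8/1.2/2/4, inclusive on the aberrant side", {
  expect_identical(classify_ratio(c(0.25, 0.8, 1.2, 2, 4)),
                   c("LOSS", "LOSS", "GAIN", "LOW_AMP", "HIGH_AMP"))
  eps <- 1e-9
  expect_identical(classify_ratio(c(0.25 - eps, 0.8 + eps, 1.2 - eps,
                                    2 - eps, 4 - eps)),
                   c("DEEP_LOSS", "NEUTRAL", "NEUTRAL", "GAIN", "LOW_AMP"))
  # total monotone step function over a grid
  grid <- seq(0.01, 6, by = 0.01)
  states <- classify_ratio(grid)
  rank <- match(states, c("DEEP_LOSS", "LOSS", "NEUTRAL", "GAIN",
                          "LOW_AMP", "HIGH_AMP"))
  expect_true(all(diff(rank) >= 0))
  expect_false(anyNA(rank))
})

test_that("germline CNV flagging needs database support or all of size+breakpoints+locus", {
  db <- data.frame(chrom = "22", start = 22.65e6, end = 22.72e6,
                   direction = "both")
  loci <- db[, c("chrom", "start", "end")]
  params <- cnv_filter_params(cnv_gene_loci = loci,
                              ig_loci = load_fixture("ig_loci"))
  # recurrent identical 70 kb loss matching the database -> CNV, all criteria
  calls <- mk_calls(c("A", "B", "C"), "22", rep(22.65, 3), rep(22.72, 3),
                    "loss")
  out <- flag_cnv(calls, db, params)
  expect_true(all(out$cnv_flag))
  expect_true(all(grepl("iv", out$cnv_reason)))
  expect_true(all(grepl("i\\+ii\\+iii", out$cnv_reason)))

  # an 82 Mb 5q loss fails the size criterion and has no database match
  big <- flag_cnv(mk_calls("A", "5", 85.18, 167.84, "loss"), db, params)
  expect_false(big$cnv_flag)

  # identical focal breakpoints in 4 patients, but no database or locus
  # support: stays an acquired CNA (the recurrent 7p15.2 gain pattern)
  hox <- mk_calls(c("A", "B", "C", "D"), "7", rep(27.15, 4), rep(27.18, 4),
                  "gain")
  out2 <- flag_cnv(hox, db, params)
  expect_false(any(out2$cnv_flag))
})

test_that("flag_cnv is idempotent and independent of cohort ordering", {
  db <- data.frame(chrom = "22", start = 22.65e6, end = 22.72e6,
                   direction = "both")
  params <- cnv_filter_params(cnv_gene_loci = db[, 1:3],
                              ig_loci = load_fixture("ig_loci"))
  calls <- rbind(mk_calls(c("A", "B"), "22", c(22.65, 22.65),
                          c(22.72, 22.72), "loss"),
                 mk_calls("C", "5", 85, 167, "loss"))
  once <- flag_cnv(calls, db, params)
  twice <- flag_cnv(once, db, params)
  expect_identical(once$cnv_flag, twice$cnv_flag)
  shuffled <- flag_cnv(calls[c(3, 1, 2), ], db, params)
  expect_identical(shuffled$cnv_flag[order(c(3, 1, 2))], once$cnv_flag)
})

test_that("IG flagging marks focal losses inside IG/TR clusters, never gains", {
  params <- cnv_filter_params()
  igh <- flag_ig(mk_calls("A", "14", 105.96, 106.00, "loss"), params)
  expect_true(igh$ig_flag)
  expect_identical(igh$ig_locus, "IGH")
  igk <- flag_ig(mk_calls("A", "2", 89.10, 89.89, "loss"), params)
  expect_true(igk$ig_flag)
  expect_identical(igk$ig_locus, "IGK")
  gain <- flag_ig(mk_calls("A", "14", 105.96, 106.00, "gain"), params)
  expect_false(gain$ig_flag)
  # a whole-arm loss sweeping over a TR locus is not a VDJ deletion
  arm <- flag_ig(mk_calls("A", "7", 0.14, 57.89, "loss"), params)
  expect_false(arm$ig_flag)
})

test_that("IG flags recomputed on the cohort fixtures equal the printed asterisks", {
  params <- cnv_filter_params()
  t4 <- flag_ig(load_fixture("table4"), params)
  expect_identical(t4$ig_flag, t4$ig_printed)
  expect_equal(sum(t4$ig_flag), 14)  # 4 IGK + 10 IGH rows
  expect_equal(length(unique(t4$patient[t4$ig_flag])), 11)
  t5 <- flag_ig(load_fixture("table5"), params)
  expect_identical(t5$ig_flag, t5$ig_printed)
  expect_equal(sum(t5$ig_flag), 5)
})
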