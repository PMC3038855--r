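test_that("band lookup places positions in their cytoband", {
  bands <- load_fixture("cytobands")
  expect_identical(band_of("21", 35.12e6, bands), "q22.12")
  expect_identical(band_of("21", 1, bands), "p13")
  expect_error(band_of("21", 50e6, bands), "outside chromosome")
})

test_that("CNA tokens render in the tables' dialect", {
  loss <- mk_calls("t-2", "7", 135.74, 137.48, "loss", ratio = 0.16,
                   state = "DEEP_LOSS")
  loss$bands <- "q33q34"
  expect_identical(format_cna(loss), "−7q33q34<135.74–137.48>[0.16]")

  gain <- mk_calls("t-19", "7", 27.15, 27.18, "gain", ratio = 1.40)
  gain$bands <- "p15.2"
  expect_identical(format_cna(gain), "+7p15.2<27.15–27.18>[1.40]")
  expect_identical(format_cna(gain, with_ratio = FALSE),
                   "+7p15.2<27.15–27.18>")

  neutral <- gain; neutral$state <- "NEUTRAL"
  expect_error(format_cna(neutral), "neutral")
})

test_that("notation parsing is lenient and inverts formatting", {
  p <- parse_cna_notation("−7q33q34<135.74–137.48>[0.16]")
  expect_identical(p$direction, "loss")
  expect_identical(p$chrom, "7")
  expect_identical(p$bands, "q33q34")
  expect_equal(p$start, 135.74e6)
  expect_equal(p$end, 137.48e6)
  expect_equal(p$ratio, 0.16)

  # decimal commas, plain hyphen, space before '<', no ratio
  q <- parse_cna_notation("+7p15.2 <27,15-27,18>")
  expect_identical(q$direction, "gain")
  expect_equal(q$start, 27.15e6)
  expect_equal(q$end, 27.18e6)
  expect_true(is.na(q$ratio))

  expect_error(parse_cna_notation("banana"), "cannot parse")
})

test_that("format and parse are mutually inverse on every fixture row", {
  for (tab in c("table4", "table5")) {
    calls <- load_fixture(tab)
    for (k in seq_len(nrow(calls))) {
      tok <- format_cna(calls[k, ])
      back <- parse_cna_notation(tok)
      expect_identical(back$direction, calls$direction[k])
      expect_identical(back$chrom, calls$chrom[k])
      expect_identical(back$bands, calls$bands[k])
      expect_equal(back$start, calls$start[k])
      expect_equal(back$end, calls$end[k])
      expect_equal(back$ratio, calls$ratio[k])
      # format(parse(token)) reproduces the token
      expect_identical(format_cna(cbind(back, state = calls$state[k])), tok)
    }
  }
})

test_that("contiguous fusion merges near-equal ratios and keeps deep losses distinct", {
  near <- mk_calls(c("A", "A"), "1", c(1, 5), c(5, 9), "loss",
                   ratio = c(0.60, 0.62))
  fused <- fuse_contiguous(near)
  expect_equal(nrow(fused), 1)
  expect_equal(fused$start, 1e6)
  expect_equal(fused$end, 9e6)
  expect_equal(fused$ratio, 2^mean(log2(c(0.60, 0.62))), tolerance = 1e-6)

  # the 18q pattern: heterozygous loss next to a deep loss is not fused
  deep <- mk_calls(c("t-2", "t-2"), "18", c(16.79, 21.74), c(21.74, 24.41),
                   "loss", ratio = c(0.59, 0.22))
  expect_equal(nrow(fuse_contiguous(deep)), 2)

  far <- mk_calls(c("A", "A"), "1", c(1, 35), c(5, 40), "loss",
                  ratio = c(0.6, 0.6))
  expect_equal(nrow(fuse_contiguous(far)), 2)

  # never across chromosomes or directions
  mixed <- rbind(mk_calls("A", "1", 1, 5, "loss", ratio = 0.6),
                 mk_calls("A", "2", 5, 9, "loss", ratio = 0.6),
                 mk_calls("A", "2", 9, 13, "gain", ratio = 1.4))
  expect_equal(nrow(fuse_contiguous(mixed)), 3)
})

test_that("karyotype synthesis appends fused band tokens to the prefix", {
  expect_identical(synthesize_karyotype(mk_calls("x", "1", 1, 2, "loss")[0, ],
                                        "46,XX"), "46,XX")

  t4 <- flag_ig(load_fixture("table4"))
  t29 <- t4[t4$patient == "t-29", ]
  expect_identical(synthesize_karyotype(t29, "46,XY"),
                   "46,XY,−21q22.1")
  t25 <- t4[t4$patient == "t-25", ]  # IG-only patient
  expect_identical(synthesize_karyotype(t25, "46,XX"), "46,XX")
})
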