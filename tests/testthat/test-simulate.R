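test_that("the clonal mixture ratio model behaves at its anchors", {
  expect_equal(expected_ratio(2, 0.3), 1.0)
  expect_equal(expected_ratio(2, 1), 1.0)
  expect_equal(expected_ratio(1, 0.8), 0.6)
  expect_equal(expected_ratio(0, 0.9), 0.1)
  expect_equal(expected_ratio(4, 0.5), 1.5)
  expect_error(expected_ratio(-1, 0.5), "copy_number")
  expect_error(expected_ratio(2, 1.5), "clonal_fraction")
})

test_that("a fixed seed fully determines simulated cohorts", {
  cfg <- sim_config(genome = toy_genome(40e6), probe_spacing_bp = 5e4,
                    n_patients = c("t-AML" = 2, "p-AML" = 2),
                    size_range_mb = c(0.2, 5), whole_chrom_prob = 0,
                    seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$profiles[[1]]$forward$probes,
                   b$profiles[[1]]$forward$probes)
  c <- simulate_cohort(sim_config(genome = toy_genome(40e6),
                                  probe_spacing_bp = 5e4,
                                  n_patients = c("t-AML" = 2, "p-AML" = 2),
                                  size_range_mb = c(0.2, 5),
                                  whole_chrom_prob = 0, seed = 43))
  expect_false(identical(a$truth, c$truth))
})

test_that("simulated CNA counts match the configured Poisson mean at n = 1000", {
  cfg <- sim_config(genome = toy_genome(200e6),
                    n_patients = c("t-AML" = 1000, "p-AML" = 0),
                    cna_mean = c("t-AML" = 3.46, "p-AML" = 1.9),
                    ig_prob = c("t-AML" = 0, "p-AML" = 0),
                    size_range_mb = c(0.5, 20), whole_chrom_prob = 0,
                    seed = 101)
  sim <- simulate_cohort(cfg, probes = FALSE)
  counts <- table(factor(sim$truth$patient,
                         levels = sprintf("t-%03d", 1:1000)))
  se <- sqrt(3.46 / 1000)
  expect_lt(abs(mean(counts) - 3.46), 3 * se)
})

test_that("noise-free simulation is recovered exactly by the calling pipeline", {
  cfg <- sim_config(genome = toy_genome(60e6), probe_spacing_bp = 2e4,
                    n_patients = c("t-AML" = 0, "p-AML" = 3),
                    cna_mean = c("t-AML" = 0, "p-AML" = 3),
                    size_range_mb = c(0.5, 10), whole_chrom_prob = 0,
                    noise_sd = 0, clonal_fraction_range = c(0.8, 1),
                    loss_cn = 1, gain_cn = 4,
                    ig_prob = c("t-AML" = 0, "p-AML" = 0), seed = 5)
  sim <- simulate_cohort(cfg)
  for (pid in names(sim$profiles)) {
    calls <- call_cna(sim$profiles[[pid]], genome = cfg$genome)
    truth <- sim$truth[sim$truth$patient == pid, , drop = FALSE]
    truth <- truth[truth$n_probes >= 5, , drop = FALSE]
    expect_equal(nrow(calls), nrow(truth))
    truth <- truth[order(truth$start), ]
    calls <- calls[order(calls$start), ]
    for (k in seq_len(nrow(truth))) {
      # recovered bounds are the truth snapped to the probe grid
      sp <- cfg$probe_spacing_bp
      first <- (floor(truth$start[k] / sp) + 1) * sp
      last <- floor(truth$end[k] / sp) * sp
      expect_equal(calls$start[k], first)
      expect_equal(calls$end[k], last)
      expect_identical(calls$direction[k], truth$direction[k])
      expect_equal(calls$ratio[k], truth$expected_ratio[k], tolerance = 1e-9)
    }
  }
})

test_that("implanted germline CNVs and IG deletions are flagged by the filters", {
  panel <- data.frame(chrom = "1", start = c(10e6, 30e6),
                      end = c(10.4e6, 30.3e6), direction = "loss",
                      frequency = 1)
  cfg <- sim_config(genome = toy_genome(60e6), probe_spacing_bp = 2e4,
                    n_patients = c("t-AML" = 0, "p-AML" = 3),
                    cna_mean = c("t-AML" = 0, "p-AML" = 0),
                    noise_sd = 0, cnv_panel = panel,
                    clonal_fraction_range = c(1, 1),
                    ig_prob = c("t-AML" = 0, "p-AML" = 1),
                    ig_loci = data.frame(name = "IGH", chrom = "1",
                                         start = 50e6, end = 52e6),
                    seed = 9)
  sim <- simulate_cohort(cfg)
  all_calls <- do.call(rbind, lapply(names(sim$profiles), function(pid) {
    cc <- call_cna(sim$profiles[[pid]], genome = cfg$genome)
    cc$patient <- pid
    cc
  }))
  params <- cnv_filter_params(cnv_gene_loci = panel[, 1:3],
                              ig_loci = cfg$ig_loci)
  ann <- annotate_calls(all_calls, cnv_db = panel, params = params)
  cnv_calls <- ann[ann$start < 40e6, ]
  ig_calls <- ann[ann$start >= 50e6, ]
  expect_true(nrow(cnv_calls) > 0)
  expect_true(all(cnv_calls$cnv_flag))        # identical breakpoints + db
  expect_true(nrow(ig_calls) > 0)
  expect_true(all(ig_calls$ig_flag))
  # IG implants never reach MCR candidates
  expect_equal(nrow(derive_mcr_candidates(ann[ann$ig_flag | ann$start >= 50e6, ],
                                          "loss")), 0)
})
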