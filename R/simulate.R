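#' Expected linear ratio of a clonal copy-number event
#'
#' Mixture of a diploid normal fraction and a tumor clone at the given copy
#' number: `1 + f * (cn/2 - 1)`. This is the attenuation model that makes a
#' monosomy in an 80%-blast sample read out near 0.6 rather than 0.5.
#'
#' @param copy_number integer copy number >= 0 (2 = neutral).
#' @param clonal_fraction fraction of tumor cells carrying the event, in
#'   \[0, 1\].
#' @return linear ratio.
#' @export
expected_ratio <- function(copy_number, clonal_fraction) {
  if (any(copy_number < 0) || any(clonal_fraction < 0) ||
      any(clonal_fraction > 1))
    stop("copy_number must be >= 0 and clonal_fraction in [0, 1]")
  1 + clonal_fraction * (copy_number / 2 - 1)
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions of the cohorts the pipeline was
#' built around: group sizes 30 (t-AML) and 36 (p-AML); mean CNA counts
#' 3.46 and 1.9 per case; loss:gain odds 63:41 and 1:1; clonal fraction
#' uniform on \[0.6, 1\] (samples were selected for at least 60% blasts);
#' probe noise sd 0.15 log2 units; dye-swap pairs for the t-AML group only.
#'
#' @param genome [genome_model()]; defaults to hg18 lengths. Tests and
#'   examples typically pass a reduced genome to keep probe counts small.
#' @param probe_spacing_bp probe grid spacing (default 12000, the density
#'   of a 244k feature genome-wide array).
#' @param n_patients named vector, patients per group.
#' @param cna_mean named vector, mean CNA count per patient per group.
#' @param loss_gain_odds named list `c(loss, gain)` odds per group.
#' @param size_range_mb log-uniform CNA size bounds, Mb.
#' @param whole_chrom_prob probability an event is a whole-chromosome
#'   gain/loss (monosomy-7-like; default 0.1).
#' @param clonal_fraction_range uniform bounds of the clonal fraction.
#' @param noise_sd probe-level Gaussian noise sd, log2 units.
#' @param loss_cn,gain_cn copy numbers used for simulated losses and gains
#'   (defaults 1 and 3; amplification studies may raise `gain_cn`).
#' @param cnv_panel data.frame of germline CNV regions with a
#'   `frequency` column (population carrier frequency); implanted with
#'   identical breakpoints across carriers. NULL disables.
#' @param ig_prob named vector, probability per group of an IG VDJ
#'   deletion (defaults 8/30 and 2/36).
#' @param ig_loci IG/TR loci used for IG implants.
#' @param dye_swap named logical vector, emit forward/reverse pairs.
#' @param seed integer seed; fixed seed gives identical output.
#' @return named list of simulation parameters.
#' @export
sim_config <- function(genome = default_genome(),
                       probe_spacing_bp = 12000,
                       n_patients = c("t-AML" = 30, "p-AML" = 36),
                       cna_mean = c("t-AML" = 3.46, "p-AML" = 1.9),
                       loss_gain_odds = list("t-AML" = c(63, 41),
                                             "p-AML" = c(1, 1)),
                       size_range_mb = c(0.1, 100),
                       whole_chrom_prob = 0.1,
                       clonal_fraction_range = c(0.6, 1),
                       noise_sd = 0.15,
                       loss_cn = 1, gain_cn = 3,
                       cnv_panel = NULL,
                       ig_prob = c("t-AML" = 8 / 30, "p-AML" = 2 / 36),
                       ig_loci = NULL,
                       dye_swap = c("t-AML" = TRUE, "p-AML" = FALSE),
                       seed = 1L) {
  stopifnot(probe_spacing_bp > 0, all(n_patients >= 0), all(cna_mean >= 0),
            all(clonal_fraction_range >= 0), all(clonal_fraction_range <= 1),
            noise_sd >= 0, all(ig_prob >= 0), all(ig_prob <= 1))
  if (is.null(ig_loci) && any(ig_prob > 0))
    ig_loci <- tryCatch(load_fixture("ig_loci"), error = function(e) NULL)
  list(genome = genome, probe_spacing_bp = probe_spacing_bp,
       n_patients = n_patients, cna_mean = cna_mean,
       loss_gain_odds = loss_gain_odds, size_range_mb = size_range_mb,
       whole_chrom_prob = whole_chrom_prob,
       clonal_fraction_range = clonal_fraction_range, noise_sd = noise_sd,
       loss_cn = loss_cn, gain_cn = gain_cn, cnv_panel = cnv_panel,
       ig_prob = ig_prob, ig_loci = ig_loci, dye_swap = dye_swap,
       seed = as.integer(seed))
}

# place n events of given sizes uniformly on the genome without overlap;
# the start is uniform over the genomic positions where the event fits.
place_events <- function(n, sizes, genome, existing = NULL, max_try = 200) {
  placed <- existing
  out <- list()
  for (k in seq_len(n)) {
    fits <- which(genome$length > sizes[k])
    if (length(fits) == 0)
      stop("event of size ", sizes[k], " bp exceeds every chromosome")
    slack <- genome$length[fits] - sizes[k]
    ok <- FALSE
    for (t in seq_len(max_try)) {
      ci <- fits[sample.int(length(fits), 1, prob = slack)]
      off <- stats::runif(1, 0, genome$length[ci] - sizes[k])
      s <- off; e <- off + sizes[k]; ch <- genome$chrom[ci]
      clash <- !is.null(placed) && nrow(placed) > 0 &&
        any(placed$chrom == ch & placed$start < e & placed$end > s)
      if (!clash) {
        row <- data.frame(chrom = ch, start = s, end = e,
                          stringsAsFactors = FALSE)
        placed <- rbind(placed, row)
        out[[k]] <- row
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place event of size ", sizes[k],
                  " bp: genome too dense")
  }
  do.call(rbind, out)
}

#' Simulate an aCGH cohort with ground truth
#'
#' For each patient, a Poisson number of CNAs (group mean) is placed
#' uniformly without overlap (log-uniform sizes, occasional
#' whole-chromosome events), each with its own clonal fraction; germline
#' CNVs from the panel are implanted with identical breakpoints in all
#' carriers; IG VDJ deletions are implanted at the configured loci as
#' clonal losses. Probe log2 ratios are `log2(expected_ratio) + noise`;
#' dye-swap groups emit forward and negated-reverse copies with
#' independent noise. A fixed seed fully determines the output.
#'
#' @param config [sim_config()].
#' @param probes emit probe-level profiles (set FALSE for truth-only runs,
#'   e.g. large count calibrations).
#' @return list with `truth` (per-event table: patient, group, chrom,
#'   start, end, direction, copy_number, clonal_fraction, category,
#'   expected_ratio, n_probes) and `profiles` (per patient: a
#'   `probe_profile`, or a list(forward, reverse) pair for dye-swap
#'   groups; NULL when `probes = FALSE`).
#' @export
simulate_cohort <- function(config = sim_config(), probes = TRUE) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  genome <- config$genome
  truth <- list()
  profiles <- list()
  for (grp in names(config$n_patients)) {
    n_pat <- config$n_patients[[grp]]
    odds <- config$loss_gain_odds[[grp]]
    for (i in seq_len(n_pat)) {
      pid <- sprintf("%s-%03d", sub("-AML", "", grp), i)
      events <- NULL
      n_cna <- stats::rpois(1, config$cna_mean[[grp]])
      if (n_cna > 0) {
        whole <- stats::runif(n_cna) < config$whole_chrom_prob
        sizes <- exp(stats::runif(n_cna, log(config$size_range_mb[1]),
                                  log(config$size_range_mb[2]))) * BP_PER_MB
        sizes <- pmin(sizes, 0.9 * max(genome$length))
        dirs <- ifelse(stats::runif(n_cna) < odds[1] / sum(odds),
                       "loss", "gain")
        rows <- vector("list", n_cna)
        placed <- NULL
        for (k in which(whole)) {
          ci <- sample(nrow(genome), 1)
          rows[[k]] <- data.frame(chrom = genome$chrom[ci], start = 0,
                                  end = genome$length[ci])
        }
        if (any(whole)) placed <- do.call(rbind, rows[whole])
        loc <- place_events(sum(!whole), sizes[!whole], genome,
                            existing = placed)
        li <- 0
        for (k in which(!whole)) {
          li <- li + 1
          rows[[k]] <- loc[li, , drop = FALSE]
        }
        events <- do.call(rbind, rows)
        events$direction <- dirs
        events$copy_number <- ifelse(dirs == "loss", config$loss_cn,
                                     config$gain_cn)
        events$category <- "CNA"
      }
      # germline CNVs: identical breakpoints across carriers
      if (!is.null(config$cnv_panel) && nrow(config$cnv_panel) > 0) {
        carrier <- stats::runif(nrow(config$cnv_panel)) < config$cnv_panel$frequency
        if (any(carrier)) {
          cnv <- config$cnv_panel[carrier, c("chrom", "start", "end"),
                                  drop = FALSE]
          cnv$direction <- if (!is.null(config$cnv_panel$direction))
            config$cnv_panel$direction[carrier] else "loss"
          cnv$copy_number <- ifelse(cnv$direction == "loss", 1, 3)
          cnv$category <- "CNV"
          events <- rbind(events, cnv)
        }
      }
      # IG VDJ deletion
      if (!is.null(config$ig_loci) && config$ig_prob[[grp]] > 0 &&
          stats::runif(1) < config$ig_prob[[grp]]) {
        li <- config$ig_loci[sample(nrow(config$ig_loci), 1), , drop = FALSE]
        width <- li$end - li$start
        ds <- li$start + stats::runif(1, 0, 0.5) * width
        de <- ds + stats::runif(1, 0.05, 0.5) * width
        de <- min(de, li$end)
        events <- rbind(events,
                        data.frame(chrom = li$chrom, start = ds, end = de,
                                   direction = "loss", copy_number = 1,
                                   category = "IG"))
      }
      if (!is.null(events) && nrow(events) > 0) {
        events$clonal_fraction <-
          stats::runif(nrow(events), config$clonal_fraction_range[1],
                       config$clonal_fraction_range[2])
        events$expected_ratio <- expected_ratio(events$copy_number,
                                                events$clonal_fraction)
        events$n_probes <- pmax(0, floor(events$end / config$probe_spacing_bp)
                                - floor(events$start / config$probe_spacing_bp))
        events <- cbind(patient = pid, group = grp, events)
        truth[[length(truth) + 1]] <- events
      }
      if (probes) {
        grid <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
          pos <- seq(config$probe_spacing_bp, genome$length[ci],
                     by = config$probe_spacing_bp)
          data.frame(chrom = genome$chrom[ci], start = pos, end = pos,
                     stringsAsFactors = FALSE)
        }))
        grid$probe_id <- paste0("P", seq_len(nrow(grid)))
        signal <- rep(0, nrow(grid))
        if (!is.null(events) && nrow(events) > 0) {
          for (k in seq_len(nrow(events))) {
            idx <- grid$chrom == events$chrom[k] &
              grid$start > events$start[k] & grid$start <= events$end[k]
            signal[idx] <- log2(events$expected_ratio[k])
          }
        }
        mk <- function(x, role) probe_profile(
          pid, data.frame(probe_id = grid$probe_id, chrom = grid$chrom,
                          start = grid$start, end = grid$end,
                          log2_ratio = x, stringsAsFactors = FALSE),
          role = role, genome = genome)
        if (isTRUE(config$dye_swap[[grp]])) {
          fwd <- signal + stats::rnorm(nrow(grid), 0, config$noise_sd)
          rev <- -signal + stats::rnorm(nrow(grid), 0, config$noise_sd)
          profiles[[pid]] <- list(forward = mk(fwd, "forward"),
                                  reverse = mk(rev, "reverse"))
        } else {
          profiles[[pid]] <- mk(signal + stats::rnorm(nrow(grid), 0,
                                                      config$noise_sd),
                                "combined")
        }
      }
    }
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(patient = character(0), group = character(0),
               chrom = character(0), start = numeric(0), end = numeric(0),
               direction = character(0), copy_number = numeric(0),
               category = character(0), clonal_fraction = numeric(0),
               expected_ratio = numeric(0), n_probes = numeric(0))
  rownames(truth) <- NULL
  list(truth = truth, profiles = if (probes) profiles else NULL)
}
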