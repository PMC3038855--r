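#' Detection parameters for aberration calling
#'
#' The reproducible filters of the detection step: a surviving aberration
#' needs at least `min_probes` probes and |mean log2 ratio| above
#' `min_abs_log2`. The changepoint threshold is `penalty_mult * log(n)` on
#' the squared two-sample t statistic (n = probes in the region under
#' test). Regions overlapping an artifact mask (by default the terminal
#' `telomere_mask_kb` of every chromosome, standing in for high-copy
#' repetitive / GC-rich and telomeric sequence) by at least half their
#' length are discarded.
#'
#' @param min_probes minimum probes per reported aberration (default 5).
#' @param min_abs_log2 minimum |mean log2 ratio| (default 0.3).
#' @param merge_gap_probes maximum probe gap bridged when merging adjacent
#'   segments (default 0: only abutting segments merge).
#' @param penalty_mult changepoint penalty multiplier (default 10).
#' @param merge_mean_tol adjacent segments whose means differ by less than
#'   this (log2 units) are merged back (default 0.1).
#' @param artifact_masks optional data.frame of masked intervals
#'   (chrom/start/end bp); overrides the telomere default.
#' @param telomere_mask_kb width of the default terminal masks (default 100).
#' @param max_exact_n regions up to this many probes use the exact O(n^2)
#'   changepoint search; larger regions use a width-grid approximation with
#'   local edge refinement (default 1200).
#' @return named list of parameters.
#' @export
detection_params <- function(min_probes = 5, min_abs_log2 = 0.3,
                             merge_gap_probes = 0, penalty_mult = 10,
                             merge_mean_tol = 0.1, artifact_masks = NULL,
                             telomere_mask_kb = 100, max_exact_n = 1200) {
  stopifnot(min_probes >= 1, min_abs_log2 > 0, penalty_mult > 0,
            merge_mean_tol >= 0, telomere_mask_kb >= 0)
  list(min_probes = min_probes, min_abs_log2 = min_abs_log2,
       merge_gap_probes = merge_gap_probes, penalty_mult = penalty_mult,
       merge_mean_tol = merge_mean_tol, artifact_masks = artifact_masks,
       telomere_mask_kb = telomere_mask_kb, max_exact_n = max_exact_n)
}

#' Combine a dye-swap pair of profiles
#'
#' Two-color hybridizations repeated with the fluorophores exchanged carry
#' the same copy-number signal with opposite sign; combining them cancels
#' dye bias. Per probe the combined log2 ratio is the mean of the forward
#' value and the negated reverse value. Probes on which the two
#' hybridizations disagree by more than `discordance_tol` (log2 units,
#' comparing forward against negated reverse) are flagged discordant and
#' excluded from segmentation.
#'
#' @param forward,reverse `probe_profile` objects with matching probe sets
#'   and roles `"forward"` / `"reverse"`.
#' @param discordance_tol log2 tolerance, default 0.5.
#' @return a combined `probe_profile`; discordant probes are recorded in
#'   `attr(, "discordant")`.
#' @export
combine_dye_swap <- function(forward, reverse, discordance_tol = 0.5) {
  f <- forward$probes; r <- reverse$probes
  if (nrow(f) != nrow(r) ||
      !identical(f$probe_id, r$probe_id) ||
      !identical(f$chrom, r$chrom) || !identical(f$start, r$start)) {
    off <- union(setdiff(f$probe_id, r$probe_id),
                 setdiff(r$probe_id, f$probe_id))
    stop("dye-swap pair has mismatched probe sets",
         if (length(off) > 0) paste0(" (e.g. ",
           paste(utils::head(off, 5), collapse = ", "), ")"))
  }
  neg_rev <- -r$log2_ratio
  combined <- (f$log2_ratio + neg_rev) / 2
  discordant <- abs(f$log2_ratio - neg_rev) > discordance_tol
  probes <- f
  probes$log2_ratio <- combined
  out <- probe_profile(forward$sample_id, probes[!discordant, , drop = FALSE],
                       role = "combined", genome = forward$genome)
  attr(out, "discordant") <- f$probe_id[discordant]
  out
}

# Exact best-window search: over all (i, j), compare mean of x[i..j] against
# the rest of the region with a pooled-variance two-sample t^2. Returns the
# maximizing window (the whole region is never a candidate).
best_window_exact <- function(x) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  tot <- cs[n + 1]; ss_tot <- sum(x^2)
  best <- list(t2 = -Inf, i = NA_integer_, j = NA_integer_)
  for (i in seq_len(n)) {
    j <- i:n
    if (i == 1) j <- j[j < n]  # the full region is not a candidate
    if (length(j) == 0) next
    n1 <- j - i + 1
    n2 <- n - n1
    s1 <- cs[j + 1] - cs[i]
    m1 <- s1 / n1; m2 <- (tot - s1) / n2
    rss <- ss_tot - n1 * m1^2 - n2 * m2^2
    s2 <- pmax(rss / pmax(n - 2, 1), 1e-20)
    t2 <- (m1 - m2)^2 / (s2 * (1 / n1 + 1 / n2))
    k <- which.max(t2)
    if (t2[k] > best$t2) best <- list(t2 = t2[k], i = i, j = j[k])
  }
  best
}

window_t2 <- function(cs, ss_tot, n, i, j) {
  n1 <- j - i + 1; n2 <- n - n1
  if (n2 <= 0) return(-Inf)
  s1 <- cs[j + 1] - cs[i]
  m1 <- s1 / n1; m2 <- (cs[n + 1] - s1) / n2
  rss <- ss_tot - n1 * m1^2 - n2 * m2^2
  s2 <- max(rss / max(n - 2, 1), 1e-20)
  (m1 - m2)^2 / (s2 * (1 / n1 + 1 / n2))
}

# Approximate best-window search for long regions: scan a grid of window
# widths (all short widths, then geometric), then refine both edges locally.
best_window_grid <- function(x) {
  n <- length(x)
  cs <- c(0, cumsum(x)); ss_tot <- sum(x^2); tot <- cs[n + 1]
  widths <- unique(c(1:32, round(32 * 1.2^(1:60))))
  widths <- widths[widths < n]
  best <- list(t2 = -Inf, i = NA, j = NA)
  for (w in widths) {
    i <- 1:(n - w + 1)
    if (w == n) next
    j <- i + w - 1
    n1 <- w; n2 <- n - w
    s1 <- cs[j + 1] - cs[i]
    m1 <- s1 / n1; m2 <- (tot - s1) / n2
    rss <- ss_tot - n1 * m1^2 - n2 * m2^2
    s2 <- pmax(rss / max(n - 2, 1), 1e-20)
    t2 <- (m1 - m2)^2 / (s2 * (1 / n1 + 1 / n2))
    drop_full <- which(i == 1 & j == n)
    if (length(drop_full) > 0) t2[drop_full] <- -Inf
    k <- which.max(t2)
    if (t2[k] > best$t2) best <- list(t2 = t2[k], i = i[k], j = j[k])
  }
  if (!is.finite(best$t2)) return(best)
  # local refinement of both edges, a couple of passes
  for (pass in 1:3) {
    g <- max(3L, ceiling(0.15 * (best$j - best$i + 1)))
    for (edge in c("i", "j")) {
      cand <- if (edge == "i") {
        ii <- max(1L, best$i - g):min(best$j, best$i + g)
        cbind(ii, best$j)
      } else {
        jj <- max(best$i, best$j - g):min(n, best$j + g)
        cbind(best$i, jj)
      }
      t2s <- apply(cand, 1, function(p) {
        if (p[1] == 1 && p[2] == n) return(-Inf)
        window_t2(cs, ss_tot, n, p[1], p[2])
      })
      k <- which.max(t2s)
      if (t2s[k] > best$t2)
        best <- list(t2 = t2s[k], i = cand[k, 1], j = cand[k, 2])
    }
  }
  best
}

# Recursive binary segmentation of one chromosome's ordered log2 ratios.
# Returns integer changepoints (last index of each segment).
segment_indices <- function(x, params) {
  n <- length(x)
  if (n < 4) return(n)
  bw <- if (n <= params$max_exact_n) best_window_exact(x) else best_window_grid(x)
  if (!is.finite(bw$t2) || bw$t2 <= params$penalty_mult * log(n)) return(n)
  i <- bw$i; j <- bw$j
  cuts <- integer(0)
  if (i > 1) cuts <- c(cuts, segment_indices(x[1:(i - 1)], params))
  cuts <- c(cuts, if (i > 1) i - 1 + segment_indices(x[i:j], params)
                  else segment_indices(x[i:j], params))
  if (j < n) cuts <- c(cuts, j + segment_indices(x[(j + 1):n], params))
  sort(unique(cuts))
}

#' Segment a probe profile into constant-ratio regions
#'
#' Per chromosome, a circular-style recursive binary segmentation: the
#' interior window maximizing the pooled two-sample t-squared statistic
#' against the rest of the region is split out when the statistic exceeds
#' the penalty `penalty_mult * log(n)`, and the three parts are segmented
#' recursively. Adjacent segments whose means differ by less than
#' `merge_mean_tol` are then merged. Deterministic for fixed input and
#' parameters. This is a documented stand-in for the proprietary ADM2
#' detection step; only the probe-count and ratio filters of that step are
#' reproducible.
#'
#' @param profile a `probe_profile` (sorted; enforced at construction).
#' @param params [detection_params()].
#' @return data.frame of segments: chrom, start, end (bp, spanning first to
#'   last contributing probe), n_probes, mean_log2, linear_ratio.
#' @export
segment_profile <- function(profile, params = detection_params()) {
  probes <- profile$probes
  if (is.unsorted(match(probes$chrom, profile$genome$chrom), strictly = FALSE))
    stop("probe profile must be sorted by (chromosome, start)")
  out <- list()
  for (ch in unique(probes$chrom)) {
    p <- probes[probes$chrom == ch, , drop = FALSE]
    if (any(diff(p$start) < 0)) stop("probes unsorted within chromosome ", ch)
    cuts <- segment_indices(p$log2_ratio, params)
    bounds <- cbind(c(1, utils::head(cuts, -1) + 1), cuts)
    segs <- data.frame(
      chrom = ch,
      start = p$start[bounds[, 1]],
      end = p$end[bounds[, 2]],
      n_probes = bounds[, 2] - bounds[, 1] + 1,
      mean_log2 = vapply(seq_len(nrow(bounds)), function(k)
        mean(p$log2_ratio[bounds[k, 1]:bounds[k, 2]]), numeric(1)),
      stringsAsFactors = FALSE)
    # merge-back of near-equal neighbours
    k <- 1
    while (k < nrow(segs)) {
      if (abs(segs$mean_log2[k + 1] - segs$mean_log2[k]) < params$merge_mean_tol) {
        w <- segs$n_probes[k] + segs$n_probes[k + 1]
        segs$mean_log2[k] <- (segs$mean_log2[k] * segs$n_probes[k] +
                              segs$mean_log2[k + 1] * segs$n_probes[k + 1]) / w
        segs$end[k] <- segs$end[k + 1]
        segs$n_probes[k] <- w
        segs <- segs[-(k + 1), , drop = FALSE]
      } else k <- k + 1
    }
    out[[ch]] <- segs
  }
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  segs$linear_ratio <- 2^segs$mean_log2
  segs
}

default_artifact_masks <- function(genome, telomere_mask_kb) {
  w <- telomere_mask_kb * 1000
  if (w <= 0) return(NULL)
  rbind(
    data.frame(chrom = genome$chrom, start = 0, end = w),
    data.frame(chrom = genome$chrom, start = genome$length - w,
               end = genome$length)
  )
}

#' Filter segments down to reportable aberrations
#'
#' Keeps segments with at least `min_probes` probes and |mean log2| above
#' `min_abs_log2`; removes segments overlapping any artifact mask by at
#' least half their length.
#'
#' @param segments output of [segment_profile()].
#' @param params [detection_params()].
#' @param genome [genome_model()] used to build the default telomeric masks.
#' @return the surviving segments.
#' @export
filter_aberrations <- function(segments, params = detection_params(),
                               genome = default_genome()) {
  keep <- segments$n_probes >= params$min_probes &
    abs(segments$mean_log2) > params$min_abs_log2
  segs <- segments[keep, , drop = FALSE]
  masks <- params$artifact_masks
  if (is.null(masks))
    masks <- default_artifact_masks(genome, params$telomere_mask_kb)
  if (!is.null(masks) && nrow(segs) > 0) {
    masked <- vapply(seq_len(nrow(segs)), function(k) {
      m <- masks[masks$chrom == segs$chrom[k], , drop = FALSE]
      if (nrow(m) == 0) return(FALSE)
      ov <- sum(pmax(0, pmin(m$end, segs$end[k]) - pmax(m$start, segs$start[k])))
      ov >= 0.5 * (segs$end[k] - segs$start[k])
    }, logical(1))
    segs <- segs[!masked, , drop = FALSE]
  }
  rownames(segs) <- NULL
  segs
}
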