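# Independent brute-force oracles used to pin expected values.

# Two-sided Fisher exact p by full hypergeometric enumeration: sum of the
# probabilities of all 2x2 tables with the observed margins whose
# probability does not exceed the observed table's.
fisher_enum <- function(a, n1, b, n2) {
  m <- a + b
  k <- max(0, m - n2):min(m, n1)
  pr <- stats::dhyper(k, n1, n2, m)
  p_obs <- stats::dhyper(a, n1, n2, m)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Per-base interval intersection on small integer instances: an interval
# (s, e] covers unit cells s+1 .. e.
cells <- function(s, e) seq(s + 1, e)
brute_intersect <- function(iv) {
  common <- Reduce(intersect, lapply(seq_len(nrow(iv)),
                                     function(k) cells(iv$start[k], iv$end[k])))
  if (length(common) == 0) return(NULL)
  c(start = min(common) - 1, end = max(common))
}

# Per-base patient-depth profile for recurrence steps.
brute_depth <- function(calls, at) {
  vapply(at, function(x)
    length(unique(calls$patient[calls$start < x & calls$end >= x])),
    integer(1))
}

# Exhaustive two-changepoint search: best partition of x into three runs by
# residual sum of squares.
best_two_changepoints <- function(x) {
  n <- length(x)
  best <- NULL; best_rss <- Inf
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) {
    seg <- list(x[1:i], x[(i + 1):j], x[(j + 1):n])
    rss <- sum(vapply(seg, function(s) sum((s - mean(s))^2), numeric(1)))
    if (rss < best_rss) { best_rss <- rss; best <- c(i, j) }
  }
  best
}

# Small profile builder on a uniform 10 kb grid of one chromosome.
toy_genome <- function(len = 50e6, chroms = "1")
  genome_model(chroms, rep(len, length(chroms)))

toy_profile <- function(x, chrom = "1", spacing = 1e4,
                        genome = toy_genome(), sample_id = "s1",
                        role = "combined") {
  pos <- seq_along(x) * spacing
  probe_profile(sample_id,
                data.frame(probe_id = paste0("P", seq_along(x)),
                           chrom = chrom, start = pos, end = pos,
                           log2_ratio = x, stringsAsFactors = FALSE),
                role = role, genome = genome)
}

# Minimal call-table constructor (Mb coordinates for readability).
mk_calls <- function(patient, chrom, start_mb, end_mb, direction,
                     ratio = ifelse(direction == "loss", 0.6, 1.4),
                     state = NULL) {
  df <- data.frame(patient = patient, chrom = as.character(chrom),
                   start = round(start_mb * 1e6), end = round(end_mb * 1e6),
                   direction = direction, ratio = ratio,
                   stringsAsFactors = FALSE)
  df$state <- if (is.null(state))
    ifelse(direction == "loss", "LOSS", "GAIN") else state
  df
}
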