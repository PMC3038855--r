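#' Breakpoint-sweep recurrence profile
#'
#' Decomposes the genome coverage of one direction's CNA calls into maximal
#' steps over which the supporting patient set is constant. A patient
#' counts once per step regardless of how many of their calls cover it, so
#' step depth is the number of distinct affected patients.
#'
#' @param calls cohort CNA data.frame (patient/chrom/start/end/direction,
#'   bp coordinates); IG- and CNV-flagged rows are dropped if flag columns
#'   are present.
#' @param direction `"gain"` or `"loss"` (amplifications count as gains,
#'   deep losses as losses).
#' @return data.frame of steps: chrom, start, end, depth, patients
#'   (comma-separated, sorted).
#' @export
build_recurrence_profile <- function(calls, direction = c("loss", "gain")) {
  direction <- match.arg(direction)
  calls <- drop_flagged(calls)
  calls <- calls[calls$direction == direction, , drop = FALSE]
  out <- list()
  for (ch in unique(calls$chrom)) {
    cc <- calls[calls$chrom == ch, , drop = FALSE]
    bp <- sort(unique(c(cc$start, cc$end)))
    if (length(bp) < 2) next
    s <- utils::head(bp, -1); e <- bp[-1]
    rows <- lapply(seq_along(s), function(k) {
      covering <- cc$start <= s[k] & cc$end >= e[k]
      pats <- sort(unique(cc$patient[covering]))
      if (length(pats) == 0) return(NULL)
      data.frame(chrom = ch, start = s[k], end = e[k],
                 depth = length(pats),
                 patients = paste(pats, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    out[[ch]] <- do.call(rbind, rows)
  }
  steps <- do.call(rbind, out)
  if (is.null(steps))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), depth = integer(0),
                      patients = character(0)))
  # merge adjacent steps with identical patient sets
  merged <- list()
  for (ch in unique(steps$chrom)) {
    st <- steps[steps$chrom == ch, , drop = FALSE]
    st <- st[order(st$start), , drop = FALSE]
    k <- 1
    while (k < nrow(st)) {
      if (st$end[k] == st$start[k + 1] &&
          st$patients[k] == st$patients[k + 1]) {
        st$end[k] <- st$end[k + 1]
        st <- st[-(k + 1), , drop = FALSE]
      } else k <- k + 1
    }
    merged[[ch]] <- st
  }
  steps <- do.call(rbind, merged)
  rownames(steps) <- NULL
  steps
}

drop_flagged <- function(calls) {
  if (!is.null(calls$ig_flag)) calls <- calls[!calls$ig_flag, , drop = FALSE]
  if (!is.null(calls$cnv_flag)) calls <- calls[!calls$cnv_flag, , drop = FALSE]
  calls
}

#' Derive minimal critical region candidates
#'
#' A minimal critical region (MCR) is the smallest genomic interval shared
#' by the same-direction CNAs of at least `min_support` patients at a
#' recurrent locus. The reconstruction used here seeds a candidate with
#' each call and shrinks it by intersection: same-direction calls from
#' other patients that overlap the current interval are processed in
#' ascending (size, patient id) order; a call is admitted - and the
#' candidate intersected with it - only if it covers at least
#' `min_member_overlap` of the current interval, otherwise it is dropped
#' (an incidental sliver of overlap must not truncate a recurrent region).
#' Candidates reaching `min_support` distinct patients are kept,
#' deduplicated, and pruned: a candidate strictly containing another
#' candidate whose support is a superset (or equal) is discarded. When two
#' candidates have identical intervals the larger support wins, ties broken
#' on the lexicographic patient set. Support is counted at patient level.
#'
#' @param calls cohort CNA data.frame (bp coordinates; IG/CNV rows dropped
#'   via their flag columns when present).
#' @param direction `"gain"` or `"loss"`; gains pool GAIN/LOW_AMP/HIGH_AMP.
#' @param min_support minimum number of distinct patients (default 2).
#' @param min_member_overlap minimum fraction of the current interval a
#'   member call must cover to be admitted (default 0.5).
#' @return data.frame of MCR candidates sorted by (chromosome, start):
#'   chrom, start, end, direction, size_mb, n_support, patients, amplified.
#' @export
derive_mcr_candidates <- function(calls, direction = c("loss", "gain"),
                                  min_support = 2, min_member_overlap = 0.5) {
  direction <- match.arg(direction)
  calls <- drop_flagged(calls)
  calls <- calls[calls$direction == direction, , drop = FALSE]
  if (nrow(calls) == 0)
    return(empty_mcr_frame())
  amp_states <- c("LOW_AMP", "HIGH_AMP")
  has_state <- !is.null(calls$state)
  cand <- list()
  for (seed in seq_len(nrow(calls))) {
    cur_s <- calls$start[seed]; cur_e <- calls$end[seed]
    ch <- calls$chrom[seed]
    members <- seed
    pats <- calls$patient[seed]
    pool <- which(calls$chrom == ch & calls$patient != calls$patient[seed] &
                  calls$start < cur_e & calls$end > cur_s)
    ord <- order(calls$end[pool] - calls$start[pool], calls$patient[pool],
                 calls$start[pool])
    for (m in pool[ord]) {
      ov <- min(cur_e, calls$end[m]) - max(cur_s, calls$start[m])
      if (ov <= 0) next                             # ceased to overlap: drop
      if (ov < min_member_overlap * (cur_e - cur_s)) next  # sliver: drop
      cur_s <- max(cur_s, calls$start[m])
      cur_e <- min(cur_e, calls$end[m])
      members <- c(members, m)
      pats <- c(pats, calls$patient[m])
    }
    pats <- sort(unique(pats))
    if (length(pats) < min_support) next
    amp <- has_state && any(calls$state[members] %in% amp_states)
    cand[[length(cand) + 1]] <- list(chrom = ch, start = cur_s, end = cur_e,
                                     patients = pats, amplified = amp)
  }
  if (length(cand) == 0) return(empty_mcr_frame())
  # deduplicate identical intervals: larger support wins, then lexicographic
  key <- vapply(cand, function(c) paste(c$chrom, c$start, c$end), character(1))
  keep <- integer(0)
  for (k in unique(key)) {
    idx <- which(key == k)
    ns <- vapply(cand[idx], function(c) length(c$patients), integer(1))
    idx <- idx[ns == max(ns)]
    if (length(idx) > 1) {
      sets <- vapply(cand[idx], function(c) paste(c$patients, collapse = ","),
                     character(1))
      idx <- idx[order(sets)][1]
    }
    keep <- c(keep, idx[1])
  }
  cand <- cand[keep]
  # containment pruning
  n <- length(cand)
  pruned <- logical(n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b || pruned[a]) next
      A <- cand[[a]]; B <- cand[[b]]
      if (A$chrom != B$chrom) next
      strictly_contains <- A$start <= B$start && A$end >= B$end &&
        (A$end - A$start) > (B$end - B$start)
      if (strictly_contains && all(A$patients %in% B$patients))
        pruned[a] <- TRUE
    }
  }
  cand <- cand[!pruned]
  out <- data.frame(
    chrom = vapply(cand, `[[`, character(1), "chrom"),
    start = vapply(cand, `[[`, numeric(1), "start"),
    end = vapply(cand, `[[`, numeric(1), "end"),
    direction = direction,
    n_support = vapply(cand, function(c) length(c$patients), integer(1)),
    patients = vapply(cand, function(c) paste(c$patients, collapse = ","),
                      character(1)),
    amplified = vapply(cand, `[[`, logical(1), "amplified"),
    stringsAsFactors = FALSE)
  out$size_mb <- size_mb(out)
  g <- default_genome()
  out <- out[order(match(out$chrom, g$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("chrom", "start", "end", "direction", "size_mb", "n_support",
          "patients", "amplified")]
}

empty_mcr_frame <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             direction = character(0), size_mb = numeric(0),
             n_support = integer(0), patients = character(0),
             amplified = logical(0), stringsAsFactors = FALSE)
}

#' Match derived candidates against a published MCR catalog
#'
#' A catalog entry matches a candidate with the same direction and
#' identical bounds at the tables' 10 kb reporting resolution. The
#' candidate set may be a strict superset of the catalog (published
#' catalogs are curated); unmatched candidates are not penalized.
#'
#' @param candidates data.frame from [derive_mcr_candidates()] (both
#'   directions may be concatenated).
#' @param catalog data.frame with chrom/start/end/direction (bp).
#' @return the catalog with `matched` (candidate row index or NA) and
#'   `candidate_size_mb` columns.
#' @export
match_catalog <- function(candidates, catalog) {
  tol <- 5e3  # half of one 10 kb reporting unit
  catalog$matched <- NA_integer_
  catalog$candidate_size_mb <- NA_real_
  if (nrow(candidates) > 0) {
    for (k in seq_len(nrow(catalog))) {
      hit <- which(candidates$chrom == catalog$chrom[k] &
                   candidates$direction == catalog$direction[k] &
                   abs(candidates$start - catalog$start[k]) < tol &
                   abs(candidates$end - catalog$end[k]) < tol)
      if (length(hit) > 0) {
        catalog$matched[k] <- hit[1]
        catalog$candidate_size_mb[k] <- candidates$size_mb[hit[1]]
      }
    }
  }
  catalog
}

#' Merge MCR catalogs across studies into a consensus table
#'
#' Same-direction entries from different studies are clustered by
#' single-linkage on interval overlap; each cluster's consensus location is
#' the intersection of its members when non-empty, otherwise the member
#' span flagged `spanned`. Patient counts are accumulated per group and
#' expressed as percentages of the supplied group totals (one decimal).
#'
#' @param studies named list; each element a data.frame of MCR entries with
#'   chrom/start/end/direction and a `counts` list-column or per-group count
#'   columns named `n_<group>`.
#' @param group_totals named integer vector, total patients per group.
#' @return consensus data.frame with per-group counts and percentages.
#' @export
merge_mcr_catalogs <- function(studies, group_totals) {
  if (any(group_totals <= 0)) stop("group totals must be positive")
  groups <- names(group_totals)
  entries <- do.call(rbind, lapply(names(studies), function(sid) {
    x <- studies[[sid]]
    x$study <- sid
    x
  }))
  for (g in groups) {
    col <- paste0("n_", g)
    if (is.null(entries[[col]])) entries[[col]] <- 0L
  }
  out <- list()
  for (dir in unique(entries$direction)) {
    for (ch in unique(entries$chrom[entries$direction == dir])) {
      e <- entries[entries$direction == dir & entries$chrom == ch, ,
                   drop = FALSE]
      e <- e[order(e$start), , drop = FALSE]
      # single-linkage clustering on overlap
      cluster <- integer(nrow(e)); cluster[1] <- 1L; cur_end <- e$end[1]
      for (k in seq_len(nrow(e))[-1]) {
        if (e$start[k] < cur_end) {
          cluster[k] <- cluster[k - 1]
          cur_end <- max(cur_end, e$end[k])
        } else {
          cluster[k] <- cluster[k - 1] + 1L
          cur_end <- e$end[k]
        }
      }
      for (cl in unique(cluster)) {
        m <- e[cluster == cl, , drop = FALSE]
        s <- max(m$start); en <- min(m$end)
        spanned <- s >= en
        if (spanned) { s <- min(m$start); en <- max(m$end) }
        row <- data.frame(chrom = ch, start = s, end = en, direction = dir,
                          spanned = spanned,
                          n_studies = length(unique(m$study)),
                          stringsAsFactors = FALSE)
        for (g in groups) {
          cnt <- sum(m[[paste0("n_", g)]])
          row[[paste0("n_", g)]] <- cnt
          row[[paste0("pct_", g)]] <-
            round_half_up(100 * cnt / group_totals[[g]], 1)
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  g <- default_genome()
  res <- res[order(match(res$chrom, g$chrom), res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
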