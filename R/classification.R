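#' Linear-ratio classification thresholds
#'
#' Copy-state boundaries on the tumor/reference linear ratio: gains and
#' losses at 1.2 / 0.8 (inclusive on the aberrant side), low- and high-level
#' amplification at 2 and 4, deep loss below 0.25. The attenuation of these
#' ratios toward 1 reflects normal-cell contamination (clonal fraction).
#'
#' @param gain_min,loss_max,low_amp_min,high_amp_min,deep_loss_max numeric
#'   boundaries; defaults 1.2, 0.8, 2, 4, 0.25.
#' @return named list of thresholds.
#' @export
classification_thresholds <- function(gain_min = 1.2, loss_max = 0.8,
                                      low_amp_min = 2, high_amp_min = 4,
                                      deep_loss_max = 0.25) {
  t <- list(gain_min = gain_min, loss_max = loss_max,
            low_amp_min = low_amp_min, high_amp_min = high_amp_min,
            deep_loss_max = deep_loss_max)
  stopifnot(t$deep_loss_max < t$loss_max, t$loss_max < 1, 1 < t$gain_min,
            t$gain_min < t$low_amp_min, t$low_amp_min < t$high_amp_min)
  t
}

CNA_STATES <- c("HIGH_AMP", "LOW_AMP", "GAIN", "NEUTRAL", "LOSS", "DEEP_LOSS")

#' Classify a linear ratio into a copy state
#'
#' Total monotone step function: HIGH_AMP >= 4, LOW_AMP in \[2,4),
#' GAIN in \[1.2,2), NEUTRAL in (0.8,1.2), LOSS in \[0.25,0.8],
#' DEEP_LOSS < 0.25.
#'
#' @param ratio positive linear ratio(s).
#' @param thresholds [classification_thresholds()].
#' @return character vector of states.
#' @export
classify_ratio <- function(ratio, thresholds = classification_thresholds()) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("linear ratio must be positive and finite")
  t <- thresholds
  out <- character(length(ratio))
  out[ratio >= t$high_amp_min] <- "HIGH_AMP"
  out[ratio >= t$low_amp_min & ratio < t$high_amp_min] <- "LOW_AMP"
  out[ratio >= t$gain_min & ratio < t$low_amp_min] <- "GAIN"
  out[ratio > t$loss_max & ratio < t$gain_min] <- "NEUTRAL"
  out[ratio <= t$loss_max & ratio >= t$deep_loss_max] <- "LOSS"
  out[ratio < t$deep_loss_max] <- "DEEP_LOSS"
  out
}

# Direction-aware state for table rows whose sign is authoritative: the
# published tables keep a reviewed call's sign even when the printed ratio
# rounds into the neutral band.
state_from_direction <- function(ratio, direction,
                                 thresholds = classification_thresholds()) {
  t <- thresholds
  ifelse(direction == "gain",
         ifelse(ratio >= t$high_amp_min, "HIGH_AMP",
                ifelse(ratio >= t$low_amp_min, "LOW_AMP", "GAIN")),
         ifelse(ratio < t$deep_loss_max, "DEEP_LOSS", "LOSS"))
}

#' CNV / IG filter parameters
#'
#' Criteria used to separate germline copy number variants and
#' immunoglobulin/T-cell-receptor VDJ deletions from acquired CNAs when no
#' matched normal DNA is available: (i) size below `max_cnv_size`;
#' (ii) identical breakpoints repeated across patients (within
#' `breakpoint_identity_tol`, one 10 kb reporting unit); (iii) overlap with
#' known CNV gene loci; (iv) reciprocal overlap with a CNV database region.
#' Database overlap alone is sufficient; criteria i-iii must co-occur.
#'
#' @param max_cnv_size Mb, default 2.
#' @param breakpoint_identity_tol Mb, default 0.01.
#' @param min_reciprocal_db_overlap fraction, default 0.5.
#' @param cnv_gene_loci data.frame of known CNV gene regions
#'   (chrom/start/end in bp); default: packaged database stand-in.
#' @param ig_loci data.frame of IG/TR cluster loci (name/chrom/start/end bp);
#'   default: packaged IGK, IGH, IGL, TRG, TRA/TRD extents.
#' @return named list of parameters.
#' @export
cnv_filter_params <- function(max_cnv_size = 2,
                              breakpoint_identity_tol = 0.01,
                              min_reciprocal_db_overlap = 0.5,
                              cnv_gene_loci = NULL,
                              ig_loci = NULL) {
  stopifnot(max_cnv_size > 0, breakpoint_identity_tol >= 0,
            min_reciprocal_db_overlap > 0, min_reciprocal_db_overlap <= 1)
  if (is.null(cnv_gene_loci)) cnv_gene_loci <- load_fixture("cnv_regions")
  if (is.null(ig_loci)) ig_loci <- load_fixture("ig_loci")
  list(max_cnv_size = max_cnv_size,
       breakpoint_identity_tol = breakpoint_identity_tol,
       min_reciprocal_db_overlap = min_reciprocal_db_overlap,
       cnv_gene_loci = cnv_gene_loci, ig_loci = ig_loci)
}

#' Flag probable germline CNVs in a cohort CNA table
#'
#' A call is flagged CNV when it has reciprocal overlap of at least
#' `min_reciprocal_db_overlap` with a database region of compatible
#' direction (criterion iv, individually sufficient), or when it is smaller
#' than `max_cnv_size`, another patient carries a same-direction call with
#' both breakpoints identical within `breakpoint_identity_tol`, and it
#' overlaps a configured CNV gene locus (criteria i+ii+iii together).
#' Reason codes record which criteria fired. The decision for one call does
#' not depend on cohort ordering.
#'
#' @param calls cohort CNA data.frame (patient/direction/chrom/start/end bp).
#' @param cnv_db CNV database regions (chrom/start/end bp, optional
#'   `direction` column with values gain/loss/both).
#' @param params [cnv_filter_params()].
#' @return `calls` with logical `cnv_flag` and character `cnv_reason` columns.
#' @export
flag_cnv <- function(calls, cnv_db = NULL, params = cnv_filter_params()) {
  if (is.null(cnv_db)) cnv_db <- params$cnv_gene_loci
  n <- nrow(calls)
  calls$cnv_flag <- logical(n)
  calls$cnv_reason <- character(n)
  if (n == 0) return(calls)
  tol_bp <- params$breakpoint_identity_tol * BP_PER_MB
  for (k in seq_len(n)) {
    ck <- calls[k, ]
    reasons <- character(0)
    # iv: reciprocal database overlap
    if (nrow(cnv_db) > 0) {
      db <- cnv_db[cnv_db$chrom == ck$chrom, , drop = FALSE]
      if (!is.null(db$direction))
        db <- db[db$direction %in% c("both", ck$direction), , drop = FALSE]
      if (nrow(db) > 0) {
        ov <- pmax(0, pmin(db$end, ck$end) - pmax(db$start, ck$start))
        rec <- pmin(ov / (ck$end - ck$start), ov / (db$end - db$start))
        if (any(rec >= params$min_reciprocal_db_overlap)) reasons <- c(reasons, "iv")
      }
    }
    # i: size
    small <- (ck$end - ck$start) / BP_PER_MB < params$max_cnv_size
    if (small) reasons <- c(reasons, "i")
    # ii: identical breakpoints in another patient, same direction
    others <- calls[calls$patient != ck$patient &
                    calls$direction == ck$direction &
                    calls$chrom == ck$chrom, , drop = FALSE]
    ident <- nrow(others) > 0 &&
      any(abs(others$start - ck$start) <= tol_bp &
          abs(others$end - ck$end) <= tol_bp)
    if (ident) reasons <- c(reasons, "ii")
    # iii: known CNV gene locus overlap
    loci <- params$cnv_gene_loci
    loci <- loci[loci$chrom == ck$chrom, , drop = FALSE]
    in_locus <- nrow(loci) > 0 &&
      any(pmin(loci$end, ck$end) - pmax(loci$start, ck$start) > 0)
    if (in_locus) reasons <- c(reasons, "iii")
    calls$cnv_flag[k] <- ("iv" %in% reasons) || (small && ident && in_locus)
    calls$cnv_reason[k] <- if (calls$cnv_flag[k]) paste(reasons, collapse = "+") else ""
  }
  calls
}

#' Flag immunoglobulin / T-cell-receptor VDJ deletions
#'
#' Focal clonal losses lying inside an IG or TR cluster are physiological
#' VDJ-recombination deletions marking the malignant clone, not candidate
#' drivers: a call is flagged when it is a loss contained within a
#' configured locus. Gains over the loci are never flagged. IG-flagged
#' calls are excluded from CNA counting, karyotype synthesis and MCR
#' derivation but retained for the IG-proportion statistic.
#'
#' @param calls cohort CNA data.frame.
#' @param params [cnv_filter_params()].
#' @return `calls` with logical `ig_flag` and character `ig_locus` columns.
#' @export
flag_ig <- function(calls, params = cnv_filter_params()) {
  loci <- params$ig_loci
  n <- nrow(calls)
  calls$ig_flag <- logical(n)
  calls$ig_locus <- character(n)
  for (k in seq_len(n)) {
    if (calls$direction[k] != "loss") next
    hit <- loci$chrom == calls$chrom[k] &
      calls$start[k] >= loci$start & calls$end[k] <= loci$end
    if (any(hit)) {
      calls$ig_flag[k] <- TRUE
      calls$ig_locus[k] <- loci$name[which(hit)[1]]
    }
  }
  calls
}
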