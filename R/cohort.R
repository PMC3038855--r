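#' Summarize a cohort group's CNA burden
#'
#' Counts acquired CNAs (rows flagged CNV or IG are excluded; IG-flagged
#' losses still mark their patient as IG-rearranged), split by direction,
#' with the mean number of CNAs per case over all patients of the group and
#' the number of patients without any CNA.
#'
#' @param calls cohort CNA data.frame for one group (may include `ig_flag`
#'   / `cnv_flag` columns).
#' @param patients character vector of all patient ids in the group
#'   (patients without calls included), or a data.frame with a `patient`
#'   column.
#' @return one-row data.frame: n_patients, n_cna_total, n_gains, n_losses,
#'   mean_cna_per_case (2 decimals), n_patients_no_cna, n_patients_ig.
#' @export
summarize_group <- function(calls, patients) {
  if (is.data.frame(patients)) patients <- patients$patient
  patients <- unique(patients)
  n_pat <- length(patients)
  ig_col <- if (!is.null(calls$ig_flag)) calls$ig_flag else
    rep(FALSE, nrow(calls))
  n_ig_pat <- length(unique(calls$patient[ig_col]))
  cna <- drop_flagged(calls)
  if (n_pat == 0)
    return(data.frame(n_patients = 0L, n_cna_total = 0L, n_gains = 0L,
                      n_losses = 0L, mean_cna_per_case = NA_real_,
                      n_patients_no_cna = 0L, n_patients_ig = 0L))
  n_gain <- sum(cna$direction == "gain")
  n_loss <- sum(cna$direction == "loss")
  data.frame(
    n_patients = n_pat,
    n_cna_total = n_gain + n_loss,
    n_gains = n_gain,
    n_losses = n_loss,
    mean_cna_per_case = round_half_up((n_gain + n_loss) / n_pat, 2),
    n_patients_no_cna = sum(!(patients %in% cna$patient)),
    n_patients_ig = n_ig_pat)
}

#' Two-sample proportion comparison
#'
#' Two-sided Fisher exact test (the sum over all 2x2 tables with the
#' observed margins whose probability does not exceed the observed table's)
#' or the Pearson chi-squared statistic on 1 df without continuity
#' correction.
#'
#' @param a successes in group 1, out of `n1`.
#' @param b successes in group 2, out of `n2`.
#' @param n1,n2 group sizes.
#' @param method `"fisher"` (default; exact, suited to small counts) or
#'   `"chi2"`.
#' @return the two-sided p-value.
#' @export
compare_proportions <- function(a, n1, b, n2, method = c("fisher", "chi2")) {
  method <- match.arg(method)
  if (any(c(a, b, n1, n2) < 0) || a > n1 || b > n2)
    stop("invalid counts: need 0 <= a <= n1 and 0 <= b <= n2")
  tab <- matrix(c(a, n1 - a, b, n2 - b), nrow = 2)
  if (method == "fisher") {
    stats::fisher.test(tab)$p.value
  } else {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  }
}
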