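#' Cytoband lookup
#'
#' Returns the band containing a position. The packaged band map is
#' synthetic (stylized arm tiling, chromosome 21 detailed); any UCSC
#' cytoBand.txt can be supplied instead via [read_cytoband()].
#'
#' @param chrom chromosome name.
#' @param pos position in bp.
#' @param bands cytoband data.frame (chrom/start/end/band).
#' @return band name, e.g. `"q22.12"`.
#' @export
band_of <- function(chrom, pos, bands = load_fixture("cytobands")) {
  b <- bands[bands$chrom == chrom, , drop = FALSE]
  if (nrow(b) == 0) stop("no bands for chromosome ", chrom)
  hit <- which(pos > b$start & pos <= b$end)
  if (pos == 0) hit <- 1L
  if (length(hit) == 0)
    stop("position ", pos, " outside chromosome ", chrom)
  b$band[hit[1]]
}

# "q14.3q35" -> c("q14.3","q35"); "pterp22.3" -> c("pter","p22.3"); "q44" ->
# c("q44","q44"). Band spans as printed in the tables.
split_band_span <- function(bands) {
  m <- gregexpr("(p|q)(ter|[0-9]+(\\.[0-9]+)?)", bands)[[1]]
  if (m[1] == -1) return(c("", ""))
  parts <- regmatches(bands, gregexpr("(p|q)(ter|[0-9]+(\\.[0-9]+)?)", bands))[[1]]
  c(parts[1], parts[length(parts)])
}

MINUS <- "−"  # the tables' minus sign
ENDASH <- "–" # the tables' range dash

#' Render a CNA call in the tables' interval notation
#'
#' `sign chrom bands <start-end> [ratio]`, e.g.
#' `-7q33q34<135.74-137.48>[0.16]` (minus sign and en dash as printed;
#' coordinates in Mb at two decimals). The call's stored band span is used
#' when present, otherwise bands are looked up from the band map; the end
#' band is omitted when it equals the start band.
#'
#' @param call one-row CNA data.frame (chrom/start/end/direction/ratio,
#'   optional bands).
#' @param bands cytoband map for the fallback lookup.
#' @param with_ratio include the `[ratio]` suffix (default TRUE when a
#'   ratio is present).
#' @return character token.
#' @export
format_cna <- function(call, bands = NULL,
                       with_ratio = !is.null(call$ratio) && !is.na(call$ratio)) {
  if (!is.null(call$state) && call$state == "NEUTRAL")
    stop("cannot format a neutral call")
  sign <- if (call$direction == "gain") "+" else MINUS
  span <- if (!is.null(call$bands) && nzchar(call$bands)) {
    call$bands
  } else {
    if (is.null(bands)) bands <- load_fixture("cytobands")
    b <- split_band_span_from_pos(call$chrom, call$start, call$end, bands)
    if (b[1] == b[2]) b[1] else paste0(b[1], b[2])
  }
  tok <- paste0(sign, call$chrom, span, "<",
                sprintf("%.2f", call$start / BP_PER_MB), ENDASH,
                sprintf("%.2f", call$end / BP_PER_MB), ">")
  if (with_ratio) tok <- paste0(tok, "[", sprintf("%.2f", call$ratio), "]")
  tok
}

split_band_span_from_pos <- function(chrom, start, end, bands) {
  c(band_of(chrom, start + 1, bands), band_of(chrom, end, bands))
}

#' Parse the tables' CNA interval notation
#'
#' Accepts the printed dialect leniently: ASCII or typographic minus,
#' hyphen or en dash, decimal commas, optional spaces, optional `[ratio]`.
#'
#' @param token character token, e.g. `"+7p15.2 <27,15-27,18>"`.
#' @return one-row data.frame: direction, chrom, bands, start, end (bp),
#'   ratio (NA when absent).
#' @export
parse_cna_notation <- function(token) {
  tok <- gsub("−", "-", token)
  tok <- gsub("–|—", "-", tok)
  tok <- gsub(" ", "", tok)
  pat <- paste0("^([+-])",                     # direction
                "([0-9]{1,2}|X|Y)",            # chromosome
                "([pq][ter0-9.]*[0-9a-z.]*)?", # band span (optional)
                "<([0-9]+[.,]?[0-9]*)-([0-9]+[.,]?[0-9]*)>",
                "(\\[([0-9]+[.,]?[0-9]*)\\])?\\*?\\.?$")
  m <- regexec(pat, tok)[[1]]
  if (m[1] == -1) stop("cannot parse CNA token: '", token, "'")
  g <- regmatches(tok, regexec(pat, tok))[[1]]
  num <- function(s) as.numeric(gsub(",", ".", s))
  data.frame(direction = if (g[2] == "+") "gain" else "loss",
             chrom = g[3],
             bands = g[4],
             start = round(num(g[5]) * BP_PER_MB),
             end = round(num(g[6]) * BP_PER_MB),
             ratio = if (nzchar(g[8])) num(g[8]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Fuse contiguous same-direction calls of one patient
#'
#' Adjacent calls in the same direction whose gap is at most `gap_tol` and
#' whose mean log2 ratios differ by at most `ratio_tol` are merged (the
#' tables fuse contiguous CNAs "whose ratios were not too different" for
#' karyotype readability, but keep e.g. a deep-loss segment distinct from
#' its flanking heterozygous loss). The merged ratio is the
#' probe-count-weighted geometric-style mean (weighted mean of log2 ratios)
#' when probe counts are known, else length-weighted.
#'
#' @param calls one patient's CNA data.frame (bp coordinates, `ratio`
#'   column; optional `n_probes`).
#' @param gap_tol maximum gap, Mb (default 2).
#' @param ratio_tol maximum |difference of log2 ratios| (default 0.2).
#' @return fused calls data.frame.
#' @export
fuse_contiguous <- function(calls, gap_tol = 2, ratio_tol = 0.2) {
  if (nrow(calls) <= 1) return(calls)
  if (length(unique(calls$patient)) > 1)
    stop("fuse_contiguous() operates on a single patient")
  g <- default_genome()
  calls <- calls[order(match(calls$chrom, g$chrom), calls$start), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  k <- 1
  while (k < nrow(calls)) {
    a <- calls[k, ]; b <- calls[k + 1, ]
    fuse <- a$chrom == b$chrom && a$direction == b$direction &&
      (b$start - a$end) / BP_PER_MB <= gap_tol &&
      abs(log2(a$ratio) - log2(b$ratio)) <= ratio_tol
    if (fuse) {
      w <- if (!is.null(calls$n_probes) && !anyNA(c(a$n_probes, b$n_probes)))
        c(a$n_probes, b$n_probes) else c(a$end - a$start, b$end - b$start)
      calls$ratio[k] <- 2^stats::weighted.mean(log2(c(a$ratio, b$ratio)), w)
      calls$end[k] <- b$end
      if (!is.null(calls$n_probes)) calls$n_probes[k] <- sum(w)
      if (!is.null(calls$bands) && nzchar(a$bands) && nzchar(b$bands)) {
        sa <- split_band_span(a$bands); sb <- split_band_span(b$bands)
        calls$bands[k] <- if (sa[1] == sb[2]) sa[1] else paste0(sa[1], sb[2])
      }
      calls <- calls[-(k + 1), , drop = FALSE]
    } else k <- k + 1
  }
  rownames(calls) <- NULL
  calls
}

#' Synthesize a revised ISCN-like karyotype string
#'
#' Comma-joined band-span tokens (`-21q22.1`, `+7p15.2`) for the patient's
#' fused, non-IG, non-CNV calls, ordered by (chromosome, start), appended
#' to the constitutional prefix (chromosome count and sex chromosomes,
#' e.g. `"46,XX"`). Structural events from the input karyotype are not
#' reconstructed; IG-flagged VDJ deletions are omitted as acquired clonal
#' CNVs.
#'
#' @param calls the patient's CNA data.frame (possibly empty).
#' @param prefix constitutional prefix string.
#' @param bands cytoband map for calls without a stored band span.
#' @param gap_tol,ratio_tol passed to [fuse_contiguous()].
#' @return the karyotype string.
#' @export
synthesize_karyotype <- function(calls, prefix, bands = NULL,
                                 gap_tol = 2, ratio_tol = 0.2) {
  calls <- drop_flagged(calls)
  if (nrow(calls) == 0) return(prefix)
  calls <- fuse_contiguous(calls, gap_tol = gap_tol, ratio_tol = ratio_tol)
  g <- default_genome()
  calls <- calls[order(match(calls$chrom, g$chrom), calls$start), ,
                 drop = FALSE]
  toks <- vapply(seq_len(nrow(calls)), function(k) {
    call <- calls[k, ]
    sign <- if (call$direction == "gain") "+" else MINUS
    span <- if (!is.null(call$bands) && nzchar(call$bands)) call$bands else {
      if (is.null(bands)) bands <<- load_fixture("cytobands")
      b <- split_band_span_from_pos(call$chrom, call$start, call$end, bands)
      if (b[1] == b[2]) b[1] else paste0(b[1], b[2])
    }
    paste0(sign, call$chrom, span)
  }, character(1))
  paste(c(prefix, toks), collapse = ",")
}
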