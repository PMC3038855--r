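#' Genome model
#'
#' An ordered set of chromosome names with their lengths in base pairs.
#' The default model packages the hg18 chromosome lengths used by the
#' cohort tables; any two-column chrom.sizes file can replace it.
#'
#' @param chrom character vector of chromosome names (unique, ordered).
#' @param length numeric vector of chromosome lengths in base pairs (> 0).
#' @return A `genome_model` object (data.frame with columns `chrom`, `length`).
#' @export
genome_model <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  g <- data.frame(chrom = chrom, length = as.numeric(length),
                  stringsAsFactors = FALSE)
  class(g) <- c("genome_model", "data.frame")
  g
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome, length in bp. A leading `chr`
#' prefix is stripped so names match the tables' bare style (`7`, `X`).
#'
#' @param path file path.
#' @return A [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "length"))
  genome_model(sub("^chr", "", x$chrom), x$length)
}

#' Default genome model (hg18 chromosome lengths)
#' @return A [genome_model()].
#' @export
default_genome <- function() {
  read_chrom_sizes(system.file("extdata", "hg18.chrom.sizes",
                               package = "cnamcr", mustWork = TRUE))
}

#' Round half-up
#'
#' Decimal rounding with ties away from zero, matching the tables'
#' presentation (base R rounds to even).
#'
#' @param x numeric.
#' @param digits decimal digits.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

BP_PER_MB <- 1e6

#' Construct genomic intervals
#'
#' Intervals are stored in base pairs; `start < end` is required and, when a
#' genome model is supplied, the interval must lie on a known chromosome and
#' within its length. Megabase input (the tables' unit, 10 kb resolution) is
#' converted on construction.
#'
#' @param chrom chromosome name(s).
#' @param start,end interval bounds.
#' @param units `"bp"` (default) or `"Mb"`.
#' @param genome optional [genome_model()] for bounds checking.
#' @return data.frame with columns `chrom`, `start`, `end` (bp).
#' @export
genomic_interval <- function(chrom, start, end, units = c("bp", "Mb"),
                             genome = NULL) {
  units <- match.arg(units)
  if (units == "Mb") {
    start <- round(start * BP_PER_MB)
    end <- round(end * BP_PER_MB)
  }
  iv <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  validate_intervals(iv, genome)
  iv
}

validate_intervals <- function(iv, genome = NULL) {
  if (any(!is.finite(iv$start)) || any(!is.finite(iv$end)))
    stop("interval bounds must be finite")
  bad <- iv$start >= iv$end
  if (any(bad))
    stop("invalid interval (start must be < end): ",
         paste0(iv$chrom[bad], ":", iv$start[bad], "-", iv$end[bad],
                collapse = ", "))
  if (!is.null(genome)) {
    m <- match(iv$chrom, genome$chrom)
    if (anyNA(m)) stop("unknown chromosome: ",
                       paste(unique(iv$chrom[is.na(m)]), collapse = ", "))
    out <- iv$start < 0 | iv$end > genome$length[m]
    if (any(out)) stop("interval outside chromosome bounds: ",
                       paste0(iv$chrom[out], ":", iv$start[out], "-",
                              iv$end[out], collapse = ", "))
  }
  invisible(iv)
}

#' Overlap length of two intervals, in Mb
#'
#' Zero when the intervals are on different chromosomes, disjoint, or merely
#' touching (an overlap is at least one shared base).
#'
#' @param a,b single intervals (one-row data.frames from [genomic_interval()]).
#' @return numeric, Mb.
#' @export
overlap_length <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (a$chrom[1] != b$chrom[1]) return(0)
  max(0, min(a$end[1], b$end[1]) - max(a$start[1], b$start[1])) / BP_PER_MB
}

#' Intersection of a set of intervals on one chromosome
#'
#' The common span `[max(starts), min(ends)]`, or `NULL` when the
#' intersection is empty. This is the elementary operation behind minimal
#' critical region derivation.
#'
#' @param intervals data.frame of intervals, all on one chromosome.
#' @return one-row interval data.frame, or `NULL` if empty.
#' @export
intersect_all <- function(intervals) {
  if (is.null(intervals) || nrow(intervals) == 0)
    stop("intersect_all() needs at least one interval")
  validate_intervals(intervals)
  if (length(unique(intervals$chrom)) != 1)
    stop("all intervals must be on one chromosome")
  s <- max(intervals$start); e <- min(intervals$end)
  if (s >= e) return(NULL)
  data.frame(chrom = intervals$chrom[1], start = s, end = e,
             stringsAsFactors = FALSE)
}

#' Interval size in Mb, reported at 10 kb resolution
#'
#' @param iv interval data.frame (may have several rows).
#' @return numeric vector, Mb rounded half-up to 2 decimals.
#' @export
size_mb <- function(iv) {
  validate_intervals(iv)
  round_half_up((iv$end - iv$start) / BP_PER_MB, 2)
}

#' Convert intervals to BED (0-based half-open)
#'
#' Internal bounds are the printed boundary positions in bp, so they map
#' directly onto BED's half-open convention.
#'
#' @param iv interval data.frame.
#' @param name optional name column.
#' @return data.frame with chrom/start/end(/name), `chr`-prefixed.
#' @export
interval_to_bed <- function(iv, name = NULL) {
  bed <- data.frame(chrom = paste0("chr", iv$chrom),
                    start = as.integer(round(iv$start)),
                    end = as.integer(round(iv$end)),
                    stringsAsFactors = FALSE)
  if (!is.null(name)) bed$name <- name
  bed
}
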