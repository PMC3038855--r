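#' Read a probe-level log2-ratio table
#'
#' Tab-delimited with header `ProbeID, Chrom, Start, End, Log2Ratio`.
#' Probes are validated (finite ratio, known chromosome, no duplicated
#' positions) and sorted by (chromosome, start); errors cite the offending
#' line of the file.
#'
#' @param path file path.
#' @param sample_id sample identifier; default: file name without extension.
#' @param role dye-swap role: `"forward"`, `"reverse"` or `"combined"`.
#' @param genome [genome_model()] used to order and bound chromosomes.
#' @return a `probe_profile` object.
#' @export
read_probe_table <- function(path, sample_id = NULL,
                             role = c("combined", "forward", "reverse"),
                             genome = default_genome()) {
  role <- match.arg(role)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, colClasses = "character")
  need <- c("ProbeID", "Chrom", "Start", "End", "Log2Ratio")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("probe table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  line <- seq_len(nrow(x)) + 1L  # header is line 1
  ratio <- suppressWarnings(as.numeric(x$Log2Ratio))
  if (anyNA(ratio))
    stop("non-numeric Log2Ratio at line ",
         paste(line[is.na(ratio)], collapse = ", "), " of ", path)
  start <- suppressWarnings(as.numeric(x$Start))
  end <- suppressWarnings(as.numeric(x$End))
  if (anyNA(start) || anyNA(end))
    stop("non-numeric coordinates at line ",
         paste(line[is.na(start) | is.na(end)], collapse = ", "), " of ", path)
  chrom <- sub("^chr", "", x$Chrom)
  unknown <- !(chrom %in% genome$chrom)
  if (any(unknown))
    stop("unknown chromosome '", chrom[which(unknown)[1]], "' at line ",
         line[which(unknown)[1]], " of ", path)
  probes <- data.frame(probe_id = x$ProbeID, chrom = chrom, start = start,
                       end = end, log2_ratio = ratio, stringsAsFactors = FALSE)
  dup <- duplicated(probes[, c("chrom", "start")])
  if (any(dup))
    stop("duplicated probe position for probe '",
         probes$probe_id[which(dup)[1]], "' (line ", line[which(dup)[1]],
         ") of ", path)
  probe_profile(sample_id, probes, role = role, genome = genome)
}

#' Construct a probe profile
#'
#' @param sample_id sample identifier.
#' @param probes data.frame with columns probe_id, chrom, start, end,
#'   log2_ratio (bp coordinates).
#' @param role dye-swap role.
#' @param genome [genome_model()] giving the chromosome order.
#' @return a `probe_profile` object (list with `sample_id`, `probes`, `role`).
#' @export
probe_profile <- function(sample_id, probes,
                          role = c("combined", "forward", "reverse"),
                          genome = default_genome()) {
  role <- match.arg(role)
  if (any(!is.finite(probes$log2_ratio)))
    stop("log2 ratios must be finite")
  ord <- order(match(probes$chrom, genome$chrom), probes$start)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  if (anyDuplicated(probes[, c("chrom", "start")]))
    stop("duplicated probe positions")
  structure(list(sample_id = sample_id, probes = probes, role = role,
                 genome = genome),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat("probe_profile '", x$sample_id, "' (", x$role, "): ",
      nrow(x$probes), " probes on ",
      length(unique(x$probes$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Write a probe profile back to its tab-delimited form
#' @param profile a `probe_profile`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_probe_table <- function(profile, path) {
  out <- data.frame(ProbeID = profile$probes$probe_id,
                    Chrom = profile$probes$chrom,
                    Start = format(profile$probes$start, scientific = FALSE,
                                   trim = TRUE),
                    End = format(profile$probes$end, scientific = FALSE,
                                 trim = TRUE),
                    Log2Ratio = profile$probes$log2_ratio)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a UCSC cytoBand file
#'
#' Tab-delimited chrom, start, end, band, stain; 0-based half-open input is
#' kept as boundary positions in bp, `chr` prefixes stripped.
#'
#' @param path file path.
#' @return data.frame chrom/start/end/band/stain.
#' @export
read_cytoband <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "band", "stain"))
  x$chrom <- sub("^chr", "", x$chrom)
  x
}

# Fixture registry: packaged transcriptions of the cohort tables plus the
# supporting reference files. Content-hashed so silent edits are caught.
.fixture_files <- c(
  table4      = "table4_taml_cna.tsv",
  table5      = "table5_paml_cna.tsv",
  table6      = "table6_mcr.tsv",
  patients    = "patients.tsv",
  cnv_regions = "cnv_regions_dgv_standin.tsv",
  ig_loci     = "ig_tr_loci.tsv",
  cytobands   = "cytoband_hg18_synthetic.txt",
  genome      = "hg18.chrom.sizes"
)

# md5 checksums of the packaged fixtures (NA disables the check for a file).
.fixture_md5 <- c(
  table4      = "514fa736d22c342eee4f45b7b83c77b7",
  table5      = "7dfa761918cc0cc099975b0a790d6a23",
  table6      = "ec43dcadc126ac04ba2df248e419750a",
  patients    = "d1e2a599b68e1212ebc8ffece8538747",
  cnv_regions = "b2d98d8401f6e504fc13786d0e71a501",
  ig_loci     = "eee66744c8bffca83800d64f6b0fb100",
  cytobands   = "7a6bf56ffb54067ce0336b48d22922c7",
  genome      = "fdc491816b4131494e4dd13f91acb4f8"
)

read_cna_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(start_mb = "numeric",
                                        end_mb = "numeric",
                                        ratio = "numeric", ig = "integer"))
  calls <- data.frame(patient = x$patient, group = x$group,
                      direction = x$direction, chrom = as.character(x$chrom),
                      bands = x$bands,
                      start = round(x$start_mb * BP_PER_MB),
                      end = round(x$end_mb * BP_PER_MB),
                      ratio = x$ratio,
                      ig_printed = x$ig == 1L,
                      stringsAsFactors = FALSE)
  calls$state <- state_from_direction(calls$ratio, calls$direction)
  validate_intervals(calls)
  calls
}

#' Load a packaged fixture
#'
#' `table4` / `table5`: per-patient cohort CNA tables (therapy-related and
#' de novo groups) transcribed row-for-row from the published tables,
#' asterisked IG rows carried in `ig_printed`, typos normalized per the
#' packaged erratum list. `table6`: the published MCR catalog, split by
#' group. `patients`: cohort membership with karyotype prefixes.
#' `cnv_regions`: germline CNV regions standing in for the Database of
#' Genomic Variants. `ig_loci`: IG/TR cluster extents. `cytobands`:
#' synthetic band map (chr21 detailed). `genome`: hg18 chromosome lengths.
#'
#' @param name one of `table4`, `table5`, `table6`, `patients`,
#'   `cnv_regions`, `ig_loci`, `cytobands`, `genome`.
#' @return the corresponding structure (see Details).
#' @export
load_fixture <- function(name = c("table4", "table5", "table6", "patients",
                                  "cnv_regions", "ig_loci", "cytobands",
                                  "genome")) {
  name <- match.arg(name)
  path <- system.file("extdata", .fixture_files[[name]], package = "cnamcr",
                      mustWork = TRUE)
  want <- .fixture_md5[[name]]
  if (!is.na(want) && want != "d41d8cd98f00b204e9800998ecf8427e") {
    got <- unname(tools::md5sum(path))
    if (!identical(got, want))
      stop("fixture '", name, "' failed its content hash check (", got,
           " != ", want, ")")
  }
  switch(name,
    table4 = read_cna_tsv(path),
    table5 = read_cna_tsv(path),
    table6 = {
      x <- utils::read.table(path, sep = "\t", header = TRUE, fill = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(start_mb = "numeric",
                                            end_mb = "numeric",
                                            chrom = "character",
                                            amp = "integer"))
      cat <- data.frame(group = x$group, direction = x$direction,
                        chrom = x$chrom, bands = x$bands,
                        start = round(x$start_mb * BP_PER_MB),
                        end = round(x$end_mb * BP_PER_MB),
                        size_mb = x$size_mb,
                        patients = x$patients, smallest = x$smallest,
                        amplified = x$amp == 1L, stringsAsFactors = FALSE)
      list(taml = cat[cat$group == "t-AML", , drop = FALSE],
           paml = cat[cat$group == "p-AML", , drop = FALSE])
    },
    patients = utils::read.table(path, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE),
    cnv_regions = {
      x <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
      data.frame(chrom = x$chrom, start = round(x$start_mb * BP_PER_MB),
                 end = round(x$end_mb * BP_PER_MB), direction = x$direction,
                 genes = x$genes, stringsAsFactors = FALSE)
    },
    ig_loci = {
      x <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(chrom = "character"))
      data.frame(name = x$name, chrom = x$chrom, band = x$band,
                 start = round(x$start_mb * BP_PER_MB),
                 end = round(x$end_mb * BP_PER_MB), stringsAsFactors = FALSE)
    },
    cytobands = read_cytoband(path),
    genome = read_chrom_sizes(path)
  )
}

#' Write a cohort CNA table
#'
#' Tab-delimited, one row per call, Mb at two decimals.
#'
#' @param calls cohort CNA data.frame (bp coordinates).
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_cna_table <- function(calls, path) {
  out <- data.frame(patient = calls$patient,
                    group = if (!is.null(calls$group)) calls$group else NA,
                    chrom = calls$chrom,
                    start_mb = sprintf("%.2f", calls$start / BP_PER_MB),
                    end_mb = sprintf("%.2f", calls$end / BP_PER_MB),
                    direction = calls$direction,
                    ratio = sprintf("%.2f", calls$ratio),
                    state = calls$state,
                    ig_flag = if (!is.null(calls$ig_flag)) calls$ig_flag else FALSE,
                    cnv_flag = if (!is.null(calls$cnv_flag)) calls$cnv_flag else FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an MCR table
#'
#' @param mcrs MCR data.frame from [derive_mcr_candidates()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_mcr_table <- function(mcrs, path) {
  out <- data.frame(chrom = mcrs$chrom,
                    start_mb = sprintf("%.2f", mcrs$start / BP_PER_MB),
                    end_mb = sprintf("%.2f", mcrs$end / BP_PER_MB),
                    direction = mcrs$direction,
                    size_mb = sprintf("%.2f", mcrs$size_mb),
                    n_support = mcrs$n_support,
                    patients = mcrs$patients,
                    amplified = mcrs$amplified)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
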