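#' Construct an intensity report
#'
#' Container for per-probe SNP-array signals: a probe table (id, chromosome,
#' 1-based position) plus matched matrices of Log R Ratios and B-allele
#' frequencies, probes in rows and samples in columns.  Probes are sorted by
#' chromosome then position; within a chromosome positions must be strictly
#' increasing.  Missing values are retained and masked downstream, never
#' imputed.
#'
#' @param probes `data.frame` with columns `probe_id`, `chromosome`,
#'   `position`.
#' @param lrr,baf numeric matrices, `nrow(probes)` x n_samples, with sample
#'   names as column names.
#' @return An object of class `IntensityReport`.
#' @export
intensity_report <- function(probes, lrr, baf) {
  stopifnot(is.data.frame(probes),
            all(c("probe_id", "chromosome", "position") %in% names(probes)),
            is.matrix(lrr), is.matrix(baf),
            nrow(lrr) == nrow(probes), nrow(baf) == nrow(probes),
            identical(colnames(lrr), colnames(baf)))
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe_id: ",
         probes$probe_id[duplicated(probes$probe_id)][1])
  ord <- order(probes$chromosome, probes$position)
  probes <- probes[ord, , drop = FALSE]
  lrr <- lrr[ord, , drop = FALSE]
  baf <- baf[ord, , drop = FALSE]
  rownames(probes) <- NULL
  for (chr in unique(probes$chromosome)) {
    p <- probes$position[probes$chromosome == chr]
    if (any(diff(p) <= 0))
      stop("duplicate probe positions on ", chr)
  }
  bad <- which(!is.na(baf) & (baf < 0 | baf > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("BAF outside [0,1] at probe ", probes$probe_id[bad[1, 1]],
         " sample ", colnames(baf)[bad[1, 2]])
  structure(list(probes = probes, lrr = lrr, baf = baf,
                 samples = colnames(lrr)),
            class = "IntensityReport")
}

#' @export
print.IntensityReport <- function(x, ...) {
  cat("IntensityReport:", nrow(x$probes), "probes,",
      length(x$samples), "samples,",
      length(unique(x$probes$chromosome)), "chromosome(s)\n")
  invisible(x)
}

#' Read a GenomeStudio-style final-report intensity table
#'
#' Expects a tab-delimited file with columns `Name`, `Chr`, `Position`
#' followed by `<sample>.LRR` / `<sample>.BAF` pairs.
#'
#' @param path file path.
#' @param sample_subset optional character vector restricting the samples
#'   loaded.
#' @return An [intensity_report()].
#' @export
read_intensity_report <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("Name", "Chr", "Position")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0)
    stop("malformed header: missing column ", miss[1])
  sig <- setdiff(names(tab), req)
  is_lrr <- grepl("\\.LRR$", sig)
  is_baf <- grepl("\\.BAF$", sig)
  if (any(!is_lrr & !is_baf))
    stop("malformed header: unrecognized column ", sig[!is_lrr & !is_baf][1])
  lrr_samples <- sub("\\.LRR$", "", sig[is_lrr])
  baf_samples <- sub("\\.BAF$", "", sig[is_baf])
  odd <- c(setdiff(lrr_samples, baf_samples), setdiff(baf_samples, lrr_samples))
  if (length(odd) > 0)
    stop("sample ", odd[1], " lacks a matching LRR/BAF column pair")
  samples <- lrr_samples
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, samples)
    if (length(missing_s) > 0)
      stop("sample not in report: ", missing_s[1])
    samples <- sample_subset
  }
  probes <- data.frame(probe_id = as.character(tab$Name),
                       chromosome = as.character(tab$Chr),
                       position = as.integer(tab$Position),
                       stringsAsFactors = FALSE)
  lrr <- as.matrix(tab[paste0(samples, ".LRR")])
  baf <- as.matrix(tab[paste0(samples, ".BAF")])
  colnames(lrr) <- colnames(baf) <- samples
  intensity_report(probes, lrr, baf)
}

#' Write an intensity report to a tab-delimited file
#' @param report an `IntensityReport`.
#' @param path output path.
#' @export
write_intensity_report <- function(report, path) {
  out <- report$probes
  names(out) <- c("Name", "Chr", "Position")
  for (s in report$samples) {
    out[[paste0(s, ".LRR")]] <- report$lrr[, s]
    out[[paste0(s, ".BAF")]] <- report$baf[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript annotation table
#'
#' Tab-delimited table of transcripts with columns `symbol`, `chromosome`,
#' `start`, `end` (1-based inclusive).  Alternate transcripts of one gene
#' are retained; the transcript-union gene interval is computed downstream
#' by [build_gene_intervals()].
#'
#' @param path file path.
#' @return `data.frame` of validated transcript records.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("symbol", "chromosome", "start", "end")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) stop("malformed header: missing column ", miss[1])
  bad <- which(tab$start > tab$end)
  if (length(bad) > 0)
    stop("transcript with start > end: ", tab$symbol[bad[1]])
  tab[req]
}

#' Write consensus calls as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open (`start - 1`, `end`).  Columns: chrom, chromStart, chromEnd,
#' name (sample id), score (caller support count), strand (`.`), direction,
#' and the comma-joined caller set.
#'
#' @param calls consensus-call `data.frame` (see [merge_consensus()]).
#' @param path output path.
#' @export
write_calls_bed <- function(calls, path) {
  if (nrow(calls) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = calls$chromosome,
                    chromStart = calls$start - 1L,
                    chromEnd = calls$end,
                    name = calls$sample,
                    score = calls$support,
                    strand = ".",
                    direction = calls$direction,
                    callers = calls$callers)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read consensus calls from BED written by [write_calls_bed()]
#' @param path BED path.
#' @return consensus-call `data.frame` with 1-based inclusive coordinates.
#' @export
read_calls_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0)
    return(data.frame(sample = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      direction = character(), support = integer(),
                      callers = character(), stringsAsFactors = FALSE))
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed) <- c("chrom", "chromStart", "chromEnd", "name", "score",
                  "strand", "direction", "callers")
  data.frame(sample = bed$name, chromosome = bed$chrom,
             start = bed$chromStart + 1L, end = bed$chromEnd,
             direction = bed$direction, support = as.integer(bed$score),
             callers = bed$callers, stringsAsFactors = FALSE)
}

#' Format a relative risk with its 95% confidence interval
#' @param rr,lo,hi numerics.
#' @return character like `"0.50 (0.20–1.27)"`.
#' @export
format_rr_ci <- function(rr, lo, hi) {
  sprintf("%.2f (%.2f–%.2f)", rr, lo, hi)
}

.assoc_cols <- c("gene", "n", "carriers", "carrier_freq", "allele_freq",
                 "n_deletions", "U", "V", "chisq", "p", "rr",
                 "ci_lo", "ci_hi", "rr_ci", "q")

#' Write an association results table
#'
#' Tab-delimited table shaped like a published per-locus association table:
#' gene symbol, carrier frequency (and the allele-count convention), score
#' statistic U and variance V, chi-square, p-value, approximate relative
#' risk with 95% CI (numeric bounds plus a formatted column), deletion
#' count, and q-value.  Numeric columns are written with 4 significant
#' figures; column order is fixed.
#'
#' @param results `data.frame` from [run_genomewide()] merged with
#'   [discrete_fdr()] q-values.
#' @param path output path.
#' @export
write_association_table <- function(results, path) {
  out <- results
  if (!"rr_ci" %in% names(out))
    out$rr_ci <- format_rr_ci(out$rr, out$ci_lo, out$ci_hi)
  if (!"q" %in% names(out)) out$q <- NA_real_
  out <- out[intersect(.assoc_cols, names(out))]
  for (cl in names(out))
    if (is.numeric(out[[cl]]) && !cl %in% c("n", "carriers", "n_deletions"))
      out[[cl]] <- signif(out[[cl]], 4)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an association results table written by [write_association_table()]
#' @param path file path.
#' @return `data.frame`.
#' @export
read_association_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a per-carrier phenotype table
#'
#' Tab-delimited with columns `sample`, `age_bc_dx`, `age_oc_dx`,
#' `age_mastectomy`, `age_oophorectomy`, `age_last_obs`; empty cells are
#' missing.  Validates that ages are positive and that no recorded event
#' age exceeds the age at last observation.
#'
#' @param path file path.
#' @return validated `data.frame`.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_phenotypes(tab)
}

#' Write a per-carrier phenotype table
#' @param phenos phenotype `data.frame`.
#' @param path output path.
#' @export
write_phenotype_table <- function(phenos, path) {
  write.table(phenos, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

validate_phenotypes <- function(tab) {
  req <- c("sample", "age_bc_dx", "age_oc_dx", "age_mastectomy",
           "age_oophorectomy", "age_last_obs")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0) stop("phenotype table missing column: ", miss[1])
  agecols <- req[-1]
  for (cl in agecols) {
    tab[[cl]] <- as.numeric(tab[[cl]])
    if (any(tab[[cl]] <= 0, na.rm = TRUE))
      stop("non-positive age in column ", cl)
  }
  if (any(is.na(tab$age_last_obs)))
    stop("age_last_obs is required for every sample")
  for (cl in c("age_bc_dx", "age_oc_dx", "age_mastectomy",
               "age_oophorectomy")) {
    late <- !is.na(tab[[cl]]) & tab[[cl]] > tab$age_last_obs
    if (any(late))
      stop("event after age_last_obs for sample ", tab$sample[late][1])
  }
  tab
}
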