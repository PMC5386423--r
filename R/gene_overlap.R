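#' Transcript-union gene intervals
#'
#' Collapses alternate transcripts of each gene symbol to one interval
#' spanning the start of the earliest and the end of the latest transcript.
#' A symbol annotated on two chromosomes is ambiguous and raises an error.
#'
#' @param transcripts `data.frame` with `symbol`, `chromosome`, `start`,
#'   `end` (see [read_gene_annotation()]).
#' @return `data.frame` of gene intervals, one row per symbol, sorted by
#'   chromosome then start.
#' @export
build_gene_intervals <- function(transcripts) {
  if (any(transcripts$start > transcripts$end))
    stop("transcript with start > end")
  split_tr <- split(transcripts, transcripts$symbol)
  out <- lapply(split_tr, function(tr) {
    if (length(unique(tr$chromosome)) > 1)
      stop("gene symbol on multiple chromosomes: ", tr$symbol[1])
    data.frame(symbol = tr$symbol[1], chromosome = tr$chromosome[1],
               start = min(tr$start), end = max(tr$end),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$start, res$symbol), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-gene deletion carrier matrix
#'
#' Marks sample s a carrier at gene g if any kept consensus deletion of s
#' overlaps the gene interval by at least 1 bp (1-based inclusive overlap:
#' `max(starts) <= min(ends)`).  The overlap scan uses an interval index
#' ([GenomicRanges::findOverlaps()]); a sample with several deletions over
#' one gene still yields a single carrier indicator (dominant coding).
#'
#' @param calls consensus `data.frame`; rows with `direction != "deletion"`
#'   are ignored.
#' @param genes gene intervals from [build_gene_intervals()].
#' @param samples full cohort sample names (the matrix rows); defaults to
#'   the samples present in `calls`, but the cohort set should be given so
#'   non-carriers count in the denominator of carrier frequencies.
#' @return list of class `CarrierMatrix`: `z` (binary samples x genes
#'   matrix), `deletion_count` (per-gene column sums), `genes`, `samples`.
#' @export
intersect_deletions_genes <- function(calls, genes,
                                      samples = unique(calls$sample)) {
  dels <- calls[calls$direction == "deletion", , drop = FALSE]
  z <- matrix(0L, length(samples), nrow(genes),
              dimnames = list(samples, genes$symbol))
  if (nrow(dels) > 0 && nrow(genes) > 0) {
    q <- GenomicRanges::GRanges(dels$chromosome,
                                IRanges::IRanges(dels$start, dels$end))
    su <- GenomicRanges::GRanges(genes$chromosome,
                                 IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::findOverlaps(q, su)
    z[cbind(dels$sample[S4Vectors::queryHits(hits)],
            genes$symbol[S4Vectors::subjectHits(hits)])] <- 1L
  }
  structure(list(z = z, deletion_count = colSums(z),
                 genes = genes, samples = samples),
            class = "CarrierMatrix")
}

#' Carrier frequency of a deletion locus
#'
#' The carrier-proportion convention: carriers / N.  This is the
#' convention under which published per-locus "MAF (array data)" figures
#' for this design reproduce from carrier counts (e.g. 79/2319 = 3.4%).
#' The allele-count convention carriers / 2N is also emitted by
#' [write_association_table()] for reference.
#'
#' @param z binary carrier vector for one gene.
#' @return fraction in `[0, 1]`.
#' @export
carrier_frequency <- function(z) {
  if (length(z) == 0) stop("empty carrier vector")
  mean(z)
}
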