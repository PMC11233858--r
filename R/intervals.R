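#' Labelled genomic interval set (0-based, half-open)
#'
#' A thin tibble class for the scan's interval outputs (Type 1 / Type 2 /
#' strong-introgression regions and any custom sets), using BED coordinate
#' conventions: 0-based half-open `[start, end)`.
#'
#' @param intervals tibble/data frame with `chrom`, `start`, `end`.
#' @param label set label, e.g. `"Type1"`.
#' @returns An `interval_set` tibble sorted by (chrom, start).
#' @export
interval_set <- function(intervals, label = "custom") {
  x <- as_tibble(intervals)[, c("chrom", "start", "end")]
  if (nrow(x) && any(x$start >= x$end)) abort("intervals must satisfy start < end")
  x <- arrange(x, .data$chrom, .data$start, .data$end)
  attr(x, "label") <- label
  class(x) <- c("interval_set", class(x))
  x
}

as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

granges_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Merge overlapping and book-ended intervals
#'
#' bedtools-merge semantics via [GenomicRanges::reduce()]: intervals that
#' overlap or touch are unioned into maximal intervals.
#'
#' @param x an [interval_set()].
#' @returns A merged `interval_set` with the same label.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0L) return(x)
  out <- granges_to_tibble(GenomicRanges::reduce(as_granges(x)))
  interval_set(out, label = attr(x, "label") %||% "custom")
}

#' Total span of an interval set in bp
#'
#' @param x an [interval_set()].
#' @param merged if `TRUE` (default) the span of the merged set (each base
#'   counted once); if `FALSE` the plain sum of interval lengths, which counts
#'   overlapping windows multiply. Both conventions are reported by the
#'   pipeline since outlier-interval spans are quoted both ways in practice.
#' @returns Numeric bp.
#' @export
interval_span <- function(x, merged = TRUE) {
  if (merged) x <- merge_intervals(x)
  sum(as.numeric(x$end - x$start))
}

#' Write an interval set as BED
#'
#' @param x an [interval_set()].
#' @param path output BED path (3 columns + name = label).
#' @returns `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- tibble(chrom = x$chrom, start = x$start, end = x$end,
               name = attr(x, "label") %||% ".")
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' Uses [rtracklayer::import()]; for GFF3 only `gene`-typed features are
#' kept. Coordinates are converted to 0-based half-open.
#'
#' @param path BED6/BED or GFF3 file (format inferred from the extension).
#' @returns Tibble (`gene_models`): `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_genes <- function(path) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type)) gr <- gr[tolower(as.character(gr$type)) == "gene"]
  id <- gr$gene_id %||% gr$ID %||% gr$Name %||% gr$name
  if (is.null(id)) id <- sprintf("gene_%05d", seq_along(gr))
  tibble(
    gene_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}
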