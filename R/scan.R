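#' Full in-memory differentiation + introgression scan
#'
#' The programmatic counterpart of [run_pipeline()]: takes a filtered
#' [genotype_panel()] and the four role labels, and returns one object
#' bundling the window statistics, the introgression windows, the Type 1 /
#' Type 2 classification, the decile association and the genome-wide
#' summaries. Methods: [tidy()] (per-window tibble), [glance()] (one-row
#' genome summary), [ggplot2::autoplot()] (windowed tracks).
#'
#' @param panel a filtered [genotype_panel()].
#' @param roles named character vector mapping `P1`, `P2`, `P3`, `O` to
#'   population labels.
#' @param spec a [window_spec()].
#' @param top_fst_fraction,tail_ratio_fraction classification tail fractions.
#' @param strong_top_fraction strong-introgression tail fraction.
#' @param min_informative minimum informative SNPs per D/f_d window.
#' @param chrom_lengths optional chromosome lengths.
#' @returns An `introscan_result`.
#' @export
introgression_scan <- function(panel, roles, spec = window_spec(),
                               top_fst_fraction = 0.05,
                               tail_ratio_fraction = 0.05,
                               strong_top_fraction = 0.01,
                               min_informative = 5L,
                               chrom_lengths = NULL) {
  windows <- window_scan(panel, roles[["P1"]], roles[["P2"]], spec, chrom_lengths)
  freqs <- population_frequencies(panel, roles)
  fd_windows <- window_d_fd(freqs, spec, min_informative, chrom_lengths)
  classification <- classify_windows(windows, top_fst_fraction, tail_ratio_fraction)
  deciles <- decile_summary(windows, fd_windows)
  structure(
    list(
      windows = windows,
      fd_windows = fd_windows,
      classification = classification,
      deciles = deciles,
      strong = strong_regions(fd_windows, strong_top_fraction),
      genome_d = genome_d(freqs),
      genome_fst = genome_fst(panel, roles[["P1"]], roles[["P2"]]),
      roles = roles, spec = spec
    ),
    class = "introscan_result"
  )
}

#' @export
print.introscan_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<introscan_result> %d windows (%d OK for f_d)\n",
           "genome F_ST = %.4f; genome D = %.4f (jackknife z = %.2f)\n",
           "Type1 %.2f Mb / Type2 %.2f Mb (merged); decile Spearman rho = %.2f\n"),
    g$n_windows, g$n_fd_ok, g$fst, g$D, g$D_z,
    g$type1_mb, g$type2_mb, g$decile_rho
  ))
  invisible(x)
}

#' @rdname introgression_scan
#' @param x an `introscan_result`.
#' @param ... unused.
#' @method tidy introscan_result
#' @export
tidy.introscan_result <- function(x, ...) {
  fd <- as_tibble(x$fd_windows)[c("chrom", "start", "end", "n_informative",
                                  "D", "fd", "status")]
  cl <- x$classification$windows[c("chrom", "start", "end", "z_fst",
                                   "log2_ratio", "type")]
  x$windows |>
    left_join(fd, by = c("chrom", "start", "end")) |>
    left_join(cl, by = c("chrom", "start", "end"))
}

#' @rdname introgression_scan
#' @method glance introscan_result
#' @export
glance.introscan_result <- function(x, ...) {
  span <- x$classification$span
  tibble(
    n_windows = nrow(x$windows),
    n_valid = sum(x$windows$valid),
    n_fd_ok = sum(x$fd_windows$status == "OK"),
    fst = x$genome_fst,
    D = x$genome_d$D,
    D_se = x$genome_d$se,
    D_z = x$genome_d$z,
    type1_mb = span$merged_bp[span$type == "Type1"] / 1e6,
    type2_mb = span$merged_bp[span$type == "Type2"] / 1e6,
    strong_mb = interval_span(x$strong) / 1e6,
    decile_rho = x$deciles$spearman_rho
  )
}
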