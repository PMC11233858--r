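#' Polarize site frequencies so the outgroup carries the ancestral allele
#'
#' Derived-allele frequencies for the four-taxon tests are obtained by taking
#' the alternate allele as derived when the outgroup alternate frequency
#' `pO < 0.5`; when `pO > 0.5` all four frequencies are flipped
#' (`p -> 1 - p`); sites with `pO == 0.5` carry no ancestral information and
#' are excluded (flagged unusable).
#'
#' @param freqs a `site_frequencies` tibble from [population_frequencies()].
#' @returns The tibble with frequencies polarized and `usable` updated.
#' @export
polarize_frequencies <- function(freqs) {
  flip <- !is.na(freqs$pO) & freqs$pO > 0.5
  for (col in c("p1", "p2", "p3", "pO")) {
    freqs[[col]][flip] <- 1 - freqs[[col]][flip]
  }
  freqs$usable <- freqs$usable & !(!is.na(freqs$pO) & freqs$pO == 0.5)
  freqs
}

#' Per-site ABBA/BABA pattern weights
#'
#' With derived-allele frequencies p1, p2, p3, pO (see
#' [polarize_frequencies()]), the frequency-based site weights are
#' `ABBA = (1-p1) p2 p3 (1-pO)` and `BABA = p1 (1-p2) p3 (1-pO)`; the f_d
#' "dynamic donor" weights substitute the per-site donor frequency
#' `pD = max(p2, p3)` into the P2 and P3 slots:
#' `ABBA_D = (1-p1) pD pD (1-pO)`, `BABA_D = p1 (1-pD) pD (1-pO)`.
#' Unusable sites are excluded (not zero-filled). A site is *informative*
#' when `ABBA + BABA > 0`.
#'
#' @param freqs a polarized `site_frequencies` tibble.
#' @returns Tibble with `chrom`, `pos`, `abba`, `baba`, `abba_d`, `baba_d`,
#'   `informative`.
#' @export
site_patterns <- function(freqs) {
  freqs <- freqs[freqs$usable %in% TRUE, , drop = FALSE]
  p1 <- freqs$p1; p2 <- freqs$p2; p3 <- freqs$p3; pO <- freqs$pO
  pd <- pmax(p2, p3)
  out <- tibble(
    chrom = freqs$chrom, pos = freqs$pos,
    abba = (1 - p1) * p2 * p3 * (1 - pO),
    baba = p1 * (1 - p2) * p3 * (1 - pO),
    abba_d = (1 - p1) * pd * pd * (1 - pO),
    baba_d = p1 * (1 - pd) * pd * (1 - pO)
  )
  out$informative <- (out$abba + out$baba) > 0
  out
}

#' Windowed Patterson's D and f_d with the scan's validity filters
#'
#' Accumulates the site weights of [site_patterns()] over the sliding-window
#' grid and reports, per window, `D = sum(ABBA - BABA) / sum(ABBA + BABA)`
#' and `fd = sum(ABBA - BABA) / sum(ABBA_D - BABA_D)`, applying the scan's
#' window filters exactly as printed for the source pipeline: windows with
#' fewer than `min_informative` informative SNPs are disregarded
#' (`TOO_FEW_SNPS`), windows with negative D are excluded (`NEGATIVE_D`), and
#' windows with `fd > 1` are excluded (`FD_GT_1`). A window whose dynamic
#' denominator is not positive while its numerator is nonzero is reported
#' distinctly as `UNDEFINED`, never as an infinite f_d. Only `OK` windows
#' carry an f_d value.
#'
#' @param freqs a `site_frequencies` tibble (polarized internally).
#' @param spec a [window_spec()].
#' @param min_informative minimum informative SNPs per window (default 5).
#' @param chrom_lengths optional chromosome lengths for terminal truncation.
#' @returns Tibble (`introgression_windows`): `chrom, start, end,
#'   n_informative, abba_sum, baba_sum, D, fd, status`.
#' @export
window_d_fd <- function(freqs, spec = window_spec(), min_informative = 5L,
                        chrom_lengths = NULL) {
  pat <- site_patterns(polarize_frequencies(freqs))
  if (nrow(pat) == 0L) abort("no usable sites for the introgression scan")
  ws <- window_sums(
    pat$chrom, pat$pos,
    cbind(abba = pat$abba, baba = pat$baba,
          abba_d = pat$abba_d, baba_d = pat$baba_d,
          informative = as.numeric(pat$informative)),
    spec, chrom_lengths
  )
  out <- ws$grid
  out$n_informative <- as.integer(round(as.vector(ws$sums[, "informative"])))
  out$abba_sum <- as.vector(ws$sums[, "abba"])
  out$baba_sum <- as.vector(ws$sums[, "baba"])
  num <- out$abba_sum - out$baba_sum
  den <- out$abba_sum + out$baba_sum
  den_d <- as.vector(ws$sums[, "abba_d"]) - as.vector(ws$sums[, "baba_d"])
  out$D <- ifelse(den > 0, num / den, NA_real_)
  fd <- ifelse(den_d > 0, num / den_d, NA_real_)
  fd[den_d <= 0 & num == 0] <- 0
  status <- rep("OK", nrow(out))
  status[!is.na(fd) & fd > 1] <- "FD_GT_1"
  status[is.na(fd)] <- "UNDEFINED"
  status[!is.na(out$D) & out$D < 0] <- "NEGATIVE_D"
  status[out$n_informative < min_informative] <- "TOO_FEW_SNPS"
  out$fd <- ifelse(status == "OK", fd, NA_real_)
  out$status <- factor(status, levels = c("OK", "TOO_FEW_SNPS", "NEGATIVE_D",
                                          "FD_GT_1", "UNDEFINED"))
  class(out) <- c("introgression_windows", class(out))
  out
}

#' Genome-wide Patterson's D with a chromosome block jackknife
#'
#' D over all usable sites pooled, with a delete-one-chromosome block
#' jackknife standard error (chromosomes are the blocks, absorbing local LD).
#' Used for null calibration: without gene flow the genome-wide D is expected
#' within a few SEs of zero.
#'
#' @param freqs a `site_frequencies` tibble.
#' @returns Tibble with one row: `D`, `se`, `z`, `n_blocks`, `n_sites`.
#' @export
genome_d <- function(freqs) {
  pat <- site_patterns(polarize_frequencies(freqs))
  tot <- c(abba = sum(pat$abba), baba = sum(pat$baba))
  D <- unname((tot["abba"] - tot["baba"]) / (tot["abba"] + tot["baba"]))
  chroms <- unique(pat$chrom)
  g <- length(chroms)
  if (g < 2L) {
    warn("block jackknife needs >= 2 chromosomes; SE unavailable")
    return(tibble(D = D, se = NA_real_, z = NA_real_, n_blocks = g,
                  n_sites = nrow(pat)))
  }
  d_loo <- vapply(chroms, function(ch) {
    keep <- pat$chrom != ch
    (sum(pat$abba[keep]) - sum(pat$baba[keep])) /
      (sum(pat$abba[keep]) + sum(pat$baba[keep]))
  }, numeric(1))
  se <- sqrt((g - 1) / g * sum((d_loo - mean(d_loo))^2))
  tibble(D = D, se = se, z = D / se, n_blocks = g, n_sites = nrow(pat))
}

#' Strong-introgression regions: top tail of window f_d, merged
#'
#' Selects the OK windows whose f_d reaches the top `top_fraction` (ties at
#' the cutoff included; see [top_tail_cutoff()]) and merges overlapping and
#' book-ended windows into maximal intervals (bedtools-merge semantics). The
#' default reproduces the "top 1% designated strong introgression regions,
#' merged" rule.
#'
#' @param windows an `introgression_windows` tibble from [window_d_fd()].
#' @param top_fraction upper tail fraction (default 0.01).
#' @returns An [interval_set()] labelled `"strong-introgression"`.
#' @export
strong_regions <- function(windows, top_fraction = 0.01) {
  check_fraction(top_fraction, "top_fraction", 1e-9, 1)
  ok <- windows[windows$status == "OK", , drop = FALSE]
  if (nrow(ok) == 0L) {
    warn("no OK windows; strong-introgression set is empty")
    return(interval_set(tibble(chrom = character(), start = integer(),
                               end = integer()), label = "strong-introgression"))
  }
  cutoff <- top_tail_cutoff(ok$fd, top_fraction)
  sel <- ok[ok$fd >= cutoff, c("chrom", "start", "end")]
  merge_intervals(interval_set(sel, label = "strong-introgression"))
}
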