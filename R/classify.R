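#' Type 1 / Type 2 outlier-interval classification
#'
#' Classifies scan windows jointly by population differentiation and the
#' diversity ratio, reproducing the two outlier interval types: windows in
#' the top `top_fst_fraction` of F_ST *and* the top `tail_ratio_fraction` of
#' `log2(pi_P2 / pi_P1)` are Type 1 (differentiated, P2 more diverse —
#' the introgression signature); windows in the top F_ST tail *and* the
#' bottom ratio tail are Type 2 (differentiated, P2 less diverse). F_ST is
#' z-scored across the valid window set and tail cutoffs are data-derived
#' (ties included; when every F_ST is identical the z-score is degenerate and
#' no window passes). Windows where either pi is 0 have an undefined log
#' ratio: they are excluded from the ratio tails (counted separately) though
#' they still participate in the F_ST tail.
#'
#' @param windows a window table from [window_scan()] (`chrom, start, end,
#'   pi_p1, pi_p2, fst, valid`).
#' @param top_fst_fraction,tail_ratio_fraction tail fractions (default 0.05).
#' @returns A list: `type1` and `type2` merged [interval_set()]s;
#'   `windows` — the input with `z_fst`, `log2_ratio`, `type` columns;
#'   `thresholds` (z cutoff and both ratio cutoffs); `span` — tibble of
#'   merged and summed bp spans per type; `n_ratio_undefined`.
#' @export
classify_windows <- function(windows, top_fst_fraction = 0.05,
                             tail_ratio_fraction = 0.05) {
  check_fraction(top_fst_fraction, "top_fst_fraction", 1e-9, 0.5)
  check_fraction(tail_ratio_fraction, "tail_ratio_fraction", 1e-9, 0.5)
  w <- as_tibble(windows)
  valid <- w$valid %in% TRUE & !is.na(w$fst) & !is.na(w$pi_p1) & !is.na(w$pi_p2)
  if (sum(valid) < 20L) abort("need >= 20 valid windows for percentile classification")
  w <- w[valid, , drop = FALSE]
  w$z_fst <- zscore(w$fst)
  ratio_ok <- w$pi_p1 > 0 & w$pi_p2 > 0
  w$log2_ratio <- ifelse(ratio_ok, log2(w$pi_p2 / w$pi_p1), NA_real_)

  z_cut <- if (all(is.na(w$z_fst))) NA_real_ else top_tail_cutoff(w$z_fst, top_fst_fraction)
  hi_cut <- top_tail_cutoff(w$log2_ratio, tail_ratio_fraction)
  lo_cut <- bottom_tail_cutoff(w$log2_ratio, tail_ratio_fraction)
  fst_tail <- !is.na(w$z_fst) & !is.na(z_cut) & w$z_fst >= z_cut
  t1 <- fst_tail & !is.na(w$log2_ratio) & w$log2_ratio >= hi_cut
  t2 <- fst_tail & !is.na(w$log2_ratio) & w$log2_ratio <= lo_cut
  w$type <- ifelse(t1, "Type1", ifelse(t2, "Type2", "none"))

  mk <- function(sel, label) {
    merge_intervals(interval_set(w[sel, c("chrom", "start", "end")], label = label))
  }
  type1 <- mk(t1, "Type1")
  type2 <- mk(t2, "Type2")
  span <- tibble(
    type = c("Type1", "Type2"),
    merged_bp = c(interval_span(type1), interval_span(type2)),
    summed_bp = c(sum(w$end[t1] - w$start[t1]), sum(w$end[t2] - w$start[t2]))
  )
  list(
    type1 = type1, type2 = type2, windows = w,
    thresholds = tibble(z_fst = z_cut, log2_ratio_high = hi_cut,
                        log2_ratio_low = lo_cut),
    span = span,
    n_ratio_undefined = sum(!ratio_ok)
  )
}

#' Decile association between window F_ST and f_d
#'
#' Ranks the valid scan windows by F_ST from high to low, splits them into 10
#' equal-count bins (any remainder goes to the first bins), and summarises
#' the distribution of OK f_d values within each decile — the decile boxplot
#' analysis relating population differentiation to introgression. Also
#' reports the Spearman correlation between decile rank (1 = highest F_ST)
#' and median f_d; a negative rho means more differentiated regions carry
#' more donor ancestry.
#'
#' @param windows window table from [window_scan()].
#' @param fd_windows `introgression_windows` from [window_d_fd()] on the same
#'   grid (matched by chrom/start/end).
#' @param n_bins number of bins (default 10).
#' @returns A list: `deciles` tibble (`decile, n, fst_median, fst_min,
#'   fst_max, n_fd, fd_median, fd_q1, fd_q3`) and `spearman_rho`.
#' @export
decile_summary <- function(windows, fd_windows, n_bins = 10L) {
  w <- as_tibble(windows)
  fd <- as_tibble(fd_windows)[c("chrom", "start", "end", "fd", "status")]
  w <- left_join(w, fd, by = c("chrom", "start", "end"))
  w <- w[w$valid %in% TRUE & !is.na(w$fst), , drop = FALSE]
  n <- nrow(w)
  if (n < n_bins) abort("fewer valid windows than bins")
  w <- arrange(w, desc(.data$fst))
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  w$decile <- rep(seq_len(n_bins), sizes)
  q <- function(x, p) if (all(is.na(x))) NA_real_ else
    unname(quantile(x, p, na.rm = TRUE, type = 7))
  deciles <- w |>
    group_by(.data$decile) |>
    summarise(
      n = n(),
      fst_median = median(.data$fst),
      fst_min = min(.data$fst),
      fst_max = max(.data$fst),
      n_fd = sum(.data$status %in% "OK"),
      fd_median = q(.data$fd[.data$status %in% "OK"], 0.5),
      fd_q1 = q(.data$fd[.data$status %in% "OK"], 0.25),
      fd_q3 = q(.data$fd[.data$status %in% "OK"], 0.75),
      .groups = "drop"
    )
  usable <- !is.na(deciles$fd_median)
  rho <- if (sum(usable) >= 3) {
    suppressWarnings(cor(deciles$decile[usable], deciles$fd_median[usable],
                         method = "spearman"))
  } else {
    NA_real_
  }
  list(deciles = deciles, spearman_rho = rho)
}

#' Genes associated with an interval set within a flank
#'
#' A gene is associated when its body, extended by `flank_bp` on both sides,
#' overlaps at least one interval by >= 1 bp (half-open semantics). This is
#' the rule used both for DMR-associated genes (2-kb flank) and for
#' GWAS peak candidate regions (10-kb flank).
#'
#' @param intervals an [interval_set()].
#' @param genes a `gene_models` tibble ([read_genes()]).
#' @param flank_bp flank in bp (>= 0).
#' @returns Character vector of associated `gene_id`s (sorted, unique).
#' @export
associate_genes <- function(intervals, genes, flank_bp = 0) {
  stopifnot(flank_bp >= 0)
  if (nrow(genes) == 0L || nrow(intervals) == 0L) return(character())
  if (!any(genes$chrom %in% intervals$chrom)) {
    abort("no gene chromosome matches any interval chromosome (naming-scheme clash?)")
  }
  g <- genes
  g$start <- pmax(0L, g$start - as.integer(flank_bp))
  g$end <- g$end + as.integer(flank_bp)
  hits <- GenomicRanges::findOverlaps(as_granges(g), as_granges(intervals),
                                      minoverlap = 1L)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' Venn-style intersection report for named candidate-gene sets
#'
#' All pairwise and the full intersections of two or more named gene-id sets,
#' with deterministic ordering — the cross-comparison step that narrows
#' interval-derived candidates against an externally supplied GWAS candidate
#' set.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @returns A list: `sizes` (per-set), `pairwise` tibble (`set_a, set_b, n,
#'   members`), `full` (character vector common to all sets), `full_n`.
#' @export
intersect_candidates <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list of >= 2 gene-id sets")
  }
  sets <- purrr::map(sets, function(s) sort(unique(as.character(s))))
  pairs <- combn(names(sets), 2L)
  pairwise <- purrr::map(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    inter <- intersect(sets[[a]], sets[[b]])
    tibble(set_a = a, set_b = b, n = length(inter),
           members = list(inter))
  }) |>
    purrr::list_rbind()
  full <- purrr::reduce(sets, intersect)
  list(
    sizes = purrr::map_int(sets, length),
    pairwise = pairwise,
    full = full,
    full_n = length(full)
  )
}

#' Per-locus, per-group genotype-class and allele-frequency summary
#'
#' For chosen loci (e.g. missense variants in a candidate gene), reports per
#' population group the fractions of hom-ref / het / hom-alt calls among
#' called samples and the alternate-allele frequency — the numbers behind
#' per-subgroup allele-frequency pie charts. Loci absent from the panel are
#' reported with `found = FALSE`, never silently skipped; a group with no
#' called sample at a locus is flagged undefined.
#'
#' @param panel a [genotype_panel()].
#' @param loci tibble with `chrom`, `pos`.
#' @param groups population labels to summarise (default: all in the panel).
#' @returns Tibble: `chrom, pos, found, population, n_called, frac_hom_ref,
#'   frac_het, frac_hom_alt, alt_freq, defined`.
#' @export
locus_summary <- function(panel, loci, groups = unique(panel$samples$population)) {
  loci <- as_tibble(loci)
  purrr::pmap(loci[c("chrom", "pos")], function(chrom, pos) {
    si <- which(panel$sites$chrom == chrom & panel$sites$pos == pos)
    purrr::map(groups, function(gp) {
      if (length(si) == 0L) {
        return(tibble(chrom = chrom, pos = pos, found = FALSE, population = gp,
                      n_called = 0L, frac_hom_ref = NA_real_, frac_het = NA_real_,
                      frac_hom_alt = NA_real_, alt_freq = NA_real_, defined = FALSE))
      }
      g <- panel$geno[si, panel$samples$population == gp]
      g <- g[!is.na(g)]
      nc <- length(g)
      tibble(
        chrom = chrom, pos = pos, found = TRUE, population = gp,
        n_called = nc,
        frac_hom_ref = if (nc) mean(g == 0L) else NA_real_,
        frac_het = if (nc) mean(g == 1L) else NA_real_,
        frac_hom_alt = if (nc) mean(g == 2L) else NA_real_,
        alt_freq = if (nc) sum(g) / (2 * nc) else NA_real_,
        defined = nc > 0L
      )
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
}

#' Cross-locus genotype-class concordance
#'
#' Fraction of samples (within a group, or all samples) carrying the same
#' genotype class at two loci, over samples called at both — quantifies the
#' co-segregation of nearby candidate variants.
#'
#' @param panel a [genotype_panel()].
#' @param locus_a,locus_b each a list/row with `chrom` and `pos`.
#' @param group optional population label.
#' @returns A single numeric fraction (NA when no sample is called at both).
#' @export
locus_concordance <- function(panel, locus_a, locus_b, group = NULL) {
  find <- function(l) {
    si <- which(panel$sites$chrom == l$chrom & panel$sites$pos == l$pos)
    if (length(si) != 1L) abort(sprintf("locus %s:%d not found", l$chrom, l$pos))
    si
  }
  cols <- if (is.null(group)) seq_len(n_samples(panel)) else
    which(panel$samples$population == group)
  ga <- panel$geno[find(locus_a), cols]
  gb <- panel$geno[find(locus_b), cols]
  both <- !is.na(ga) & !is.na(gb)
  if (!any(both)) return(NA_real_)
  mean(ga[both] == gb[both])
}
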