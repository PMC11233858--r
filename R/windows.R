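#' Sliding-window specification
#'
#' The scan's window grid: windows of `size_bp` starting at `anchor`,
#' `anchor + step_bp`, ... per chromosome (half-open bp intervals reported
#' 0-based in all outputs). Defaults reproduce the 50-kb windows sliding in
#' 5-kb steps used throughout the differentiation and introgression scan.
#'
#' @param size_bp window length in bp (default 50000).
#' @param step_bp slide step in bp (default 5000); must be <= `size_bp`.
#' @param anchor 1-based position of the first window start (default 1).
#' @returns A `window_spec` object.
#' @export
window_spec <- function(size_bp = 50000, step_bp = 5000, anchor = 1) {
  stopifnot(size_bp > 0, step_bp > 0, step_bp <= size_bp, anchor >= 1)
  structure(
    list(size_bp = as.integer(size_bp), step_bp = as.integer(step_bp),
         anchor = as.integer(anchor)),
    class = "window_spec"
  )
}

# Window grid per chromosome: starts anchor, anchor+step, ... while
# start <= last variant position. Full-size windows unless an explicit
# chromosome length truncates the terminal ones. Returns a tibble of
# half-open [start0, end) windows (start0 is 0-based = start - 1).
window_grid <- function(chrom, last_pos, spec, chrom_lengths = NULL) {
  purrr::map2(chrom, last_pos, function(ch, lp) {
    starts <- seq.int(spec$anchor, lp, by = spec$step_bp)
    end <- starts + spec$size_bp - 1L   # 1-based inclusive end
    len <- chrom_lengths[[ch]] %||% NA_integer_
    if (!is.na(len)) end <- pmin(end, as.integer(len))
    tibble(chrom = ch, start = starts - 1L, end = as.integer(end))
  }) |>
    purrr::list_rbind()
}

# Map each site to the window indices covering it. Returns tibble(win, site)
# where win indexes the rows of the window grid of its chromosome (offset
# applied by caller). pos is 1-based; windows are [start0, end) half-open,
# i.e. 1-based start0+1 .. end.
site_window_map <- function(pos, spec, n_windows) {
  rel <- pos - spec$anchor            # 0-based offset from first window start
  k_hi <- rel %/% spec$step_bp        # last window index (0-based) containing pos
  k_lo <- pmax(0L, (rel - spec$size_bp) %/% spec$step_bp + 1L)
  k_hi <- pmin(k_hi, n_windows - 1L)
  keep <- which(k_hi >= k_lo & rel >= 0L)
  counts <- (k_hi - k_lo + 1L)[keep]
  tibble(
    win = unlist(purrr::map2(k_lo[keep], k_hi[keep], seq.int)) + 1L,
    site = rep(keep, counts)
  )
}

# Aggregate a per-site numeric matrix into windows. values: matrix or vector
# indexed by site; returns list(grid, sums (matrix n_windows x ncol), n_sites).
window_sums <- function(sites_chrom, sites_pos, values, spec,
                        chrom_lengths = NULL, site_valid = NULL) {
  values <- as.matrix(values)
  chroms <- unique(sites_chrom)
  last_pos <- vapply(chroms, function(ch) max(sites_pos[sites_chrom == ch]), numeric(1))
  grid <- window_grid(chroms, last_pos, spec, chrom_lengths)
  sums <- matrix(0, nrow(grid), ncol(values),
                 dimnames = list(NULL, colnames(values)))
  n_in <- integer(nrow(grid))
  offset <- 0L
  for (ch in chroms) {
    si <- which(sites_chrom == ch)
    nwin <- sum(grid$chrom == ch)
    mp <- site_window_map(sites_pos[si], spec, nwin)
    if (!is.null(site_valid)) {
      ok <- site_valid[si][mp$site]
      mp <- mp[ok %in% TRUE, , drop = FALSE]
    }
    if (nrow(mp)) {
      v <- values[si[mp$site], , drop = FALSE]
      v[is.na(v)] <- 0
      agg <- rowsum(v, group = mp$win, reorder = TRUE)
      rows <- as.integer(rownames(agg))
      sums[offset + rows, ] <- sums[offset + rows, , drop = FALSE] + agg
      n_in[offset + seq_len(nwin)] <- tabulate(mp$win, nbins = nwin)
    }
    offset <- offset + nwin
  }
  list(grid = grid, sums = sums, n_sites = n_in)
}

# per-site nucleotide diversity from allele counts: 1 - sum_a C(n_a,2)/C(n,2)
site_pi <- function(alt, n) {
  ref <- n - alt
  denom <- n * (n - 1) / 2
  ifelse(n >= 2, 1 - (alt * (alt - 1) / 2 + ref * (ref - 1) / 2) / denom, NA_real_)
}

#' Windowed nucleotide diversity
#'
#' Per-site pi is computed from called allele counts as
#' `1 - sum_a C(n_a,2) / C(n,2)`; windowed pi divides the sum of site pi by the
#' window length in bp (monomorphic and unobserved positions contribute 0),
#' the VCFtools convention. Windows with no called variant site are flagged
#' invalid.
#'
#' @param panel a [genotype_panel()].
#' @param population population label (>= 2 samples required).
#' @param spec a [window_spec()].
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   truncate terminal windows.
#' @returns Tibble: `chrom`, `start` (0-based), `end`, `n_snps`, `pi`, `valid`.
#' @export
window_pi <- function(panel, population, spec = window_spec(),
                      chrom_lengths = NULL) {
  idx <- which(panel$samples$population == population)
  if (length(idx) < 2L) abort(sprintf("population '%s' has < 2 samples", population))
  ac <- allele_counts(panel, idx)
  sp <- site_pi(ac$alt, ac$n)
  ws <- window_sums(panel$sites$chrom, panel$sites$pos, cbind(pi = sp), spec,
                    chrom_lengths, site_valid = !is.na(sp))
  out <- ws$grid
  out$n_snps <- ws$n_sites
  out$pi <- as.vector(ws$sums[, "pi"]) / (out$end - out$start)
  out$valid <- ws$n_sites > 0L
  out$pi[!out$valid] <- NA_real_
  out
}

# Weir & Cockerham (1984) per-site variance components for r = 2 populations,
# from per-population sample sizes (called individuals), alternate allele
# frequencies, and observed heterozygote frequencies. Returns a, b, c vectors;
# NA where undefined (any n_i < 1, nbar <= 1, or site monomorphic overall).
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- pbar > 0 & pbar < 1
  ok <- ok & poly & nc > 0
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc)
}

# per-population per-site (n individuals called, alt freq, het freq)
pop_site_stats <- function(panel, idx) {
  g <- panel$geno[, idx, drop = FALSE]
  n <- unname(rowSums(!is.na(g)))
  alt <- unname(rowSums(g, na.rm = TRUE))
  het <- unname(rowSums(g == 1L, na.rm = TRUE))
  list(n = n, p = ifelse(n > 0, alt / (2 * n), NA_real_),
       h = ifelse(n > 0, het / n, NA_real_))
}

#' Windowed Weir-Cockerham F_ST
#'
#' Computes the Weir & Cockerham (1984) variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals) per site from genotype counts, and reports the windowed
#' weighted ("ratio of sums") estimate `sum(a) / sum(a + b + c)` over sites
#' with defined components — the VCFtools "weighted Fst" semantics. Sites
#' monomorphic across both populations are excluded; negative estimates are
#' retained (the scan z-scores windows downstream). Windows with no
#' informative site are flagged invalid.
#'
#' @inheritParams window_pi
#' @param popA,popB population labels (each >= 2 samples).
#' @returns Tibble: `chrom`, `start`, `end`, `n_snps` (informative sites),
#'   `fst`, `valid`.
#' @export
window_fst <- function(panel, popA, popB, spec = window_spec(),
                       chrom_lengths = NULL) {
  ia <- which(panel$samples$population == popA)
  ib <- which(panel$samples$population == popB)
  if (length(ia) < 2L || length(ib) < 2L) abort("both populations need >= 2 samples")
  sa <- pop_site_stats(panel, ia)
  sb <- pop_site_stats(panel, ib)
  comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  ok <- !is.na(comp$a)
  ws <- window_sums(
    panel$sites$chrom, panel$sites$pos,
    cbind(a = comp$a, tot = comp$a + comp$b + comp$c),
    spec, chrom_lengths, site_valid = ok
  )
  out <- ws$grid
  out$n_snps <- ws$n_sites
  out$fst <- ifelse(as.vector(ws$sums[, "tot"]) != 0,
                    as.vector(ws$sums[, "a"]) / as.vector(ws$sums[, "tot"]),
                    NA_real_)
  out$valid <- ws$n_sites > 0L & !is.na(out$fst)
  out$fst[!out$valid] <- NA_real_
  out
}

#' Genome-wide weighted F_ST
#'
#' The same Weir-Cockerham ratio of sums taken over all informative sites at
#' once (the single number quoted for subgroup-level differentiation).
#'
#' @inheritParams window_fst
#' @returns A single numeric value.
#' @export
genome_fst <- function(panel, popA, popB) {
  ia <- which(panel$samples$population == popA)
  ib <- which(panel$samples$population == popB)
  if (length(ia) < 2L || length(ib) < 2L) abort("both populations need >= 2 samples")
  sa <- pop_site_stats(panel, ia)
  sb <- pop_site_stats(panel, ib)
  comp <- wc_components(sa$n, sa$p, sa$h, sb$n, sb$p, sb$h)
  sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
}

#' Combined window scan of pi (two populations) and F_ST
#'
#' Convenience wrapper aligning [window_pi()] for P1 and P2 with
#' [window_fst()] on the same grid; the result feeds
#' [classify_windows()] and [decile_summary()].
#'
#' @inheritParams window_fst
#' @param popA treated as P1 (e.g. NHB analog), `popB` as P2 (SHB analog).
#' @returns Tibble with `chrom, start, end, n_snps, pi_p1, pi_p2, fst, valid`.
#' @export
window_scan <- function(panel, popA, popB, spec = window_spec(),
                        chrom_lengths = NULL) {
  pa <- window_pi(panel, popA, spec, chrom_lengths)
  pb <- window_pi(panel, popB, spec, chrom_lengths)
  fs <- window_fst(panel, popA, popB, spec, chrom_lengths)
  out <- fs[c("chrom", "start", "end")]
  out$n_snps <- fs$n_snps
  out$pi_p1 <- pa$pi
  out$pi_p2 <- pb$pi
  out$fst <- fs$fst
  out$valid <- fs$valid & pa$valid & pb$valid
  out
}

#' Greedy LD pruning by dosage-correlation r-squared
#'
#' Within sliding windows of `window_snps` SNPs (advancing `step_snps` at a
#' time), repeatedly removes the later-positioned SNP of the currently
#' retained pair with the highest squared dosage correlation until no retained
#' pair exceeds `r2_max`, then slides. r-squared is the squared Pearson
#' correlation of alternate-dosage vectors over samples with both genotypes
#' called (the PLINK composite measure for unphased data). Defaults are the
#' 50-SNP window, 10-SNP step, r2 > 0.1 pruning used before population
#' structure analysis.
#'
#' @param panel a [genotype_panel()].
#' @param window_snps SNPs per pruning window (>= 2).
#' @param step_snps SNPs to advance per slide.
#' @param r2_max retain only pairs with r-squared <= this threshold.
#' @returns The pruned `genotype_panel`.
#' @export
ld_prune <- function(panel, window_snps = 50L, step_snps = 10L, r2_max = 0.1) {
  stopifnot(window_snps >= 2L, step_snps >= 1L)
  keep <- rep(TRUE, n_sites(panel))
  for (ch in unique(panel$sites$chrom)) {
    si <- which(panel$sites$chrom == ch)
    m <- length(si)
    start <- 1L
    repeat {
      stop_at <- min(start + window_snps - 1L, m)
      widx <- si[start:stop_at]
      widx <- widx[keep[widx]]
      if (length(widx) >= 2L) {
        g <- panel$geno[widx, , drop = FALSE]
        repeat {
          r2 <- suppressWarnings(cor(t(g), use = "pairwise.complete.obs"))^2
          r2[!upper.tri(r2)] <- NA
          worst <- max(r2, na.rm = TRUE)
          if (!is.finite(worst) || worst <= r2_max) break
          # worst pair; ties broken toward the pair whose later SNP has the
          # largest position, then remove that later-positioned SNP
          cand <- which(r2 == worst, arr.ind = TRUE)
          drop_local <- max(cand[, 2])
          keep[widx[drop_local]] <- FALSE
          widx <- widx[-drop_local]
          if (length(widx) < 2L) break
          g <- panel$geno[widx, , drop = FALSE]
        }
      }
      if (stop_at >= m) break
      start <- start + step_snps
    }
  }
  panel_subset(panel, sites = keep)
}
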