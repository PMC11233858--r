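# Independent brute-force oracles, coded directly from first principles /
# published formulas with explicit loops. They share no code with the package
# implementations they check.

# Nucleotide diversity in a half-open window [start0, end) by exhaustive
# comparison of every unordered pair of called alleles at every site.
oracle_window_pi <- function(panel, population, chrom, start0, end) {
  cols <- which(panel$samples$population == population)
  in_win <- which(panel$sites$chrom == chrom &
                    panel$sites$pos > start0 & panel$sites$pos <= end)
  total <- 0
  for (si in in_win) {
    alleles <- integer(0)
    for (ci in cols) {
      g <- panel$geno[si, ci]
      if (!is.na(g)) alleles <- c(alleles, as.integer(c(g >= 1L, g == 2L)))
    }
    n <- length(alleles)
    if (n < 2L) next
    diff_pairs <- 0L
    pairs <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        pairs <- pairs + 1L
        if (alleles[i] != alleles[j]) diff_pairs <- diff_pairs + 1L
      }
    }
    total <- total + diff_pairs / pairs
  }
  total / (end - start0)
}

# Weir & Cockerham (1984) theta-hat for two populations, written as a per-site
# scalar loop over the published component formulas (r = 2), accumulating the
# ratio of sums. Genotype class counts are tallied explicitly.
oracle_wc_fst <- function(panel, popA, popB, sites = seq_len(nrow(panel$sites))) {
  ca <- which(panel$samples$population == popA)
  cb <- which(panel$samples$population == popB)
  sum_a <- 0
  sum_abc <- 0
  for (si in sites) {
    tally <- function(cols) {
      n <- 0L; alt <- 0L; het <- 0L
      for (ci in cols) {
        g <- unname(panel$geno[si, ci])
        if (is.na(g)) next
        n <- n + 1L
        alt <- alt + g
        if (g == 1L) het <- het + 1L
      }
      c(n = n, p = if (n > 0) alt / (2 * n) else NA_real_,
        h = if (n > 0) het / n else NA_real_)
    }
    A <- tally(ca); B <- tally(cb)
    n1 <- A[["n"]]; n2 <- B[["n"]]
    if (n1 < 1 || n2 < 1) next
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    pbar <- (n1 * A[["p"]] + n2 * B[["p"]]) / (2 * nbar)
    if (pbar <= 0 || pbar >= 1) next   # monomorphic across both
    nc <- (2 * nbar - (n1^2 + n2^2) / (2 * nbar)) / 1
    if (nc <= 0) next
    s2 <- (n1 * (A[["p"]] - pbar)^2 + n2 * (B[["p"]] - pbar)^2) / nbar
    hbar <- (n1 * A[["h"]] + n2 * B[["h"]]) / (2 * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    sum_a <- sum_a + a
    sum_abc <- sum_abc + a + b + cc
  }
  sum_a / sum_abc
}

# Per-site ABBA/BABA pattern sums for one window, as a scalar loop (derived
# frequencies assumed already polarized; sites with pO == 0.5 skipped).
oracle_d_fd <- function(freqs, chrom, start0, end) {
  abba <- baba <- abba_d <- baba_d <- 0
  n_inf <- 0L
  for (i in seq_len(nrow(freqs))) {
    if (freqs$chrom[i] != chrom) next
    if (!(freqs$pos[i] > start0 && freqs$pos[i] <= end)) next
    if (!isTRUE(freqs$usable[i])) next
    p1 <- freqs$p1[i]; p2 <- freqs$p2[i]; p3 <- freqs$p3[i]; pO <- freqs$pO[i]
    if (pO == 0.5) next
    if (pO > 0.5) {
      p1 <- 1 - p1; p2 <- 1 - p2; p3 <- 1 - p3; pO <- 1 - pO
    }
    ab <- (1 - p1) * p2 * p3 * (1 - pO)
    ba <- p1 * (1 - p2) * p3 * (1 - pO)
    pd <- if (p2 > p3) p2 else p3
    abba <- abba + ab
    baba <- baba + ba
    abba_d <- abba_d + (1 - p1) * pd * pd * (1 - pO)
    baba_d <- baba_d + p1 * (1 - pd) * pd * (1 - pO)
    if (ab + ba > 0) n_inf <- n_inf + 1L
  }
  list(abba = abba, baba = baba,
       D = if (abba + baba > 0) (abba - baba) / (abba + baba) else NA_real_,
       fd = if (abba_d - baba_d > 0) (abba - baba) / (abba_d - baba_d) else NA_real_,
       n_informative = n_inf)
}

# Greedy LD pruning, re-coded with explicit loops: same rule (within each
# 50-SNP window remove the later SNP of the worst r^2 pair until none exceeds
# the threshold, slide by step).
oracle_ld_prune_keep <- function(panel, window_snps, step_snps, r2_max) {
  keep <- rep(TRUE, nrow(panel$sites))
  for (ch in unique(panel$sites$chrom)) {
    si <- which(panel$sites$chrom == ch)
    m <- length(si)
    start <- 1L
    repeat {
      stop_at <- min(start + window_snps - 1L, m)
      repeat {
        widx <- si[start:stop_at]
        widx <- widx[keep[widx]]
        if (length(widx) < 2L) break
        worst <- -1
        worst_pair <- NULL
        for (i in seq_len(length(widx) - 1L)) {
          for (j in (i + 1L):length(widx)) {
            gi <- panel$geno[widx[i], ]
            gj <- panel$geno[widx[j], ]
            ok <- !is.na(gi) & !is.na(gj)
            if (sum(ok) < 2L) next
            r <- suppressWarnings(cor(gi[ok], gj[ok]))
            if (is.na(r)) next
            r2 <- r^2
            # ties toward the pair whose later SNP has the larger position
            if (r2 > worst + 1e-15 ||
                (abs(r2 - worst) <= 1e-15 && j > worst_pair[2])) {
              worst <- r2
              worst_pair <- c(i, j)
            }
          }
        }
        if (worst <= r2_max) break
        keep[widx[worst_pair[2]]] <- FALSE
      }
      if (stop_at >= m) break
      start <- start + step_snps
    }
  }
  keep
}

# Interval merge by sort-and-sweep (overlapping or book-ended).
oracle_merge <- function(df) {
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (is.null(cur) || row$chrom != cur$chrom || row$start > cur$end) {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- row
    } else {
      cur$end <- max(cur$end, row$end)
    }
  }
  if (!is.null(cur)) out[[length(out) + 1L]] <- cur
  dplyr::bind_rows(out)
}

# Exhaustive all-pairs gene-interval association with a flank.
oracle_associate <- function(intervals, genes, flank) {
  hits <- character(0)
  for (i in seq_len(nrow(genes))) {
    gs <- max(0, genes$start[i] - flank)
    ge <- genes$end[i] + flank
    for (j in seq_len(nrow(intervals))) {
      if (genes$chrom[i] != intervals$chrom[j]) next
      if (gs < intervals$end[j] && intervals$start[j] < ge) {
        hits <- c(hits, genes$gene_id[i])
        break
      }
    }
  }
  sort(unique(hits))
}

# Direct per-site allele-frequency tally for one population.
oracle_pop_freq <- function(panel, population) {
  cols <- which(panel$samples$population == population)
  m <- nrow(panel$sites)
  p <- rep(NA_real_, m)
  n <- integer(m)
  for (si in seq_len(m)) {
    alt <- 0L; called <- 0L
    for (ci in cols) {
      g <- panel$geno[si, ci]
      if (is.na(g)) next
      called <- called + 2L
      alt <- alt + g
    }
    n[si] <- called
    if (called >= 2L) p[si] <- alt / called
  }
  list(p = p, n = n)
}
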