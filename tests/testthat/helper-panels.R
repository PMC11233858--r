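# Small hand-built panels used across the suite.

# Quick panel from a dosage matrix (sites x samples).
make_panel <- function(geno, populations, chrom = "chr1", pos = NULL,
                       qual = NULL, depth = NULL) {
  geno <- as.matrix(geno)
  m <- nrow(geno)
  pos <- pos %||% seq(100L, by = 100L, length.out = m)
  sites <- tibble::tibble(
    chrom = rep(chrom, length.out = m), pos = pos,
    ref = rep("A", m), alt = rep("T", m),
    qual = qual %||% rep(90, m)
  )
  samples <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(ncol(geno))),
    population = populations
  )
  introscan::genotype_panel(sites, geno, samples, depth = depth)
}

# The 10-site filter fixture: 20 samples, each site violating exactly one
# criterion except two clean sites. Defaults: MAF > 0.05, missing < 0.10,
# QUAL > 30, 4 < mean depth < 100.
filter_fixture_panel <- function() {
  n <- 20L
  clean_row <- function(n_alt_het) c(rep(1L, n_alt_het), rep(0L, n - n_alt_het))
  rows <- list(
    maf_low1    = c(1L, rep(0L, n - 1L)),          # pooled alt freq 1/40 = 0.025
    maf_low2    = c(2L, rep(0L, n - 1L)),          # 2/40 = 0.05, not > 0.05
    miss_high1  = c(rep(NA_integer_, 3L), clean_row(8)[1:17]),  # 15% missing
    miss_high2  = c(rep(NA_integer_, 2L), clean_row(8)[1:18]),  # 10%, not < 10%
    qual_low1   = clean_row(8),
    qual_low2   = clean_row(8),
    depth_low   = clean_row(8),
    depth_high  = clean_row(8),
    clean1      = clean_row(8),
    clean2      = clean_row(10)
  )
  geno <- do.call(rbind, rows)
  qual <- c(90, 90, 90, 90, 25, 30, 90, 90, 90, 90)
  depth <- matrix(30, nrow = 10, ncol = n)
  depth[7, ] <- 4     # mean 4, not > 4
  depth[8, ] <- 100   # mean 100, not < 100
  make_panel(geno, populations = rep(c("A", "B"), each = 10L),
             qual = qual, depth = depth)
}

# Seeded random panel: m sites, n samples per listed population.
random_panel <- function(m, pops = c(A = 5L), maf = c(0.1, 0.5),
                         missing_rate = 0, seed = 1L, chrom = "chr1") {
  set.seed(seed)
  n <- sum(pops)
  p <- runif(m, maf[1], maf[2])
  geno <- matrix(rbinom(m * n, 2L, rep(p, n)), m, n)
  if (missing_rate > 0) geno[runif(m * n) < missing_rate] <- NA_integer_
  make_panel(geno, populations = rep(names(pops), pops), chrom = chrom,
             pos = sort(sample.int(m * 150L, m)))
}

# Random role-frequency table for the D/f_d estimators.
random_freqs <- function(m, seed = 1L, pO = 0) {
  set.seed(seed)
  tibble::tibble(
    chrom = "chr1", pos = sort(sample.int(m * 200L, m)),
    p1 = runif(m), p2 = runif(m), p3 = runif(m),
    pO = if (length(pO) == 1L && pO == 0) rep(0, m) else runif(m),
    n1 = 20L, n2 = 20L, n3 = 20L, nO = 8L,
    usable = TRUE
  )
}

scan_roles <- c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O")
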