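test_that("frequency simulation honours its degenerate limits", {
  # no drift, no admixture: every population carries the ancestral frequency
  cfg0 <- sim_config(n_chromosomes = 1, chrom_length_bp = 5e4,
                     drift_F = c(P1 = 0, P2 = 0, P3 = 0, O = 0),
                     outgroup_polymorphic = TRUE, seed = 11)
  tr0 <- simulate_frequencies(cfg0)
  expect_equal(tr0$freqs$p1, tr0$freqs$ancestral)
  expect_equal(tr0$freqs$p2, tr0$freqs$ancestral)
  expect_equal(tr0$freqs$p3, tr0$freqs$ancestral)
  expect_equal(tr0$freqs$pO, tr0$freqs$ancestral)

  # full replacement: f = 1 inside a window makes P2 identical to P3 there
  cfg1 <- sim_config(n_chromosomes = 1, chrom_length_bp = 2e5,
                     introgressed_windows = tibble::tibble(
                       chrom = "chr1", start = 50000, end = 100000),
                     admixture_f = 1, seed = 12)
  tr1 <- simulate_frequencies(cfg1)
  inw <- tr1$freqs$introgressed
  expect_gt(sum(inw), 0)
  expect_equal(tr1$freqs$p2[inw], tr1$freqs$p3[inw])
  expect_false(isTRUE(all.equal(tr1$freqs$p2[!inw], tr1$freqs$p3[!inw])))
})

test_that("Balding-Nichols draws match an independently coded sampler at the summary level", {
  n <- 20000L
  F <- 0.05
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 3.1e6,
                    drift_F = c(P1 = F, P2 = F, P3 = F, O = 0), seed = 21)
  tr <- simulate_frequencies(cfg)
  expect_gte(nrow(tr$freqs), n)
  # conditional mean: E[p | x] = x, so mean(p - x) ~ 0 within Monte-Carlo error
  dev <- tr$freqs$p1 - tr$freqs$ancestral
  expect_lt(abs(mean(dev)), 4 * sd(dev) / sqrt(length(dev)))

  # independent sampler: inverse-CDF Beta draws, fresh uniforms
  set.seed(9001)
  x <- runif(n, 0.05, 0.95)
  s <- (1 - F) / F
  p_oracle <- qbeta(runif(n), x * s, (1 - x) * s)
  dev_o <- p_oracle - x
  # the two samplers agree on the drift magnitude: Var(p - x) = F * E[x(1-x)]
  expect_lt(abs(var(dev) - var(dev_o)),
            5 * sd(c(dev^2, dev_o^2)) / sqrt(n))
  expect_lt(abs(var(dev) - F * mean(tr$freqs$ancestral * (1 - tr$freqs$ancestral))),
            4 * sd(dev^2) / sqrt(n))
})

test_that("genotype draws conserve the truth frequencies", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 2e6,
                    n_samples = c(P1 = 25L, P2 = 2L, P3 = 2L, O = 2L),
                    drift_F = c(P1 = 0.1, P2 = 0, P3 = 0, O = 0),
                    missing_rate = 0.02, seed = 31)
  sim <- simulate_panel(cfg)
  m <- n_sites(sim$panel)
  expect_gte(m, 10000L)
  cols <- which(sim$panel$samples$population == "P1")
  g <- sim$panel$geno[, cols]
  alt <- rowSums(g, na.rm = TRUE)
  n_called <- 2L * rowSums(!is.na(g))
  # per-site exact binomial test at alpha = 0.001; under the model the
  # rejection fraction should sit near alpha
  pval <- vapply(seq_len(m), function(i) {
    stats::binom.test(alt[i], n_called[i], p = sim$truth$freqs$p1[i])$p.value
  }, numeric(1))
  expect_lt(mean(pval < 0.001), 0.005)

  # fixed-frequency endpoints map to fixed genotypes
  tr <- sim$truth
  tr$freqs$p1 <- rep(c(0, 1), length.out = m)
  panel01 <- simulate_genotypes(tr)
  g01 <- panel01$geno[, panel01$samples$population == "P1"]
  expect_true(all(g01[tr$freqs$p1 == 0, ] == 0L, na.rm = TRUE))
  expect_true(all(g01[tr$freqs$p1 == 1, ] == 2L, na.rm = TRUE))
})

test_that("pooled sample frequency lands within binomial error of the truth", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 1.6e6,
                    n_samples = c(P1 = 50L, P2 = 2L, P3 = 2L, O = 2L),
                    drift_F = c(P1 = 0, P2 = 0, P3 = 0, O = 0),
                    missing_rate = 0, seed = 41)
  sim <- simulate_panel(cfg)
  tr <- sim$truth
  tr$freqs$p1 <- rep(0.3, nrow(tr$freqs))
  panel <- simulate_genotypes(tr)
  g <- panel$geno[, panel$samples$population == "P1"]
  n_draws <- length(g) * 2L
  phat <- sum(g) / n_draws
  se <- sqrt(0.3 * 0.7 / n_draws)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("identical config gives byte-identical VCF; fixtures round-trip", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length_bp = 1e5, seed = 51,
                    missing_rate = 0.05)
  p1 <- simulate_panel(cfg)$panel
  p2 <- simulate_panel(cfg)$panel
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(p1, f1)
  write_vcf_fixture(p2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  pops <- withr::local_tempfile(fileext = ".tsv")
  write_population_table(p1, pops)
  back <- read_vcf(f1, pops)
  expect_identical(unname(back$geno), unname(p1$geno))
  expect_equal(back$sites$pos, p1$sites$pos)
  expect_equal(back$samples, p1$samples)

  # ground truth serializes losslessly
  tr <- simulate_frequencies(sim_config(
    n_chromosomes = 1, chrom_length_bp = 5e4,
    introgressed_windows = tibble::tibble(chrom = "chr1", start = 0, end = 2e4),
    admixture_f = 0.3, donor_divergent = TRUE, seed = 52))
  tj <- withr::local_tempfile(fileext = ".json")
  write_sim_truth(tr, tj)
  tr2 <- read_sim_truth(tj)
  expect_equal(tr2$freqs, tr$freqs)
  expect_equal(unclass(tr2$config), unclass(tr$config))

  # a missing call is written as ./. and read back missing
  tiny <- make_panel(rbind(c(0L, NA, 2L)), populations = rep("A", 3))
  ft <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(tiny, ft)
  expect_true(any(grepl("\\./\\.", readLines(ft))))
  popt <- withr::local_tempfile(fileext = ".tsv")
  write_population_table(tiny, popt)
  expect_identical(unname(read_vcf(ft, popt)$geno), unname(tiny$geno))
})

test_that("with no gene flow and equal drift, P1 and P2 are exchangeable", {
  # across seeds, the genome-mean windowed pi difference between P1 and P2
  # is centred on zero
  diffs <- vapply(1:8, function(s) {
    cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 3e5,
                      n_samples = c(P1 = 15L, P2 = 15L, P3 = 2L, O = 2L),
                      drift_F = c(P1 = 0.05, P2 = 0.05, P3 = 0, O = 0),
                      seed = 100 + s)
    panel <- simulate_panel(cfg)$panel
    spec <- window_spec(50000, 50000)
    mean(window_pi(panel, "P1", spec)$pi - window_pi(panel, "P2", spec)$pi,
         na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)) + 1e-12)
})

test_that("haplotype-level introgression mode shifts P2 allele frequencies toward P3", {
  win <- tibble::tibble(chrom = "chr1", start = 0, end = 3e5)
  cfg <- sim_config(n_chromosomes = 1, chrom_length_bp = 3e5,
                    n_samples = c(P1 = 30L, P2 = 30L, P3 = 30L, O = 2L),
                    drift_F = c(P1 = 0.02, P2 = 0.02, P3 = 0.3, O = 0),
                    introgressed_windows = win, admixture_f = 1,
                    introgression_mode = "haplotype", missing_rate = 0, seed = 61)
  sim <- simulate_panel(cfg)
  # frequencies themselves are untouched in haplotype mode
  expect_false(isTRUE(all.equal(sim$truth$freqs$p2, sim$truth$freqs$p3)))
  g2 <- sim$panel$geno[, sim$panel$samples$population == "P2"]
  p2_hat <- rowMeans(g2) / 2
  # at f = 1 every P2 allele is a P3 draw
  err <- p2_hat - sim$truth$freqs$p3
  expect_lt(abs(mean(err)), 0.01)
  # squared error against the donor frequency is smaller than against the
  # un-introgressed P2 frequency
  expect_gt(mean((p2_hat - sim$truth$freqs$p2)^2) -
              mean((p2_hat - sim$truth$freqs$p3)^2), 0)
})
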