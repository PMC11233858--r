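# The stated simulation worlds used by the calibration / recovery tests and
# by scripts/pilot_bands.R (which registers tolerance bands from pilot runs
# across seeds before the assertions were frozen). Generator parameters are
# fixed here once; tests never move them.

# Six designated 50-kb donor windows on two chromosomes; admixture fraction f.
world_fd_recovery <- function(f, seed) {
  introscan::sim_config(
    n_chromosomes = 2, chrom_length_bp = 6e5,
    n_samples = c(P1 = 20L, P2 = 20L, P3 = 20L, O = 4L),
    drift_F = c(P1 = 0.05, P2 = 0.05, P3 = 0.2, O = 0),
    introgressed_windows = tibble::tibble(
      chrom = rep(c("chr1", "chr2"), each = 3),
      start = rep(c(100000L, 250000L, 400000L), 2),
      end = rep(c(150000L, 300000L, 450000L), 2)
    ),
    admixture_f = f, missing_rate = 0.02, seed = seed
  )
}

# Eight truth windows at f = 0.5 for outlier-recall tests.
world_recall <- function(seed) {
  introscan::sim_config(
    n_chromosomes = 4, chrom_length_bp = 1e6,
    n_samples = c(P1 = 25L, P2 = 25L, P3 = 25L, O = 4L),
    drift_F = c(P1 = 0.05, P2 = 0.05, P3 = 0.2, O = 0),
    introgressed_windows = tibble::tibble(
      chrom = rep(sprintf("chr%d", 1:4), each = 2),
      start = rep(c(200000L, 600000L), 4),
      end = rep(c(250000L, 650000L), 4)
    ),
    admixture_f = 0.5, missing_rate = 0.02, donor_divergent = TRUE, seed = seed
  )
}

# Whole-genome gradient of admixture fractions: 30 contiguous 50-kb donor
# blocks per chromosome, f declining linearly from 0.95 to 0.10 across the
# genome, so the F_ST decile rank tracks donor ancestry.
world_decile <- function(seed) {
  blocks <- tidyr::crossing(
    chrom = sprintf("chr%d", 1:4),
    start = seq(0L, 1450000L, by = 50000L)
  )
  blocks$end <- blocks$start + 50000L
  f <- seq(0.95, 0.10, length.out = nrow(blocks))
  introscan::sim_config(
    n_chromosomes = 4, chrom_length_bp = 1.5e6,
    n_samples = c(P1 = 25L, P2 = 25L, P3 = 25L, O = 4L),
    drift_F = c(P1 = 0.05, P2 = 0.05, P3 = 0.2, O = 0),
    introgressed_windows = blocks, admixture_f = f,
    missing_rate = 0.02, donor_divergent = TRUE, seed = seed
  )
}

# No gene flow, symmetric drift; truth windows designated but empty (f = 0),
# for null calibration of D and of the truth-vs-elsewhere fd contrast.
world_null <- function(seed) {
  introscan::sim_config(
    n_chromosomes = 6, chrom_length_bp = 3e5,
    n_samples = c(P1 = 15L, P2 = 15L, P3 = 15L, O = 4L),
    drift_F = c(P1 = 0.05, P2 = 0.05, P3 = 0.2, O = 0),
    introgressed_windows = tibble::tibble(
      chrom = rep(sprintf("chr%d", 1:6), each = 2),
      start = rep(c(50000L, 200000L), 6),
      end = rep(c(100000L, 250000L), 6)
    ),
    admixture_f = 0, missing_rate = 0.02, seed = seed
  )
}

truth_intervals <- function(cfg) {
  introscan::interval_set(cfg$introgressed_windows[c("chrom", "start", "end")],
                          label = "truth")
}

# TRUE for scan windows lying inside a truth interval (half-open containment).
window_in_truth <- function(windows, truth) {
  vapply(seq_len(nrow(windows)), function(i) {
    any(truth$chrom == windows$chrom[i] &
          truth$start <= windows$start[i] &
          windows$end[i] <= truth$end)
  }, logical(1))
}

# Fraction of truth intervals overlapped (>= 1 bp) by an interval set.
interval_recall <- function(truth, found) {
  if (nrow(found) == 0L) return(0)
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(found$chrom == truth$chrom[i] &
          found$start < truth$end[i] & truth$start[i] < found$end)
  }, logical(1))
  mean(hit)
}

# Mean f_d of OK scan windows contained in the truth windows.
mean_fd_in_truth <- function(cfg, min_informative = 5L) {
  sim <- introscan::simulate_panel(cfg)
  freqs <- introscan::population_frequencies(sim$panel, scan_roles)
  iw <- introscan::window_d_fd(freqs, introscan::window_spec(),
                               min_informative = min_informative)
  truth <- truth_intervals(cfg)
  inside <- window_in_truth(iw, truth)
  mean(iw$fd[inside & iw$status == "OK"], na.rm = TRUE)
}

pilot_bands_path <- function() {
  testthat::test_path("fixtures", "pilot_bands.tsv")
}
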