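#' Simulation configuration for a four-population genotype panel
#'
#' Describes the stated world of the synthetic panels: four populations
#' P1/P2/P3/O whose per-site allele frequencies drift from a shared ancestral
#' frequency under the Balding-Nichols model, with donor-to-P2 introgression
#' confined to designated windows at a known admixture fraction. This gives
#' every downstream window statistic a known expectation (e.g. pairwise
#' Weir-Cockerham F_ST between two populations with equal drift F has
#' expectation F; window f_d in an introgressed window has expectation close
#' to the admixture fraction).
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param snp_density SNPs per kb; the default 6.62 matches the density of the
#'   filtered highbush-blueberry SNP map this pipeline is modelled on.
#' @param n_samples named integer vector of diploid sample counts, names
#'   `P1,P2,P3,O`; each must be >= 2.
#' @param drift_F named numeric vector of Balding-Nichols drift parameters in
#'   `[0,1)` for `P1,P2,P3,O`. `drift_F = 0` means the population frequency
#'   equals the ancestral frequency exactly (no drift). The default keeps the
#'   outgroup at 0 drift *and* monomorphic ancestral (see
#'   `outgroup_polymorphic`).
#' @param introgressed_windows tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open bp intervals) naming the windows where P2 receives
#'   donor ancestry; `NULL` for none.
#' @param admixture_f admixture fraction(s) in `[0,1]`: a scalar applied to all
#'   introgressed windows, or one value per row of `introgressed_windows`.
#' @param missing_rate probability that any genotype call is missing.
#' @param outgroup_polymorphic if `FALSE` (default) the outgroup is fixed for
#'   the ancestral allele (alternate frequency 0), so derived = alternate
#'   exactly; if `TRUE` the outgroup drifts from the ancestral frequency like
#'   the ingroups (using `drift_F["O"]`), exercising the polarization logic of
#'   the D/f_d estimator.
#' @param donor_divergent if `TRUE`, the donor P3 drifts around its own,
#'   independently drawn ancestral frequency (Uniform(0.05, 0.95)) rather than
#'   the shared one — emulating donation from a distinct species, as in
#'   interspecific crop introgression. Only then can introgression raise the
#'   recipient's nucleotide diversity (the Type 1 signature): mixing two pools
#'   with equal per-site means can only lower heterozygosity. Default `FALSE`
#'   (all four populations share the ancestral frequency).
#' @param introgression_mode `"frequency"` (default): P2's site frequency is
#'   replaced by `(1-f)*p2 + f*p3` inside introgressed windows.
#'   `"haplotype"`: frequencies are untouched and instead each P2 allele draw
#'   inside the window comes from the P3 frequency with probability `f`,
#'   giving within-sample LD realism at the same expected frequency.
#' @param seed integer RNG seed; identical configs (including seed) give
#'   bit-identical panels and VCF fixtures.
#' @returns A `sim_config` object (validated list).
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length_bp = 1e6,
                       snp_density = 6.62,
                       n_samples = c(P1 = 20L, P2 = 20L, P3 = 20L, O = 4L),
                       drift_F = c(P1 = 0.05, P2 = 0.05, P3 = 0.2, O = 0),
                       introgressed_windows = NULL,
                       admixture_f = 0,
                       missing_rate = 0.02,
                       outgroup_polymorphic = FALSE,
                       donor_divergent = FALSE,
                       introgression_mode = c("frequency", "haplotype"),
                       seed = 1L) {
  pops <- c("P1", "P2", "P3", "O")
  stopifnot(
    n_chromosomes >= 1, chrom_length_bp >= 1000, snp_density > 0,
    all(pops %in% names(n_samples)), all(pops %in% names(drift_F))
  )
  n_samples <- as.integer(n_samples[pops])
  names(n_samples) <- pops
  if (any(n_samples < 2L)) abort("each population needs >= 2 samples")
  drift_F <- as.numeric(drift_F[pops])
  names(drift_F) <- pops
  check_fraction(drift_F, "drift_F", 0, 1 - 1e-9)
  check_fraction(missing_rate, "missing_rate")
  introgression_mode <- match.arg(introgression_mode)
  if (!is.null(introgressed_windows)) {
    introgressed_windows <- as_tibble(introgressed_windows)
    stopifnot(all(c("chrom", "start", "end") %in% names(introgressed_windows)))
    if (any(introgressed_windows$start < 0) ||
        any(introgressed_windows$end > chrom_length_bp) ||
        any(introgressed_windows$start >= introgressed_windows$end)) {
      abort("introgressed windows must be non-empty and lie within chromosome bounds")
    }
    nw <- nrow(introgressed_windows)
    check_fraction(admixture_f, "admixture_f")
    if (!(length(admixture_f) %in% c(1L, nw))) {
      abort("`admixture_f` must be a scalar or one value per introgressed window")
    }
    introgressed_windows$f <- rep(admixture_f, length.out = nw)
  } else {
    check_fraction(admixture_f, "admixture_f")
  }
  structure(
    list(
      n_chromosomes = as.integer(n_chromosomes),
      chrom_length_bp = as.integer(chrom_length_bp),
      snp_density = snp_density,
      n_samples = n_samples,
      drift_F = drift_F,
      introgressed_windows = introgressed_windows,
      admixture_f = admixture_f,
      missing_rate = missing_rate,
      outgroup_polymorphic = outgroup_polymorphic,
      donor_divergent = donor_divergent,
      introgression_mode = introgression_mode,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Balding-Nichols draw: Beta(x(1-F)/F, (1-x)(1-F)/F) with mean x and variance
# F x (1-x); F = 0 degenerates to the ancestral frequency itself.
rbn <- function(x, F) {
  if (F == 0) return(x)
  s <- (1 - F) / F
  rbeta(length(x), x * s, (1 - x) * s)
}

#' Simulate per-site population allele frequencies (ground truth)
#'
#' Draws ancestral alternate-allele frequencies from Uniform(0.05, 0.95) at
#' uniformly placed site positions, drifts each population independently under
#' the Balding-Nichols model, and applies windowed frequency-level
#' introgression from P3 into P2. The result is the `sim_truth` against which
#' estimator recovery is tested.
#'
#' @param config a [sim_config()].
#' @returns A `sim_truth` object: the config plus a tibble `freqs` with
#'   columns `chrom`, `pos` (1-based), `ancestral`, `p1`, `p2`, `p3`, `pO`,
#'   and `introgressed` (logical truth flag per site).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_per_chrom <- max(2L, round(config$chrom_length_bp / 1000 * config$snp_density))
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  freqs <- purrr::map(chroms, function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, n_per_chrom, replace = FALSE))
    x <- runif(n_per_chrom, 0.05, 0.95)
    x3 <- if (config$donor_divergent) runif(n_per_chrom, 0.05, 0.95) else x
    tibble(
      chrom = ch, pos = pos, ancestral = x, ancestral_p3 = x3,
      p1 = rbn(x, config$drift_F[["P1"]]),
      p2 = rbn(x, config$drift_F[["P2"]]),
      p3 = rbn(x3, config$drift_F[["P3"]]),
      pO = if (config$outgroup_polymorphic) rbn(x, config$drift_F[["O"]]) else 0
    )
  }) |>
    purrr::list_rbind()
  freqs$introgressed <- FALSE
  iw <- config$introgressed_windows
  if (!is.null(iw) && nrow(iw) > 0) {
    for (i in seq_len(nrow(iw))) {
      hit <- freqs$chrom == iw$chrom[i] &
        freqs$pos > iw$start[i] & freqs$pos <= iw$end[i]
      freqs$introgressed[hit] <- TRUE
      if (config$introgression_mode == "frequency") {
        f <- iw$f[i]
        freqs$p2[hit] <- (1 - f) * freqs$p2[hit] + f * freqs$p3[hit]
      }
    }
  }
  structure(list(config = config, freqs = freqs), class = "sim_truth")
}

# per-window f looked up for haplotype-mode genotype draws
site_admixture_f <- function(truth) {
  freqs <- truth$freqs
  f <- numeric(nrow(freqs))
  iw <- truth$config$introgressed_windows
  if (!is.null(iw) && nrow(iw) > 0) {
    for (i in seq_len(nrow(iw))) {
      hit <- freqs$chrom == iw$chrom[i] &
        freqs$pos > iw$start[i] & freqs$pos <= iw$end[i]
      f[hit] <- iw$f[i]
    }
  }
  f
}

#' Simulate diploid genotypes from truth frequencies
#'
#' Each sample's genotype at each site is the sum of two Bernoulli allele
#' draws at its population's truth frequency (binomial dosage); missing calls
#' are introduced independently at `missing_rate`. Reference/alternate bases
#' and a uniform QUAL in (60, 100) are attached so the panel round-trips
#' through VCF.
#'
#' @param truth a `sim_truth` from [simulate_frequencies()].
#' @returns A [genotype_panel()] with population labels from the config.
#' @export
simulate_genotypes <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  config <- truth$config
  freqs <- truth$freqs
  m <- nrow(freqs)
  set.seed(config$seed + 1L)
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4L, m, replace = TRUE)
  alt_i <- 1L + (ref_i - 1L + sample.int(3L, m, replace = TRUE)) %% 4L
  sites <- tibble(
    chrom = freqs$chrom, pos = freqs$pos,
    ref = bases[ref_i], alt = bases[alt_i],
    qual = round(runif(m, 60, 100), 2)
  )
  pops <- c("P1", "P2", "P3", "O")
  hap_f <- if (config$introgression_mode == "haplotype") site_admixture_f(truth) else NULL
  geno_blocks <- purrr::map(pops, function(pop) {
    n <- config$n_samples[[pop]]
    p <- freqs[[c(P1 = "p1", P2 = "p2", P3 = "p3", O = "pO")[[pop]]]]
    if (pop == "P2" && !is.null(hap_f) && any(hap_f > 0)) {
      # haplotype mode: each allele copy is a P3 draw with probability f
      g <- matrix(0L, m, n)
      for (copy in 1:2) {
        donor <- matrix(rbinom(m * n, 1L, rep(hap_f, n)), m, n)
        pa <- ifelse(donor == 1L, freqs$p3, p)
        g <- g + matrix(rbinom(m * n, 1L, pa), m, n)
      }
      g
    } else {
      matrix(rbinom(m * n, 2L, rep(p, n)), m, n)
    }
  })
  geno <- do.call(cbind, geno_blocks)
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(geno)) < config$missing_rate, m, ncol(geno))
    geno[miss] <- NA_integer_
  }
  samples <- tibble(
    sample_id = unlist(purrr::map(pops, function(pop) {
      sprintf("%s_%02d", pop, seq_len(config$n_samples[[pop]]))
    })),
    population = rep(pops, config$n_samples[pops])
  )
  genotype_panel(sites, geno, samples)
}

#' One-call simulation of a panel plus its truth
#'
#' @param config a [sim_config()].
#' @returns List with elements `truth` and `panel`.
#' @export
simulate_panel <- function(config) {
  truth <- simulate_frequencies(config)
  list(truth = truth, panel = simulate_genotypes(truth))
}

#' Write a genotype panel as a VCF 4.2 fixture
#'
#' Emits a minimal GT-only VCF (GT:DP when per-sample depth is attached) that
#' round-trips through [read_vcf()] to an identical panel. Missing calls are
#' written as `./.`.
#'
#' @param panel a [genotype_panel()].
#' @param path output file path.
#' @returns `path`, invisibly.
#' @export
write_vcf_fixture <- function(panel, path) {
  if (n_sites(panel) == 0L) abort("refusing to write an empty panel")
  sites <- panel$sites
  ref <- sites %k% "ref" %||% rep("A", n_sites(panel))
  alt <- sites %k% "alt" %||% rep("T", n_sites(panel))
  qual <- sites %k% "qual"
  qual_s <- if (is.null(qual)) rep(".", n_sites(panel)) else format(qual, trim = TRUE, scientific = FALSE)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix(gt_code[as.character(panel$geno)], nrow = n_sites(panel))
  gt[is.na(panel$geno)] <- "./."
  has_dp <- !is.null(panel$depth)
  if (has_dp) {
    dp <- format(panel$depth, trim = TRUE, scientific = FALSE)
    dp[is.na(panel$depth)] <- "."
    gt <- matrix(paste(gt, dp, sep = ":"), nrow = n_sites(panel))
  }
  chrom_max <- tapply(sites$pos, sites$chrom, max)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=introscan",
    sprintf("##contig=<ID=%s,length=%d>", names(chrom_max), as.integer(chrom_max)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples$sample_id), collapse = "\t")
  )
  body <- paste(
    sites$chrom, sites$pos, ".", ref, alt, qual_s, "PASS", ".",
    if (has_dp) "GT:DP" else "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the sample-to-population assignment table
#'
#' @param panel a [genotype_panel()].
#' @param path output TSV path (columns `sample_id`, `population`).
#' @returns `path`, invisibly.
#' @export
write_population_table <- function(panel, path) {
  readr::write_tsv(panel$samples, path)
  invisible(path)
}

#' Serialize / restore simulation ground truth as JSON
#'
#' @param truth a `sim_truth`.
#' @param path JSON file path.
#' @returns `path` invisibly; `read_sim_truth()` returns the `sim_truth`.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  cfg$n_samples <- as.list(cfg$n_samples)   # keep names through JSON
  cfg$drift_F <- as.list(cfg$drift_F)
  cfg$introgressed_windows <- if (is.null(cfg$introgressed_windows)) {
    NULL
  } else {
    as.data.frame(cfg$introgressed_windows)
  }
  jsonlite::write_json(
    list(config = unclass(cfg), freqs = as.data.frame(truth$freqs)),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- raw$config
  config <- sim_config(
    n_chromosomes = cfg$n_chromosomes,
    chrom_length_bp = cfg$chrom_length_bp,
    snp_density = cfg$snp_density,
    n_samples = unlist(cfg$n_samples),
    drift_F = unlist(cfg$drift_F),
    introgressed_windows = if (is.null(cfg$introgressed_windows)) NULL else
      as_tibble(cfg$introgressed_windows)[c("chrom", "start", "end")],
    admixture_f = cfg$admixture_f,
    missing_rate = cfg$missing_rate,
    outgroup_polymorphic = cfg$outgroup_polymorphic,
    donor_divergent = cfg$donor_divergent %||% FALSE,
    introgression_mode = cfg$introgression_mode,
    seed = cfg$seed
  )
  structure(list(config = config, freqs = as_tibble(raw$freqs)), class = "sim_truth")
}
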