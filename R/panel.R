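#' Genotype panel
#'
#' The central in-memory container of the package: per-sample diploid genotype
#' dosages at biallelic SNP sites, with site metadata and a sample-to-population
#' assignment. Genotypes are coded as alternate-allele dosage 0/1/2, `NA` for a
#' missing call; phase is ignored.
#'
#' @param sites tibble with columns `chrom` (character), `pos` (1-based
#'   integer position), and optionally `ref`, `alt`, `qual`. Positions must be
#'   strictly increasing within each chromosome.
#' @param geno integer matrix, sites x samples, values in `{0,1,2,NA}`. Column
#'   names are sample ids.
#' @param samples tibble with columns `sample_id`, `population`; one row per
#'   genotype column, in column order.
#' @param depth optional numeric matrix of per-site per-sample read depth,
#'   same shape as `geno`.
#' @returns An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, geno, samples, depth = NULL) {
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(sites)) {
    abort("`geno` must have one row per site")
  }
  samples <- as_tibble(samples)
  stopifnot(all(c("sample_id", "population") %in% names(samples)))
  if (ncol(geno) != nrow(samples)) {
    abort("`geno` must have one column per sample")
  }
  colnames(geno) <- samples$sample_id
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    abort("genotype dosages must be 0, 1, 2 or NA")
  }
  ord <- order(sites$chrom, sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[ord, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[ord, , drop = FALSE]
  }
  if (anyDuplicated(sites[c("chrom", "pos")])) {
    abort("duplicate (chrom, pos) sites in panel")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(geno)))
  }
  structure(
    list(sites = sites, geno = geno, samples = samples, depth = depth),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  pops <- table(x$samples$population)
  cat(sprintf(
    "<genotype_panel> %d sites x %d samples (%d chromosome%s)\n",
    n_sites(x), n_samples(x), length(unique(x$sites$chrom)),
    if (length(unique(x$sites$chrom)) == 1L) "" else "s"
  ))
  cat("populations:", paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("missing calls: %.2f%%; depth %s\n", 100 * miss,
              if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' @rdname genotype_panel
#' @param panel a `genotype_panel`.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' @rdname genotype_panel
#' @export
n_samples <- function(panel) nrow(panel$samples)

#' Subset a panel by site index or by population
#'
#' @param panel a `genotype_panel`.
#' @param sites integer or logical index over sites (optional).
#' @param populations character vector of population labels to keep (optional).
#' @returns A new `genotype_panel`.
#' @export
panel_subset <- function(panel, sites = NULL, populations = NULL) {
  keep_s <- if (is.null(sites)) seq_len(n_sites(panel)) else sites
  keep_c <- if (is.null(populations)) {
    seq_len(n_samples(panel))
  } else {
    which(panel$samples$population %in% populations)
  }
  genotype_panel(
    sites = panel$sites[keep_s, , drop = FALSE],
    geno = panel$geno[keep_s, keep_c, drop = FALSE],
    samples = panel$samples[keep_c, , drop = FALSE],
    depth = if (is.null(panel$depth)) NULL else panel$depth[keep_s, keep_c, drop = FALSE]
  )
}

# Per-site alternate allele count / called allele count over a sample index.
# Returns list(alt, n): alt = sum of dosages, n = 2 * called genotypes.
allele_counts <- function(panel, cols = seq_len(n_samples(panel))) {
  g <- panel$geno[, cols, drop = FALSE]
  called <- !is.na(g)
  list(
    alt = unname(rowSums(g, na.rm = TRUE)),
    n = 2L * unname(rowSums(called))
  )
}

#' Per-site summary of a panel as a tibble
#'
#' One row per site with pooled alternate-allele frequency, missing-call rate,
#' and mean depth where available.
#'
#' @param panel a `genotype_panel`.
#' @returns A tibble.
#' @export
panel_sites <- function(panel) {
  ac <- allele_counts(panel)
  out <- panel$sites
  out$alt_freq <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
  out$missing_rate <- rowMeans(is.na(panel$geno))
  if (!is.null(panel$depth)) out$mean_depth <- rowMeans(panel$depth, na.rm = TRUE)
  out
}
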