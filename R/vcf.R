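#' Read a multi-sample VCF into a genotype panel
#'
#' Reads a VCF 4.x file (plain or bgzipped) through
#' [VariantAnnotation::readVcf()], keeps biallelic SNV records only
#' (multiallelic and indel records are dropped and counted), codes genotypes
#' as alternate-allele dosage ignoring phase, and attaches population labels
#' from a two-column TSV (`sample_id`, `population`).
#'
#' @param path VCF file.
#' @param pop_table path to the sample-to-population TSV, or a data frame with
#'   those columns. Every VCF sample must appear in the table; extra table
#'   rows are allowed (with a warning).
#' @returns A [genotype_panel()]. The per-site mean depth, when FORMAT `DP` is
#'   present, is carried in the `depth` matrix; dropped-record counts are in
#'   `attr(panel, "dropped")`.
#' @export
read_vcf <- function(path, pop_table) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  pops <- if (is.data.frame(pop_table)) {
    as_tibble(pop_table)
  } else {
    readr::read_tsv(pop_table, show_col_types = FALSE)
  }
  stopifnot(all(c("sample_id", "population") %in% names(pops)))

  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- VariantAnnotation::ref(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1L
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[!multi] <- as.character(unlist(alt[!multi]))
  snv <- !multi & nchar(as.character(ref)) == 1L & nchar(alt1) == 1L &
    as.character(ref) %in% c("A", "C", "G", "T") &
    alt1 %in% c("A", "C", "G", "T")
  keep <- which(!multi & snv %in% TRUE)
  dropped <- c(multiallelic = sum(multi), non_snv = sum(!multi) - length(keep))

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) abort("VCF has no GT FORMAT field")
  gt <- gt[keep, , drop = FALSE]
  vcf_samples <- colnames(gt)
  missing_samples <- setdiff(vcf_samples, pops$sample_id)
  if (length(missing_samples)) {
    abort(sprintf("samples absent from population table: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  extra <- setdiff(pops$sample_id, vcf_samples)
  if (length(extra)) {
    warn(sprintf("%d population-table rows have no VCF sample and are ignored",
                 length(extra)))
  }
  samples <- pops[match(vcf_samples, pops$sample_id), c("sample_id", "population")]

  # dosage lookup over the small set of observed GT strings; any allele "."
  # or unparseable entry becomes a missing call
  codes <- unique(as.vector(gt))
  dos <- vapply(codes, function(code) {
    alleles <- strsplit(code, "[/|]")[[1]]
    if (length(alleles) == 0L || any(alleles == ".") ||
        any(is.na(suppressWarnings(as.integer(alleles))))) {
      return(NA_integer_)
    }
    sum(as.integer(alleles) > 0L)
  }, integer(1))
  geno <- matrix(dos[match(as.vector(gt), codes)], nrow = nrow(gt))

  depth <- NULL
  dp <- VariantAnnotation::geno(vcf) %k% "DP"
  if (!is.null(dp)) {
    depth <- matrix(as.numeric(dp[keep, , drop = FALSE]), nrow = length(keep))
  }
  sites <- tibble(
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep],
    ref = as.character(ref)[keep],
    alt = alt1[keep],
    qual = as.numeric(rr$QUAL)[keep]
  )
  panel <- genotype_panel(sites, geno, samples, depth = depth)
  attr(panel, "dropped") <- dropped
  panel
}

#' Filter a panel by the standard resequencing SNP criteria
#'
#' Applies, jointly on the unfiltered panel, the filters used to derive the
#' high-quality SNP set: minor allele frequency (MAF) > `maf_min` computed
#' over all called alleles with samples pooled, missing-genotype fraction
#' < `max_missing`, site QUAL > `qual_min`, and mean per-sample depth strictly
#' between `depth_min` and `depth_max`. All inequalities are strict, as
#' printed for the source pipeline (MAF > 5%, missing < 10%, QUAL > 30,
#' depth > 4 and < 100). Criteria are evaluated per site on the input panel,
#' so filtering is order-independent by construction.
#'
#' @param panel a [genotype_panel()].
#' @param maf_min,max_missing,qual_min,depth_min,depth_max thresholds.
#' @returns The filtered `genotype_panel`; `attr(, "drop_counts")` is a named
#'   vector counting, per criterion, the sites violating it (a site failing
#'   several criteria is counted under each).
#' @export
filter_variants <- function(panel, maf_min = 0.05, max_missing = 0.10,
                            qual_min = 30, depth_min = 4, depth_max = 100) {
  check_fraction(maf_min, "maf_min", 0, 0.5)
  check_fraction(max_missing, "max_missing")
  ac <- allele_counts(panel)
  p <- ifelse(ac$n > 0, ac$alt / ac$n, NA_real_)
  maf <- pmin(p, 1 - p)
  fail_maf <- is.na(maf) | maf <= maf_min
  fail_missing <- rowMeans(is.na(panel$geno)) >= max_missing
  qual <- panel$sites %k% "qual"
  fail_qual <- if (is.null(qual)) {
    warn("panel has no QUAL; quality filter skipped")
    rep(FALSE, n_sites(panel))
  } else {
    !is.na(qual) & qual <= qual_min
  }
  if (is.null(panel$depth)) {
    warn("panel has no depth; depth filter skipped")
    fail_depth <- rep(FALSE, n_sites(panel))
  } else {
    md <- rowMeans(panel$depth, na.rm = TRUE)
    fail_depth <- !is.na(md) & (md <= depth_min | md >= depth_max)
  }
  keep <- !(fail_maf | fail_missing | fail_qual | fail_depth)
  out <- panel_subset(panel, sites = keep)
  attr(out, "drop_counts") <- c(
    maf = sum(fail_maf), missing = sum(fail_missing),
    qual = sum(fail_qual), depth = sum(fail_depth)
  )
  out
}

#' Per-population alternate-allele frequencies for the four scan roles
#'
#' Computes, per site, the alternate-allele frequency among called alleles of
#' each of the four roles of the four-taxon configuration (((P1,P2),P3),O):
#' P1 and P2 are the two diverging sister populations (e.g. the northern and
#' southern highbush subgroups), P3 the candidate donor, O the outgroup used
#' to infer ancestral states. Sites where any role has fewer than 2 called
#' alleles are flagged unusable for the D/f_d estimators.
#'
#' @param panel a [genotype_panel()].
#' @param roles named character vector mapping role -> population label, names
#'   `P1`, `P2`, `P3`, `O`.
#' @returns A tibble (`site_frequencies`): `chrom`, `pos`, `p1,p2,p3,pO`
#'   (frequencies, `NA` where the role has < 2 called alleles), `n1,n2,n3,nO`
#'   (called-allele counts) and `usable`.
#' @export
population_frequencies <- function(panel, roles) {
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(roles)))
  cols <- purrr::map(c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"), function(r) {
    idx <- which(panel$samples$population == roles[[r]])
    if (length(idx) == 0L) {
      abort(sprintf("role %s maps to population '%s' with zero samples", r, roles[[r]]))
    }
    idx
  })
  freq_of <- function(idx) {
    ac <- allele_counts(panel, idx)
    list(p = ifelse(ac$n >= 2L, ac$alt / ac$n, NA_real_), n = ac$n)
  }
  f1 <- freq_of(cols$P1); f2 <- freq_of(cols$P2)
  f3 <- freq_of(cols$P3); fO <- freq_of(cols$O)
  out <- tibble(
    chrom = panel$sites$chrom, pos = panel$sites$pos,
    p1 = f1$p, p2 = f2$p, p3 = f3$p, pO = fO$p,
    n1 = f1$n, n2 = f2$n, n3 = f3$n, nO = fO$n
  )
  out$usable <- !is.na(out$p1) & !is.na(out$p2) & !is.na(out$p3) & !is.na(out$pO)
  class(out) <- c("site_frequencies", class(out))
  out
}
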