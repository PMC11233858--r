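# Constructed window tables for classification tests.
mk_windows <- function(n, fst, pi_p1 = 0.002, pi_p2 = 0.002, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom,
    start = seq(0L, by = 50000L, length.out = n),
    end = seq(0L, by = 50000L, length.out = n) + 50000L,
    n_snps = 100L,
    pi_p1 = rep(pi_p1, length.out = n),
    pi_p2 = rep(pi_p2, length.out = n),
    fst = fst,
    valid = TRUE
  )
}

test_that("classify_windows picks exactly the joint-tail windows", {
  n <- 100L
  fst <- seq(0.01, 0.2, length.out = n)
  pi2 <- rep(0.002, n)
  # windows 96..100 have both top-5% fst and top-5% ratio
  pi2[96:100] <- 0.01
  w <- mk_windows(n, fst = fst, pi_p2 = pi2)
  cl <- classify_windows(w)
  expect_equal(sum(cl$windows$type == "Type1"), 5L)
  expect_equal(which(cl$windows$type == "Type1"), 96:100)
  # contiguous 50-kb blocks merge into one interval
  expect_equal(nrow(cl$type1), 1L)
  expect_equal(cl$type1$start, w$start[96])
  expect_equal(cl$type1$end, w$end[100])
  expect_equal(nrow(cl$type2), 0L)
  expect_equal(cl$span$merged_bp[cl$span$type == "Type1"], 5 * 50000)
  expect_equal(cl$span$summed_bp[cl$span$type == "Type1"], 5 * 50000)

  # Type2: bottom ratio tail on the same fst tail
  pi2b <- rep(0.002, n)
  pi2b[96:100] <- 0.0004
  cl2 <- classify_windows(mk_windows(n, fst = fst, pi_p2 = pi2b))
  expect_equal(which(cl2$windows$type == "Type2"), 96:100)
  expect_equal(nrow(cl2$type1), 0L)
})

test_that("degenerate identical F_ST leaves both sets empty", {
  w <- mk_windows(50, fst = rep(0.05, 50),
                  pi_p2 = seq(0.001, 0.004, length.out = 50))
  cl <- classify_windows(w)
  expect_equal(nrow(cl$type1), 0L)
  expect_equal(nrow(cl$type2), 0L)
  expect_true(all(cl$windows$type == "none"))
})

test_that("classification matches an independent percentile-then-filter oracle", {
  set.seed(53)
  n <- 400L
  w <- mk_windows(n, fst = runif(n, 0, 0.3),
                  pi_p1 = runif(n, 1e-4, 5e-3), pi_p2 = runif(n, 1e-4, 5e-3))
  # a few zero-pi windows must be excluded from ratio tails
  w$pi_p1[c(5, 10)] <- 0
  cl <- classify_windows(w, top_fst_fraction = 0.1, tail_ratio_fraction = 0.1)

  # oracle: direct sort-based reclassification
  ratio <- ifelse(w$pi_p1 > 0 & w$pi_p2 > 0, log2(w$pi_p2 / w$pi_p1), NA)
  k_fst <- ceiling(n * 0.1)
  fst_cut <- sort(w$fst, decreasing = TRUE)[k_fst]
  nr <- sum(!is.na(ratio))
  hi_cut <- sort(ratio[!is.na(ratio)], decreasing = TRUE)[ceiling(nr * 0.1)]
  lo_cut <- sort(ratio[!is.na(ratio)])[ceiling(nr * 0.1)]
  t1 <- w$fst >= fst_cut & !is.na(ratio) & ratio >= hi_cut
  t2 <- w$fst >= fst_cut & !is.na(ratio) & ratio <= lo_cut
  expect_equal(cl$windows$type == "Type1", t1)
  expect_equal(cl$windows$type == "Type2", t2)
  expect_equal(cl$n_ratio_undefined, 2L)

  # structural invariants
  expect_equal(sum(t1 & t2), 0L)
  top_fst_span <- sum((w$end - w$start)[w$fst >= fst_cut])
  expect_lte(cl$span$summed_bp[1] + cl$span$summed_bp[2], top_fst_span)
  expect_error(classify_windows(mk_windows(10, fst = runif(10))),
               ">= 20 valid windows")
})

test_that("decile binning is exact and ordered by F_ST", {
  fd_tbl <- function(w, fd) {
    tibble::tibble(chrom = w$chrom, start = w$start, end = w$end,
                   fd = fd, status = "OK")
  }
  w100 <- mk_windows(100, fst = runif(100))
  d100 <- decile_summary(w100, fd_tbl(w100, runif(100)))
  expect_equal(d100$deciles$n, rep(10L, 10))

  w103 <- mk_windows(103, fst = runif(103))
  d103 <- decile_summary(w103, fd_tbl(w103, runif(103)))
  expect_equal(d103$deciles$n, c(11L, 11L, 11L, rep(10L, 7)))
  expect_equal(sum(d103$deciles$n), 103L)

  # decile 1 holds the highest F_ST windows
  expect_true(min(d103$deciles$fst_min[1]) >= max(d103$deciles$fst_max[2]))

  # fd tracking fst by construction gives a perfectly negative rank correlation
  wt <- mk_windows(100, fst = seq(0.01, 0.5, length.out = 100))
  dt <- decile_summary(wt, fd_tbl(wt, seq(0.001, 0.4, length.out = 100)))
  expect_equal(dt$spearman_rho, -1)
})

test_that("gene association honours the flank and matches the all-pairs oracle", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 1000L, end = 2000L, strand = "+")
  iv <- interval_set(tibble::tibble(chrom = "chr1", start = 2500L, end = 3000L))
  expect_equal(associate_genes(iv, genes, flank_bp = 2000), "g1")
  expect_equal(associate_genes(iv, genes, flank_bp = 0), character(0))

  # monotonicity in flank + oracle on random sets
  set.seed(59)
  genes_r <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:200),
    chrom = sample(c("chr1", "chr2"), 200, TRUE),
    start = sample.int(1e6, 200)
  )
  genes_r$end <- genes_r$start + sample(500:5000, 200, TRUE)
  genes_r$strand <- "+"
  iv_r <- interval_set(tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 40, TRUE),
    start = sample.int(1e6, 40)
  ) |> dplyr::mutate(end = start + sample(1000:50000, 40, TRUE)))
  a0 <- associate_genes(iv_r, genes_r, 0)
  a2k <- associate_genes(iv_r, genes_r, 2000)
  expect_true(all(a0 %in% a2k))
  expect_equal(a0, oracle_associate(iv_r, genes_r, 0))
  expect_equal(a2k, oracle_associate(iv_r, genes_r, 2000))

  bad_genes <- dplyr::mutate(genes, chrom = "scaffold_1")
  expect_error(associate_genes(iv, bad_genes, 0), "naming-scheme clash")
})

test_that("candidate-set intersection reports Venn counts deterministically", {
  res <- intersect_candidates(list(interval = c("a", "b", "c"),
                                   gwas = c("b", "c", "d")))
  expect_equal(res$full, c("b", "c"))
  expect_equal(res$full_n, 2L)
  expect_equal(res$pairwise$n, 2L)

  expect_equal(intersect_candidates(list(x = "a", y = "b"))$full_n, 0L)

  set.seed(61)
  sets <- list(A = sample(letters, 15), B = sample(letters, 15),
               C = sample(letters, 15))
  res3 <- intersect_candidates(sets)
  brute_full <- sort(unique(letters[
    letters %in% sets$A & letters %in% sets$B & letters %in% sets$C]))
  expect_equal(res3$full, brute_full)
  for (i in seq_len(nrow(res3$pairwise))) {
    a <- sets[[res3$pairwise$set_a[i]]]
    b <- sets[[res3$pairwise$set_b[i]]]
    expect_equal(res3$pairwise$n[i], sum(sort(unique(a)) %in% b))
  }
  expect_error(intersect_candidates(list(c("a"))), "named list")
})

test_that("locus summaries report genotype classes, frequencies and concordance", {
  g <- c(rep(0L, 5), rep(1L, 3), rep(2L, 2))
  geno <- rbind(g, g, c(rep(NA_integer_, 5), g[6:10]))
  panel <- make_panel(geno, populations = rep(c("N", "S"), each = 5),
                      pos = c(100L, 200L, 300L))
  ls <- locus_summary(panel, tibble::tibble(chrom = "chr1", pos = c(100L, 999L)),
                      groups = c("N", "S"))
  n_row <- ls[ls$pos == 100 & ls$population == "N", ]
  expect_equal(n_row$frac_hom_ref, 1)
  expect_equal(n_row$alt_freq, 0)
  s_row <- ls[ls$pos == 100 & ls$population == "S", ]
  expect_equal(s_row$frac_het, 0.6)
  expect_equal(s_row$frac_hom_alt, 0.4)
  expect_equal(s_row$alt_freq, (3 + 4) / 10)
  # absent locus reported, not skipped
  expect_true(all(!ls$found[ls$pos == 999]))

  # one group entirely missing at a locus
  ls3 <- locus_summary(panel, tibble::tibble(chrom = "chr1", pos = 300L),
                       groups = c("N", "S"))
  expect_false(ls3$defined[ls3$population == "N"])
  expect_true(ls3$defined[ls3$population == "S"])

  # identical genotype columns -> concordance 1
  expect_equal(locus_concordance(panel,
                                 list(chrom = "chr1", pos = 100L),
                                 list(chrom = "chr1", pos = 200L)), 1)
})

test_that("ten-sample genotype-class example from the counting rule", {
  g <- c(rep(0L, 5), rep(1L, 3), rep(2L, 2))
  panel <- make_panel(rbind(g), populations = rep("G", 10))
  ls <- locus_summary(panel, tibble::tibble(chrom = "chr1", pos = 100L),
                      groups = "G")
  expect_equal(unlist(ls[c("frac_hom_ref", "frac_het", "frac_hom_alt")],
                      use.names = FALSE),
               c(0.5, 0.3, 0.2))
  expect_equal(ls$alt_freq, 0.35)
})
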