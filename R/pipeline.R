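#' Pipeline configuration
#'
#' A single validated config object drives the whole scan (filter -> window
#' statistics -> introgression -> classification -> association). It
#' serializes losslessly to JSON via [write_pipeline_config()] /
#' [read_pipeline_config()], and its hash is recorded in the run manifest so
#' reruns are attributable.
#'
#' @param vcf input VCF path.
#' @param pop_table sample-to-population TSV path.
#' @param roles named character vector mapping role (P1,P2,P3,O) -> population
#'   label in `pop_table`.
#' @param out_dir output directory (created if absent).
#' @param genes optional gene annotation (BED/GFF3) path.
#' @param loci optional TSV of loci (`chrom`, `pos`) for genotype summaries.
#' @param candidate_sets optional named list of character vectors of gene ids
#'   (external candidate sets, e.g. GWAS candidates) to intersect with the
#'   interval-derived genes.
#' @param window_size_bp,window_step_bp window grid (defaults 50 kb / 5 kb).
#' @param maf_min,max_missing,qual_min,depth_min,depth_max SNP filters
#'   (defaults: MAF > 0.05, missing < 0.10, QUAL > 30, 4 < depth < 100).
#' @param top_fst_fraction,tail_ratio_fraction classification tails (0.05).
#' @param strong_top_fraction strong-introgression tail (0.01).
#' @param min_informative minimum informative SNPs per D/f_d window (5).
#' @param flank_bp gene-association flank in bp (default 2000).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @param seed integer seed recorded in the manifest (the scan itself is
#'   deterministic; the seed feeds any resampling steps).
#' @returns A `pipeline_config` object.
#' @export
pipeline_config <- function(vcf, pop_table, roles, out_dir,
                            genes = NULL, loci = NULL, candidate_sets = NULL,
                            window_size_bp = 50000, window_step_bp = 5000,
                            maf_min = 0.05, max_missing = 0.10, qual_min = 30,
                            depth_min = 4, depth_max = 100,
                            top_fst_fraction = 0.05, tail_ratio_fraction = 0.05,
                            strong_top_fraction = 0.01, min_informative = 5L,
                            flank_bp = 2000, chrom_lengths = NULL, seed = 1L) {
  for (p in c(vcf, pop_table, genes, loci)) {
    if (!is.null(p) && !file.exists(p)) abort(sprintf("input path does not exist: %s", p))
  }
  stopifnot(all(c("P1", "P2", "P3", "O") %in% names(roles)))
  check_fraction(c(top_fst_fraction, tail_ratio_fraction), "classification fractions",
                 1e-9, 0.5)
  check_fraction(strong_top_fraction, "strong_top_fraction", 1e-9, 0.5)
  structure(
    list(
      vcf = vcf, pop_table = pop_table, roles = as.list(roles),
      out_dir = out_dir, genes = genes, loci = loci,
      candidate_sets = candidate_sets,
      window_size_bp = as.integer(window_size_bp),
      window_step_bp = as.integer(window_step_bp),
      maf_min = maf_min, max_missing = max_missing, qual_min = qual_min,
      depth_min = depth_min, depth_max = depth_max,
      top_fst_fraction = top_fst_fraction,
      tail_ratio_fraction = tail_ratio_fraction,
      strong_top_fraction = strong_top_fraction,
      min_informative = as.integer(min_informative),
      flank_bp = as.integer(flank_bp),
      chrom_lengths = if (is.null(chrom_lengths)) NULL else as.list(chrom_lengths),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, c(
    raw[setdiff(names(raw), c("roles", "candidate_sets", "chrom_lengths"))],
    list(roles = unlist(raw$roles),
         candidate_sets = raw$candidate_sets,
         chrom_lengths = if (is.null(raw$chrom_lengths)) NULL else unlist(raw$chrom_lengths))
  ))
}

cfg_spec <- function(config) {
  window_spec(config$window_size_bp, config$window_step_bp)
}

cfg_lengths <- function(config) {
  if (is.null(config$chrom_lengths)) NULL else unlist(config$chrom_lengths)
}

out_path <- function(config, name) file.path(config$out_dir, name)

load_filtered_panel <- function(config) {
  read_vcf(out_path(config, "filtered.vcf"), out_path(config, "population.tsv"))
}

pipeline_stages <- c("filter", "windows", "introgression", "classify", "associate")

#' Run one pipeline stage from saved intermediates
#'
#' Each stage reads only files (the config's inputs plus prior stages'
#' outputs under `out_dir`) and writes its own outputs, so running stages
#' individually is equivalent to the end-to-end run.
#'
#' @param config a [pipeline_config()].
#' @param stage one of `"filter"`, `"windows"`, `"introgression"`,
#'   `"classify"`, `"associate"`.
#' @returns A tibble of (output file, row count) for the stage's outputs.
#' @export
run_stage <- function(config, stage = pipeline_stages) {
  stage <- match.arg(stage)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cfg_spec(config)
  lens <- cfg_lengths(config)
  outputs <- switch(
    stage,
    filter = {
      panel <- read_vcf(config$vcf, config$pop_table)
      filtered <- filter_variants(panel, config$maf_min, config$max_missing,
                                  config$qual_min, config$depth_min, config$depth_max)
      write_vcf_fixture(filtered, out_path(config, "filtered.vcf"))
      write_population_table(filtered, out_path(config, "population.tsv"))
      dc <- attr(filtered, "drop_counts")
      readr::write_tsv(tibble(criterion = names(dc), n_dropped = as.integer(dc)),
                       out_path(config, "filter_drop_counts.tsv"))
      tibble(file = c("filtered.vcf", "population.tsv", "filter_drop_counts.tsv"),
             rows = c(n_sites(filtered), n_samples(filtered), length(dc)))
    },
    windows = {
      panel <- load_filtered_panel(config)
      ws <- window_scan(panel, config$roles$P1, config$roles$P2, spec, lens)
      readr::write_tsv(ws, out_path(config, "windows.tsv"))
      tibble(file = "windows.tsv", rows = nrow(ws))
    },
    introgression = {
      panel <- load_filtered_panel(config)
      freqs <- population_frequencies(panel, unlist(config$roles))
      iw <- window_d_fd(freqs, spec, config$min_informative, lens)
      readr::write_tsv(as_tibble(iw), out_path(config, "introgression.tsv"))
      sr <- strong_regions(iw, config$strong_top_fraction)
      write_bed(sr, out_path(config, "strong_introgression.bed"))
      gd <- genome_d(freqs)
      jsonlite::write_json(as.list(gd), out_path(config, "d_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      tibble(file = c("introgression.tsv", "strong_introgression.bed", "d_summary.json"),
             rows = c(nrow(iw), nrow(sr), 1L))
    },
    classify = {
      ws <- readr::read_tsv(out_path(config, "windows.tsv"), show_col_types = FALSE)
      iw <- readr::read_tsv(out_path(config, "introgression.tsv"), show_col_types = FALSE)
      cl <- classify_windows(ws, config$top_fst_fraction, config$tail_ratio_fraction)
      write_bed(cl$type1, out_path(config, "type1.bed"))
      write_bed(cl$type2, out_path(config, "type2.bed"))
      jsonlite::write_json(
        list(thresholds = as.list(cl$thresholds), span = cl$span,
             n_ratio_undefined = cl$n_ratio_undefined),
        out_path(config, "classification_summary.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows"
      )
      dec <- decile_summary(ws, iw)
      readr::write_tsv(dec$deciles, out_path(config, "deciles.tsv"))
      jsonlite::write_json(list(spearman_rho = dec$spearman_rho),
                           out_path(config, "decile_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      tibble(
        file = c("type1.bed", "type2.bed", "classification_summary.json",
                 "deciles.tsv", "decile_summary.json"),
        rows = c(nrow(cl$type1), nrow(cl$type2), 1L, nrow(dec$deciles), 1L)
      )
    },
    associate = {
      if (is.null(config$genes)) return(tibble(file = character(), rows = integer()))
      genes <- read_genes(config$genes)
      read_bed_set <- function(name, label) {
        p <- out_path(config, name)
        df <- if (file.size(p) > 0) {
          readr::read_tsv(p, col_names = c("chrom", "start", "end", "name"),
                          show_col_types = FALSE)
        } else {
          tibble(chrom = character(), start = integer(), end = integer())
        }
        interval_set(df[c("chrom", "start", "end")], label = label)
      }
      sets <- list(
        Type1 = read_bed_set("type1.bed", "Type1"),
        Type2 = read_bed_set("type2.bed", "Type2"),
        strong_introgression = read_bed_set("strong_introgression.bed",
                                            "strong-introgression")
      )
      assoc <- purrr::imap(sets, function(iv, nm) {
        ids <- if (nrow(iv)) associate_genes(iv, genes, config$flank_bp) else character()
        tibble(set = nm, gene_id = ids)
      }) |>
        purrr::list_rbind()
      readr::write_tsv(assoc, out_path(config, "associated_genes.tsv"))
      files <- tibble(file = "associated_genes.tsv", rows = nrow(assoc))
      if (!is.null(config$candidate_sets)) {
        interval_genes <- unique(assoc$gene_id[assoc$set %in% c("Type1", "Type2")])
        venn <- intersect_candidates(c(list(interval_genes = interval_genes),
                                       config$candidate_sets))
        jsonlite::write_json(
          list(sizes = as.list(venn$sizes),
               pairwise = dplyr::mutate(venn$pairwise,
                                        members = purrr::map_chr(.data$members,
                                                                 paste, collapse = ",")),
               full = venn$full, full_n = venn$full_n),
          out_path(config, "venn_report.json"),
          auto_unbox = TRUE, digits = NA, dataframe = "rows"
        )
        files <- bind_rows(files, tibble(file = "venn_report.json", rows = 1L))
      }
      if (!is.null(config$loci)) {
        panel <- load_filtered_panel(config)
        loci <- readr::read_tsv(config$loci, show_col_types = FALSE)
        ls <- locus_summary(panel, loci,
                            groups = unlist(config$roles[c("P1", "P2")]))
        readr::write_tsv(ls, out_path(config, "locus_summary.tsv"))
        files <- bind_rows(files, tibble(file = "locus_summary.tsv", rows = nrow(ls)))
      }
      files
    }
  )
  outputs
}

#' Run the full scan pipeline
#'
#' Executes the stages in fixed order (filter, windows, introgression,
#' classify, associate), writing every intermediate as a text artifact under
#' `out_dir`, and a `manifest.json` recording the config hash, seed, package
#' version and per-stage output row counts. Rerunning the same config
#' reproduces byte-identical TSV/BED/JSON outputs. A failing stage aborts
#' with the stage name after writing the partial manifest.
#'
#' @param config a [pipeline_config()].
#' @returns The manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    introscan_version = as.character(packageVersion("introscan")),
    stages = list()
  )
  write_manifest <- function() {
    jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  for (stage in pipeline_stages) {
    res <- tryCatch(
      run_stage(config, stage),
      error = function(e) {
        manifest$stages[[stage]] <<- list(status = "error",
                                          message = conditionMessage(e))
        write_manifest()
        abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
      }
    )
    manifest$stages[[stage]] <- list(status = "ok", outputs = res)
    inform(sprintf("[introscan] stage %-13s ok (%s)", stage,
                   paste(sprintf("%s: %d", res$file, res$rows), collapse = ", ")))
  }
  write_manifest()
  invisible(manifest)
}

#' Simulate a ready-to-run fixture directory
#'
#' Emits, under `dir`: the simulated VCF, the sample-to-population TSV, the
#' ground-truth JSON, and a pipeline config JSON pointing at them, so
#' `run_pipeline(read_pipeline_config(file.path(dir, "config.json")))` runs
#' end-to-end on known truth.
#'
#' @param config a [sim_config()].
#' @param dir fixture directory (created).
#' @param ... further arguments to [pipeline_config()] (e.g. `genes`,
#'   `strong_top_fraction`).
#' @returns List: `dir`, `vcf`, `pop_table`, `truth_json`, `config_json`,
#'   `truth`, `panel`, `pipeline_config`.
#' @export
simulate_fixture <- function(config, dir, ...) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_panel(config)
  vcf <- file.path(dir, "panel.vcf")
  pops <- file.path(dir, "population.tsv")
  truth_json <- file.path(dir, "truth.json")
  write_vcf_fixture(sim$panel, vcf)
  write_population_table(sim$panel, pops)
  write_sim_truth(sim$truth, truth_json)
  lens <- setNames(rep(config$chrom_length_bp, config$n_chromosomes),
                   sprintf("chr%d", seq_len(config$n_chromosomes)))
  pc <- pipeline_config(
    vcf = vcf, pop_table = pops,
    roles = c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"),
    out_dir = file.path(dir, "out"),
    chrom_lengths = lens, seed = config$seed, ...
  )
  config_json <- file.path(dir, "config.json")
  write_pipeline_config(pc, config_json)
  list(dir = dir, vcf = vcf, pop_table = pops, truth_json = truth_json,
       config_json = config_json, truth = sim$truth, panel = sim$panel,
       pipeline_config = pc)
}
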