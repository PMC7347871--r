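#' Default pipeline configuration
#'
#' All stage parameters in one list, with the conventional defaults:
#' 200/25 bp skew windows, 10,000 bootstrap replicates, genetic-code
#' table 5, Cq detection cutoff 35, five mitochondria per sperm cell, 95%
#' intervals. When no input paths are supplied the pipeline generates a
#' seeded synthetic bundle covering every stage.
#'
#' @param ... Overrides for any default field. Input paths: `genbank_f`,
#'   `genbank_m` (GenBank flat files), `alignment_files` (named vector of
#'   aligned FASTAs with `|group` headers), `haplotype_files` (named vector
#'   of haplotype FASTAs), `dilutions_file`, `samples_file` (TSV),
#'   `ngs_counts` (list reads_m/reads_f/len_m/len_f).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L, out_dir = NULL,
    window = 200L, step = 25L, neutral_window = 1000L,
    bootstrap_reps = 10000L, code_table = 5L,
    cq_cutoff = 35, n_mito = 5L, ci_level = 0.95,
    theta_per_site = 0.02, n_haplotypes = 18L,
    genbank_f = NULL, genbank_m = NULL, alignment_files = NULL,
    haplotype_files = NULL, dilutions_file = NULL, samples_file = NULL,
    ngs_counts = NULL,
    stages = c("skew", "divergence", "popgen", "quantify", "sperm_model")
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  cfg <- cfg[setdiff(names(cfg), "out_dir")] # parameters only, not placement
  flat <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "=", collapse = ";")
  # small deterministic polynomial hash; no external digest dependency
  h <- 17
  for (b in utf8ToInt(flat)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

write_stage_tsv <- function(df, path, cfg) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", config_hash(cfg), cfg$seed), con)
  write.table(as.data.frame(df), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

require_file <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("%s file not found: %s", what, path))
  }
  path
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes the requested stages in dependency order over the configured
#' inputs (or a seeded synthetic bundle when paths are absent), writes one
#' TSV per stage into `out_dir` — each carrying the config hash and seed in
#' a header comment — and returns the stage results. Any stage error aborts
#' with a message naming the failing input. Identical configs and seeds give
#' byte-identical tables.
#'
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a named list of stage result tibbles/objects.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  out_dir <- cfg$out_dir %||% tempfile("mitodui_report_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  code <- genetic_code(cfg$code_table)
  results <- list()
  synthetic <- is.null(cfg$genbank_f)

  message(sprintf("[mitodui] pipeline seed=%d hash=%s out=%s",
                  cfg$seed, config_hash(cfg), out_dir))

  # --- inputs ---------------------------------------------------------------
  if (synthetic) {
    pair <- simulate_mitogenome_pair(divergence = 0.1,
                                     seed = cfg$seed, code = code)
    genome_f <- pair$genome_f; genome_m <- pair$genome_m
    alignments <- pair$alignments
  } else {
    genome_f <- parse_genbank(require_file(cfg$genbank_f, "F genome"), "F")
    genome_m <- parse_genbank(require_file(cfg$genbank_m, "M genome"), "M")
    alignments <- NULL
    if (!is.null(cfg$alignment_files)) {
      alignments <- lapply(cfg$alignment_files, function(p)
        read_alignment(require_file(p, "alignment")))
      names(alignments) <- names(cfg$alignment_files)
    }
  }

  # --- skew -----------------------------------------------------------------
  if ("skew" %in% cfg$stages) {
    tracks <- list(
      at = windowed_index(genome_f, "AT_skew", cfg$window, cfg$step),
      at_filtered = windowed_index(genome_f, "AT_skew", cfg$window, cfg$step,
                                   site_filter = "second_noncoding"),
      at_neutral = windowed_index(genome_f, "AT_skew", cfg$neutral_window,
                                  cfg$step, site_filter = "neutral"),
      gc = windowed_index(genome_f, "GC_skew", cfg$window, cfg$step),
      gc_neutral = windowed_index(genome_f, "GC_skew", cfg$neutral_window,
                                  cfg$step, site_filter = "neutral"),
      gc_content = windowed_index(genome_f, "GC_content", cfg$window,
                                  cfg$step, relative = TRUE)
    )
    skew_tbl <- list_rbind(imap(tracks, function(tr, nm)
      mutate(as_tibble(tr), track = nm)))
    write_stage_tsv(skew_tbl, file.path(out_dir, "skew_tracks.tsv"), cfg)
    results$skew <- skew_tbl
  }

  # --- divergence -----------------------------------------------------------
  if ("divergence" %in% cfg$stages && !is.null(alignments)) {
    div <- per_gene_divergence(genome_f, genome_m, alignments,
                               bootstrap_reps = min(cfg$bootstrap_reps, 2000L),
                               seed = cfg$seed, code = code)
    write_stage_tsv(div, file.path(out_dir, "divergence.tsv"), cfg)
    results$divergence <- div
  }

  # --- popgen ---------------------------------------------------------------
  if ("popgen" %in% cfg$stages) {
    sets <- if (!is.null(cfg$haplotype_files)) {
      lapply(cfg$haplotype_files, function(p) {
        read_alignment(require_file(p, "haplotype alignment"))
      })
    } else {
      list(ND5 = simulate_haplotypes(cfg$n_haplotypes, 1317,
                                     cfg$theta_per_site, seed = cfg$seed),
           ND6 = simulate_haplotypes(cfg$n_haplotypes, 417,
                                     cfg$theta_per_site, seed = cfg$seed + 1L),
           CYTB = simulate_haplotypes(cfg$n_haplotypes, 663,
                                      cfg$theta_per_site, seed = cfg$seed + 2L))
    }
    rows <- imap(sets, function(hs, nm)
      region_summary(hs, region = nm, code = code,
                     bootstrap_reps = min(cfg$bootstrap_reps, 1000L),
                     seed = cfg$seed))
    rows$concatamer <- region_summary(sets, region = "concatamer", code = code,
                                      bootstrap_reps = min(cfg$bootstrap_reps, 1000L),
                                      seed = cfg$seed)
    popgen_tbl <- list_rbind(unname(rows))
    write_stage_tsv(popgen_tbl, file.path(out_dir, "popgen.tsv"), cfg)
    results$popgen <- popgen_tbl
  }

  # --- quantify + sperm model ----------------------------------------------
  if (any(c("quantify", "sperm_model") %in% cfg$stages)) {
    if (!is.null(cfg$dilutions_file)) {
      dil <- as_tibble(read.delim(require_file(cfg$dilutions_file, "dilutions"),
                                  comment.char = "#"))
      smp <- as_tibble(read.delim(require_file(cfg$samples_file, "samples"),
                                  comment.char = "#"))
    } else {
      sim <- simulate_qpcr_dataset(seed = cfg$seed)
      dil <- sim$dilutions; smp <- sim$samples
      results$qpcr_truth <- sim$truth
    }
    curves <- fit_standard_curves(dil)
    results$curves <- curves
    quants <- quantify_samples(smp, curves, ci_level = cfg$ci_level,
                               cq_cutoff = cfg$cq_cutoff)
    write_stage_tsv(quants, file.path(out_dir, "quantifications.tsv"), cfg)
    results$quantify <- quants
    ratios <- ratio_table(quants, curves, "M_nad1", "F_cox1",
                          ci_level = cfg$ci_level)
    write_stage_tsv(ratios, file.path(out_dir, "mf_ratios.tsv"), cfg)
    results$ratios <- ratios
    if (!is.null(cfg$ngs_counts)) {
      results$ngs <- ngs_ratio(cfg$ngs_counts$reads_m, cfg$ngs_counts$reads_f,
                               cfg$ngs_counts$len_m, cfg$ngs_counts$len_f,
                               ci_level = cfg$ci_level, seed = cfg$seed)
      write_stage_tsv(results$ngs, file.path(out_dir, "ngs_ratio.tsv"), cfg)
    }
    if ("sperm_model" %in% cfg$stages) {
      pts <- sperm_points(quants)
      fit <- fit_sperm_model(pts, ci_level = cfg$ci_level,
                             n_mito = cfg$n_mito)
      results$sperm_fit <- fit
      write_stage_tsv(glance(fit), file.path(out_dir, "sperm_model.tsv"), cfg)
    }
  }

  results$out_dir <- out_dir
  invisible(results)
}
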