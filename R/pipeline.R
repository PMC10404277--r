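#' Default pipeline configuration
#'
#' A single nested list drives [run_pipeline()]; every stage can be toggled
#' and parameterized, and all randomness derives from one root seed with a
#' fixed per-stage offset (simulate +1, RPF sampling +2, luciferase +3), so
#' reruns with the same configuration are byte-identical.
#'
#' @param out_dir Output directory.
#' @param seed Root seed.
#' @return Nested configuration list.
#' @export
default_config <- function(out_dir = "polyte_run", seed = 1L) {
  list(
    out_dir = out_dir,
    seed = as.integer(seed),
    stages = list(simulate = TRUE, normalize = TRUE, te = TRUE, de = TRUE,
                  uorf = TRUE, occupancy = TRUE, reporter = TRUE),
    simulate = list(
      n_genes = 200L,
      utr5_len_range = c(60L, 120L),
      cds_codons_range = c(50L, 150L),
      utr3_len_range = c(30L, 80L),
      uorf_genes = list(contained = "gene0001",
                        overlapping_out_of_frame = "gene0001"),
      replicates = 2L,
      mean_depth = 500,
      dispersion = 0.05,
      n_te_up = 10L, n_te_down = 10L, te_effect = 2,
      n_spikes = 92L,
      rpf_reads = 4000L,
      rpf_region_weights = list(control = c(uORF2 = 0.5, CDS = 0.5),
                                mutant = c(uORF2 = 0.2, CDS = 0.8))
    ),
    normalize = list(min_count = 5L, method = "median_ratio"),
    te = list(pseudocount = 1, te_threshold = 1, rna_threshold = 1,
              combine = "geometric"),
    de = list(fdr_threshold = 0.05, lfc_threshold = 1, pseudocount = 0.5),
    occupancy = list(min_len = 28L, max_len = 32L, mode = "coverage"),
    reporter = list(
      control_id = "NC-psi-check2",
      activities = c(`NC-psi-check2` = 1, `UTR-wt` = 2.5, `UTR-uORF2mut` = 1.8),
      n_replicates = 3L, cv = 0.1
    )
  )
}


stage_header <- function(stage, params) {
  sprintf("# polyte %s | stage=%s | %s",
          as.character(utils::packageVersion("polyte")), stage,
          paste(names(params), unlist(params), sep = "=", collapse = " "))
}

write_stage_tsv <- function(x, path, stage, params) {
  writeLines(stage_header(stage, params), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate counts /
#' transcripts / RPFs, spike-in normalization, TE classification,
#' differential expression, uORF annotation, ribosome-occupancy comparison,
#' reporter statistics — writing TSV outputs plus a JSON run manifest that
#' echoes parameters, seeds and output paths.
#'
#' @param config Configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @return The manifest (invisibly), also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  stage_status <- list()
  log_stage <- function(stage, msg) {
    message(sprintf("[polyte:%s] %s", stage, msg))
  }
  outfile <- function(name) file.path(cfg$out_dir, name)

  state <- new.env(parent = emptyenv())

  if (isTRUE(cfg$stages$simulate)) {
    log_stage("simulate", "generating transcriptome, counts and RPF reads")
    sc <- cfg$simulate
    uorf_spec <- bind_rows(purrr::imap(sc$uorf_genes, function(genes, kind) {
      tibble(gene_id = genes, kind = kind)
    }))
    tx <- generate_transcriptome(
      sc$n_genes, sc$utr5_len_range, sc$cds_codons_range, sc$utr3_len_range,
      uorf_spec = if (nrow(uorf_spec) > 0) uorf_spec else NULL,
      seed = cfg$seed + 1L
    )
    gene_ids <- unique(tx$transcripts$gene_id)
    te_genes <- setdiff(gene_ids, uorf_spec$gene_id)
    te_effects <- c(
      setNames(rep(sc$te_effect, sc$n_te_up), head(te_genes, sc$n_te_up)),
      setNames(rep(-sc$te_effect, sc$n_te_down),
               head(setdiff(te_genes, head(te_genes, sc$n_te_up)),
                    sc$n_te_down))
    )
    design <- simulation_design(
      replicates = sc$replicates, mean_depth = sc$mean_depth,
      dispersion = sc$dispersion, te_effects = te_effects,
      seed = cfg$seed + 1L
    )
    ref <- spikein_reference(sc$n_spikes)
    fc <- generate_fraction_counts(gene_ids, design, ref)

    # occupancy demo transcript: fixed uORF2 geometry (see
    # synthetic_uorf_transcript) so the footprint redistribution is visible
    demo <- synthetic_uorf_transcript(seed = cfg$seed + 1L)
    demo$transcripts$transcript_id <- "uorf_demo.t1"
    demo$transcripts$gene_id <- "uorf_demo"
    demo$features$transcript_id <- "uorf_demo.t1"
    tx$transcripts <- bind_rows(tx$transcripts, demo$transcripts)
    tx$features <- bind_rows(tx$features, demo$features)
    rpf <- purrr::imap(sc$rpf_region_weights, function(w, cond) {
      generate_rpf_reads(demo$transcripts, tx$features, unlist(w),
                         sc$rpf_reads,
                         seed = cfg$seed + 2L +
                           match(cond, names(sc$rpf_region_weights)))
    })

    paths$transcriptome <- write_transcriptome(tx, cfg$out_dir)
    paths$counts <- write_stage_tsv(fc$counts, outfile("counts.tsv"),
      "simulate", list(n_genes = sc$n_genes, depth = sc$mean_depth,
                       dispersion = sc$dispersion, seed = cfg$seed))
    paths$design <- write_table_tsv(fc$design, outfile("library_design.tsv"))
    paths$spikein <- write_table_tsv(ref, outfile("spikein_reference.tsv"))
    for (cond in names(rpf)) {
      paths[[paste0("rpf_", cond)]] <-
        write_rpf_tsv(rpf[[cond]], outfile(paste0("rpf_", cond, ".tsv")))
    }
    state$tx <- tx; state$counts <- fc$counts; state$design <- fc$design
    state$ref <- ref; state$rpf <- rpf
    state$planted_te <- te_effects
    stage_status$simulate <- "ok"
  }

  if (isTRUE(cfg$stages$normalize)) {
    log_stage("normalize", "computing spike-in size factors")
    counts <- state$counts %||% read_counts_tsv(outfile("counts.tsv"))
    ref <- state$ref %||% read_table_tsv(outfile("spikein_reference.tsv"))
    sf <- compute_size_factors(counts, ref,
                               min_count = cfg$normalize$min_count,
                               method = cfg$normalize$method)
    norm <- normalize_counts(counts, sf)
    paths$size_factors <- write_stage_tsv(sf, outfile("size_factors.tsv"),
      "normalize", cfg$normalize)
    paths$norm_counts <- write_stage_tsv(norm, outfile("norm_counts.tsv"),
      "normalize", cfg$normalize)
    state$norm <- norm; state$sf <- sf
    stage_status$normalize <- "ok"
  }

  if (isTRUE(cfg$stages$te)) {
    log_stage("te", "translation-efficiency analysis")
    norm <- state$norm %||%
      read_counts_tsv(outfile("norm_counts.tsv"), integer_counts = FALSE)
    design <- state$design %||% read_table_tsv(outfile("library_design.tsv"))
    te <- te_analysis(norm, design,
                      pseudocount = cfg$te$pseudocount,
                      te_threshold = cfg$te$te_threshold,
                      rna_threshold = cfg$te$rna_threshold,
                      combine = cfg$te$combine)
    paths$te <- write_stage_tsv(
      te[, c("gene_id", "te_control", "te_mutant", "te_log2fc",
             "rna_log2fc", "te_class")],
      outfile("te_results.tsv"), "te", cfg$te)
    state$te <- te
    stage_status$te <- "ok"
  }

  if (isTRUE(cfg$stages$de)) {
    log_stage("de", "negative-binomial differential expression")
    norm <- state$norm %||%
      read_counts_tsv(outfile("norm_counts.tsv"), integer_counts = FALSE)
    design <- state$design %||% read_table_tsv(outfile("library_design.tsv"))
    de <- differential_expression(norm, design,
                                  fdr_threshold = cfg$de$fdr_threshold,
                                  lfc_threshold = cfg$de$lfc_threshold,
                                  pseudocount = cfg$de$pseudocount)
    paths$de <- write_stage_tsv(de, outfile("de_results.tsv"), "de", cfg$de)
    state$de <- de
    stage_status$de <- "ok"
  }

  if (isTRUE(cfg$stages$uorf)) {
    log_stage("uorf", "annotating uORFs")
    tx <- state$tx %||% read_transcriptome(outfile("transcripts.fa"),
                                           outfile("features.gff3"))
    uorfs <- find_uorfs(tx$transcripts)
    paths$uorfs <- write_stage_tsv(uorfs, outfile("uorfs.tsv"), "uorf",
      list(starts = "AUG"))
    state$uorfs <- uorfs
    stage_status$uorf <- "ok"
  }

  if (isTRUE(cfg$stages$occupancy)) {
    log_stage("occupancy", "ribosome-occupancy profiles and comparison")
    tx <- state$tx %||% read_transcriptome(outfile("transcripts.fa"),
                                           outfile("features.gff3"))
    rpf <- state$rpf %||% list(
      control = read_rpf_tsv(outfile("rpf_control.tsv")),
      mutant = read_rpf_tsv(outfile("rpf_mutant.tsv")))
    tid <- unique(rpf[[1]]$transcript_id)[1]
    tr <- tx$transcripts[tx$transcripts$transcript_id == tid, ]
    regions <- tx$features[tx$features$transcript_id == tid, ]
    occ <- purrr::map(rpf, function(r) {
      r %>%
        filter_rpf_by_length(cfg$occupancy$min_len, cfg$occupancy$max_len) %>%
        occupancy_profile(tr, mode = cfg$occupancy$mode)
    })
    reg <- purrr::map(occ, region_occupancy, regions = regions)
    cmp <- compare_occupancy(reg$mutant, reg$control)
    for (cond in names(occ)) {
      paths[[paste0("occupancy_", cond)]] <-
        write_table_tsv(occ[[cond]], outfile(paste0("occupancy_", cond, ".tsv")))
    }
    paths$occupancy_comparison <-
      write_stage_tsv(cmp, outfile("occupancy_comparison.tsv"),
                      "occupancy", cfg$occupancy)
    state$occupancy <- list(profiles = occ, comparison = cmp)
    stage_status$occupancy <- "ok"
  }

  if (isTRUE(cfg$stages$reporter)) {
    log_stage("reporter", "dual-luciferase statistics")
    rc <- cfg$reporter
    wells <- generate_luciferase_table(unlist(rc$activities),
                                       n_replicates = rc$n_replicates,
                                       cv = rc$cv, seed = cfg$seed + 3L)
    rel <- relative_luciferase(wells, rc$control_id)
    tests <- reporter_tests(rel)
    paths$luciferase <- write_table_tsv(wells, outfile("luciferase_wells.tsv"))
    paths$reporter <- write_table_tsv(rel, outfile("reporter_relative.tsv"))
    paths$reporter_tests <- write_stage_tsv(tests, outfile("reporter_tests.tsv"),
      "reporter", list(control = rc$control_id, n = rc$n_replicates))
    state$reporter <- list(relative = rel, tests = tests)
    stage_status$reporter <- "ok"
  }

  manifest <- list(
    tool = "polyte",
    version = as.character(packageVersion("polyte")),
    seed = cfg$seed,
    stages = stage_status,
    parameters = cfg[setdiff(names(cfg), c("out_dir"))],
    outputs = purrr::map(paths, as.character)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(structure(manifest, results = as.list(state)))
}
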