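# End-to-end orchestration: simulate (or load) data, run every analysis
# stage, write tables and a run manifest.

#' Run the analysis pipeline
#'
#' Chains the stages on simulated data with a known history: simulate ->
#' orthology (RBH + multi-copy + synteny filters) -> block chaining ->
#' scaffolding of the draft contigs against the reference -> signed-genome
#' conversion and DCJ distance/scenario -> breakpoint extraction and the
#' random breakage test -> report. All outputs are TSV tables in `outdir`
#' plus a YAML `manifest.yaml` recording the configuration snapshot, seed,
#' stages executed, package version and input digests; stage outputs are
#' pure functions of (config, seed).
#'
#' @param config a [sim_spec()], a list of `sim_spec` arguments, or the
#'   path to a YAML file of them.
#' @param outdir output directory (created; pass `NULL` to skip writing).
#' @param seed integer seed overriding the config's `rng_seed`.
#' @param stages character vector of stages to run, or `"all"`. Stage
#'   names: `simulate`, `orthologs`, `blocks`, `scaffold`, `rearrange`,
#'   `breakpoints`, `report`.
#' @param config_overrides named list overriding individual config fields
#'   (flags beat the config file).
#' @param verbose emit progress messages to stderr.
#' @return invisibly, a list with the stage outputs: `sim`, `pairs`,
#'   `blocks`, `assembly`, `signed`, `distance`, `scenario`, `mcd`,
#'   `breakpoint_regions`, `breakage`, `report`.
#' @export
run_pipeline <- function(config = sim_spec(), outdir = NULL, seed = NULL,
                         stages = "all", config_overrides = NULL,
                         verbose = FALSE) {
  input_digests <- character(0)
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_bad_arg(paste0("config file not found: ", config))
    }
    input_digests <- c(manifest_digest(config))
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "sim_spec")) {
    config <- do.call(sim_spec, config)
  }
  if (!is.null(config_overrides)) {
    config[names(config_overrides)] <- config_overrides
    config <- do.call(sim_spec, unclass(config))
  }
  if (!is.null(seed)) config$rng_seed <- as.integer(seed)
  all_stages <- c("simulate", "orthologs", "blocks", "scaffold",
                  "rearrange", "breakpoints", "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    abort_bad_arg(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  }
  say <- function(...) if (verbose) message("[syntenica] ", ...)
  out <- list(config = config)
  cfg <- analysis_config(rng_seed = config$rng_seed)

  say("simulating (seed ", config$rng_seed, ")")
  sim <- simulate_pair(config, avoid_rearranged_cuts = TRUE)
  out$sim <- sim

  if (any(c("orthologs", "blocks", "scaffold", "rearrange", "breakpoints",
            "report") %in% stages)) {
    say("inferring orthologues")
    pairs <- infer_rbh(sim$hits$ab, sim$hits$ba, cfg$evalue_max) |>
      drop_multicopy(sim$draft_genome$genes, sim$ancestor_genome$genes) |>
      filter_by_synteny(sim$draft_genome$genes, sim$ancestor_genome$genes,
                        cfg$min_neighbors, cfg$window_genes)
    out$pairs <- pairs

    say("chaining anchors into blocks")
    blocks <- chain_anchors(pairs, sim$draft_genome$genes,
                            sim$ancestor_genome$genes,
                            cfg$max_anchor_gap_bp, cfg$min_block_anchors)
    end_labels <- classify_contig_ends(sim$draft_genome$genes,
                                       sim$draft_genome$contigs,
                                       cfg$subtelomere_margin_bp)
    blocks <- classify_blocks(blocks, sim$draft_genome$contigs, end_labels,
                              cfg$gross_min_block_bp,
                              cfg$subtelomere_margin_bp)
    out$blocks <- blocks
    out$end_labels <- end_labels

    say("scaffolding ", nrow(sim$draft_genome$contigs), " contigs")
    candidates <- build_adjacency_graph(
      list(reference = blocks), sim$draft_genome$contigs,
      cfg$max_reference_gap_bp, cfg$subtelomere_margin_bp)
    assembly <- order_contigs(candidates, end_labels,
                              sim$draft_genome$contigs,
                              config$n_chromosomes)
    out$assembly <- assembly

    say("computing rearrangement distance")
    # lift blocks onto the assembled chromosomes first, so that contig
    # fragmentation does not count as rearrangement
    lifted <- lift_blocks_to_assembly(blocks, assembly$assemblies,
                                      sim$draft_genome$contigs)
    signed <- blocks_to_signed_genomes(lifted$blocks, lifted$contigs,
                                       sim$ancestor_genome$contigs)
    out$signed <- signed
    out$distance <- rearrangement_distance(signed$a, signed$b)
    out$scenario <- sort_scenario(signed$a, signed$b)
    gross <- lifted$blocks[blocks$gross, , drop = FALSE]
    gs <- blocks_to_signed_genomes(gross, lifted$contigs,
                                   sim$ancestor_genome$contigs)
    gross_distance <- rearrangement_distance(gs$a, gs$b)
    genome_mb <- sum(sim$ancestor_genome$contigs$length) / 1e6
    out$mcd <- mcd_summary(out$distance, gross_distance,
                           config$n_chromosomes, genome_mb)

    say("breakpoints and random breakage test")
    regions <- find_breakpoints(gross, side = "b") |>
      annotate_breakpoints(sim$ancestor_genome$genes,
                           cfg$breakpoint_margin_bp)
    out$breakpoint_regions <- regions
    seg <- gross$length_bp
    out$breakage <- if (length(seg) >= 5)
      random_breakage_test(seg, cfg$bootstrap_reps,
                           seed = derive_seed(config$rng_seed, "breakage"))
    else NULL

    say("assembling report")
    out$report <- build_report(
      assemblies = assembly$assemblies,
      mcd_summaries = list(draft_vs_reference = out$mcd),
      breakage = if (!is.null(out$breakage))
        list(draft_vs_reference = out$breakage) else NULL)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_pair_table(out$pairs, file.path(outdir, "orthologues.tsv"))
    write_block_table(out$blocks, file.path(outdir, "blocks.tsv"))
    write_assembly(out$assembly$assemblies, file.path(outdir, "assembly.tsv"))
    readr::write_tsv(out$assembly$conflicts,
                     file.path(outdir, "scaffold_conflicts.tsv"))
    write_signed_genome(out$signed$a, file.path(outdir, "genome_a.grimm"))
    write_signed_genome(out$signed$b, file.path(outdir, "genome_b.grimm"))
    readr::write_tsv(out$scenario, file.path(outdir, "scenario.tsv"))
    write_breakpoint_table(out$breakpoint_regions,
                           file.path(outdir, "breakpoints.tsv"))
    if (!is.null(out$breakage)) {
      readr::write_tsv(tidy(out$breakage),
                       file.path(outdir, "breakage_histogram.tsv"))
    }
    write_report(out$report, file.path(outdir, "report"))
    manifest <- list(
      tool = "syntenica",
      version = as.character(utils::packageVersion("syntenica")),
      seed = config$rng_seed,
      stages = stages,
      config = unclass(config)[!vapply(unclass(config), is.function, TRUE)],
      input_digests = as.list(input_digests))
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }
  invisible(out)
}

manifest_digest <- function(path) {
  stats::setNames(as.character(tools::md5sum(path)), basename(path))
}
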