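## cli_orchestration: JSON pipeline configuration, stage runner, run
## manifests.  The exec/muflap script is a thin Rscript over these
## functions; the functions themselves are the tested interface.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "muflap_run",
    genome = NULL,        # FASTA path
    annotations = NULL,   # TSV/GFF3 path
    prophages = NULL,     # JSON path
    reads = NULL,         # FASTA/FASTQ path (phage particles)
    cell_reads = NULL,    # FASTA/FASTQ path (cellular DNA)
    counts = NULL,        # abundance count table TSV
    topology = "circular",
    flap_len = 20L,
    anchor_len = 20L,
    n_bins = 6L,
    alpha = 0.01,
    top_bins = c(1L, 2L),
    low_bins = c(4L, 5L, 6L),
    spot_method = "pooled",
    dedupe = FALSE,
    min_evidence = 1L,
    sim = list()          # sim_config() overrides for the simulate stage
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a JSON file path or a plain list.  Unknown keys are rejected
#' with an error naming them; missing keys are filled with defaults.
#' Validation is idempotent: re-validating a normalized configuration
#' returns it unchanged.
#'
#' @param config JSON file path or named list.
#' @return normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- unclass(config)
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (!is.null(config$sim)) {
    sim_ok <- names(formals(sim_config))
    bad <- setdiff(names(config$sim), sim_ok)
    if (length(bad))
      stop(sprintf("unknown sim key(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
  }
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  num_keys <- c("seed", "flap_len", "anchor_len", "n_bins", "min_evidence")
  for (kk in num_keys) {
    if (!is.numeric(cfg[[kk]]))
      stop(sprintf("configuration key '%s' must be numeric", kk), call. = FALSE)
    cfg[[kk]] <- as.integer(cfg[[kk]])
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  for (pk in c("genome", "annotations", "prophages", "reads", "cell_reads",
               "counts")) {
    if (!is.null(cfg[[pk]]) && !file.exists(cfg[[pk]]))
      stop(sprintf("configuration path '%s' = '%s' does not exist",
                   pk, cfg[[pk]]), call. = FALSE)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

require_inputs <- function(cfg, keys, stage) {
  missing <- keys[vapply(keys, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(missing))
    stop(sprintf("stage '%s' requires configuration key(s): %s",
                 stage, paste(missing, collapse = ", ")),
         call. = FALSE)
}

write_manifest <- function(cfg, stage, inputs, outputs) {
  manifest <- list(
    stage = stage,
    parameters = unclass(cfg)[setdiff(names(cfg),
                                      c("genome", "annotations", "prophages",
                                        "reads", "cell_reads", "counts"))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(md5sum(p)))),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(md5sum(p)))))
  path <- file.path(cfg$out_dir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  path
}

pipeline_stages <- c("simulate", "scan-motifs", "extract-flaps", "ttp",
                     "burst", "detect-induction", "abundance", "ptw")

#' Run one pipeline stage
#'
#' Stages: `simulate` (emit a synthetic lysogen, reads and tables),
#' `scan-motifs`, `extract-flaps`, `ttp`, `burst`, `detect-induction`,
#' `abundance`, `ptw`.  Each stage writes its outputs plus a
#' machine-readable manifest (parameters + input/output md5 checksums)
#' under `config$out_dir`; identical configuration and seed reproduce the
#' outputs byte-for-byte.
#'
#' @param name stage name.
#' @param config a [validate_config()] result (or list/path accepted by it).
#' @return (invisibly) list with `status` (0 on success) and `outputs`.
#' @export
run_stage <- function(name, config = list()) {
  if (!name %in% pipeline_stages)
    stop(sprintf("unknown stage '%s'; stages: %s", name,
                 paste(pipeline_stages, collapse = ", ")), call. = FALSE)
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    name,
    "simulate" = stage_simulate(cfg),
    "scan-motifs" = stage_scan_motifs(cfg),
    "extract-flaps" = stage_extract_flaps(cfg),
    "ttp" = stage_ttp(cfg),
    "burst" = stage_burst(cfg),
    "detect-induction" = stage_detect_induction(cfg),
    "abundance" = stage_abundance(cfg),
    "ptw" = stage_ptw(cfg))
  manifest <- write_manifest(cfg, name, out$inputs, out$outputs)
  invisible(list(status = 0L, outputs = out$outputs, manifest = manifest))
}

stage_simulate <- function(cfg) {
  sc <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  sim <- make_lysogen(sc)
  events <- simulate_replicative_transposition(sim$lysogen, sim$annotations,
                                               sc)
  mols <- simulate_headful_packaging(sim$lysogen, events, sc)
  reads <- simulate_reads(mols, sc)
  d <- cfg$out_dir
  paths <- list(
    genome = file.path(d, "host.fasta"),
    annotations = file.path(d, "annotations.tsv"),
    prophages = file.path(d, "prophages.json"),
    reads = file.path(d, "particle_reads.fastq"),
    truth = file.path(d, "truth.json"))
  write_genome(sim$lysogen$host, paths$genome)
  write_annotations(sim$annotations, paths$annotations)
  write_prophages(sim$lysogen$prophages, paths$prophages)
  write_reads(reads, paths$reads)
  jsonlite::write_json(
    list(mu_site = sim$truth$mu_site, ss_site = sim$truth$ss_site,
         cos_position = sim$truth$cos_position,
         event_positions = events$position,
         n_events = nrow(events)),
    paths$truth, auto_unbox = TRUE, pretty = TRUE)
  list(inputs = character(0), outputs = unlist(paths, use.names = FALSE))
}

load_first_prophage <- function(cfg, mechanism = NULL) {
  pros <- read_prophages(cfg$prophages)
  if (!is.null(mechanism)) {
    mech <- vapply(pros, `[[`, character(1), "mechanism")
    pros <- pros[mech == mechanism]
    if (length(pros) == 0L)
      stop(sprintf("no prophage with mechanism '%s' in %s", mechanism,
                   cfg$prophages), call. = FALSE)
  }
  pros[[1]]
}

stage_scan_motifs <- function(cfg) {
  require_inputs(cfg, c("genome", "annotations"), "scan-motifs")
  g <- read_genome(cfg$genome, topology = cfg$topology)
  ann <- read_annotations(cfg$annotations)
  mt <- motif_count_per_gene(scan_nysrn(g), ann, g)
  out <- file.path(cfg$out_dir, "motif_table.tsv")
  write_motif_table(mt, out)
  list(inputs = c(cfg$genome, cfg$annotations), outputs = out)
}

flap_pipeline <- function(cfg) {
  g <- read_genome(cfg$genome, topology = cfg$topology)
  pro <- load_first_prophage(cfg, "transposition")
  reads <- read_reads(cfg$reads)
  fl <- extract_flaps(reads, pro$genome, flap_len = cfg$flap_len,
                      anchor_len = cfg$anchor_len)
  fl <- map_flaps(fl, g)
  list(genome = g, prophage = pro,
       counts = classify_flaps(fl, pro, dedupe = cfg$dedupe))
}

stage_extract_flaps <- function(cfg) {
  require_inputs(cfg, c("genome", "prophages", "reads"), "extract-flaps")
  res <- flap_pipeline(cfg)
  out <- file.path(cfg$out_dir, "flaps.tsv")
  write_flap_table(res$counts$flaps, out)
  list(inputs = c(cfg$genome, cfg$prophages, cfg$reads), outputs = out)
}

stage_burst <- function(cfg) {
  require_inputs(cfg, c("genome", "prophages", "reads"), "burst")
  res <- flap_pipeline(cfg)
  out <- file.path(cfg$out_dir, "burst.json")
  jsonlite::write_json(list(x = res$counts$x, y = res$counts$y,
                            unmapped = res$counts$unmapped,
                            ambiguous = res$counts$ambiguous,
                            burst = burst_size(res$counts)),
                       out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(inputs = c(cfg$genome, cfg$prophages, cfg$reads), outputs = out)
}

stage_ttp <- function(cfg) {
  require_inputs(cfg, c("genome", "annotations", "prophages", "reads"), "ttp")
  res <- flap_pipeline(cfg)
  ann <- read_annotations(cfg$annotations)
  mt <- motif_count_per_gene(scan_nysrn(res$genome), ann, res$genome)
  rows <- ttp_scores(res$counts$flaps, ann, mt, flap_len = cfg$flap_len)
  binned <- bin_genes(rows, n_bins = cfg$n_bins)
  enr <- category_enrichment(binned, alpha = cfg$alpha)
  spots <- call_spots(enr, top_bins = cfg$top_bins, low_bins = cfg$low_bins,
                      alpha = cfg$alpha, method = cfg$spot_method)
  d <- cfg$out_dir
  outs <- c(file.path(d, "ttp_table.tsv"), file.path(d, "enrichment.tsv"),
            file.path(d, "spot_calls.tsv"))
  write.table(binned, outs[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(enr, outs[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(spots, outs[3], sep = "\t", quote = FALSE, row.names = FALSE)
  list(inputs = c(cfg$genome, cfg$annotations, cfg$prophages, cfg$reads),
       outputs = outs)
}

stage_detect_induction <- function(cfg) {
  require_inputs(cfg, c("genome", "prophages", "cell_reads"),
                 "detect-induction")
  g <- read_genome(cfg$genome, topology = cfg$topology)
  pros <- read_prophages(cfg$prophages)
  reads <- read_reads(cfg$cell_reads)
  reports <- lapply(pros, function(p) {
    rep <- if (p$mechanism == "transposition") {
      detect_mu_induction(reads, p, g, min_evidence = cfg$min_evidence,
                          flap_len = cfg$flap_len,
                          anchor_len = cfg$anchor_len)
    } else {
      sig <- build_attP_junction(p, g)
      detect_integrase_induction(reads, sig, min_evidence = cfg$min_evidence)
    }
    list(prophage_id = rep$prophage_id, mechanism = rep$mechanism,
         evidence_count = rep$evidence_count, induced = rep$induced)
  })
  out <- file.path(cfg$out_dir, "induction.json")
  jsonlite::write_json(reports, out, auto_unbox = TRUE, pretty = TRUE)
  list(inputs = c(cfg$genome, cfg$prophages, cfg$cell_reads), outputs = out)
}

stage_abundance <- function(cfg) {
  require_inputs(cfg, "counts", "abundance")
  tab <- read_count_table(cfg$counts)
  out <- file.path(cfg$out_dir, "abundance.tsv")
  write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(inputs = cfg$counts, outputs = out)
}

stage_ptw <- function(cfg) {
  require_inputs(cfg, "counts", "ptw")
  tab <- read_count_table(cfg$counts)
  pairs <- pair_stations(tab)
  res <- loglog_slope(pairs)
  d <- cfg$out_dir
  outs <- c(file.path(d, "pairs.tsv"), file.path(d, "ptw_results.json"))
  write.table(pairs, outs[1], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_stations = res$n_stations, slope = res$slope,
         ci_low = res$ci[1], ci_high = res$ci[2],
         slope_class = res$slope_class,
         spearman_phage_host = res$spearman_phage_host,
         spearman_vhr_host = res$spearman_vhr_host),
    outs[2], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(inputs = cfg$counts, outputs = outs)
}
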