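test_that("make_lysogen builds a valid polylysogen with its ground truth", {
  sim <- make_lysogen(sim_config(seed = 91))
  lys <- sim$lysogen
  expect_s3_class(lys, "lysogen")
  host <- lys$host$sequence
  mu <- lys$prophages[[1]]
  ss <- lys$prophages[[2]]
  # integrated spans equal the recorded prophage genomes
  expect_equal(substr(host, mu$left + 1, mu$right), mu$genome)
  expect_equal(substr(host, ss$left + 1, ss$right), ss$genome)
  # 5-bp duplication flanks both Mu ends; attP core flanks both SS ends
  expect_equal(substr(host, mu$left - 4, mu$left), mu$target_dup)
  expect_equal(substr(host, mu$right + 1, mu$right + 5), mu$target_dup)
  expect_true(is_nysrn(mu$target_dup))
  a <- nchar(ss$attP)
  expect_equal(substr(host, ss$left - a + 1, ss$left), ss$attP)
  expect_equal(substr(host, ss$right + 1, ss$right + a), ss$attP)
  # genes stay intact and inside the chromosome
  validate_annotations(sim$annotations, lys$host)
  expect_equal(sim$annotations$end - sim$annotations$start,
               rep(sim_config()$gene_length, nrow(sim$annotations)))
  # gene sequences are untouched host sequence (shift bookkeeping correct)
  naive <- sim$truth$naive_genome$sequence
  for (i in c(1, 10, 25, 40)) {
    expect_equal(
      substr(host, sim$annotations$start[i] + 1, sim$annotations$end[i]),
      substr(naive, sim$truth$naive_annotations$start[i] + 1,
             sim$truth$naive_annotations$end[i]))
  }
  # cos planted at the recorded position inside the SS genome
  expect_equal(substr(ss$genome, sim$truth$cos_position + 1,
                      sim$truth$cos_position + nchar(ss$cos)), ss$cos)
})

test_that("simulation is deterministic under seed and errors on tiny genomes", {
  a <- make_lysogen(sim_config(seed = 92))
  b <- make_lysogen(sim_config(seed = 92))
  expect_identical(a$lysogen$host$sequence, b$lysogen$host$sequence)
  expect_identical(a$annotations, b$annotations)
  expect_error(make_lysogen(sim_config(seed = 1, genome_length = 2000L,
                                       n_genes = 40L)),
               "too small")
})

test_that("transposition targets respect weights, support and self-immunity", {
  cfg <- sim_config(seed = 93)
  sim <- make_lysogen(cfg)
  ev <- simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg,
                                           n_events = 2000, replace = TRUE)
  # all events on NYSRN sites
  expect_true(all(is_nysrn(ev$target_dup)))
  sites <- scan_nysrn(sim$lysogen$host)
  expect_true(all(ev$position %in% sites))
  # cold multiplier 0: no events in the cold category
  expect_false(any(ev$category == cfg$cold_category, na.rm = TRUE))
  # self-immunity: nothing inside the resident Mu prophage
  mu <- sim$lysogen$prophages[[1]]
  expect_false(any(ev$position + 5 > mu$left - 5 & ev$position < mu$right + 5))
  # hot category enriched roughly by the multiplier
  mt <- motif_count_per_gene(sites, sim$annotations, sim$lysogen$host)
  per_cat <- function(cat) {
    genes <- sim$annotations$gene_id[sim$annotations$category == cat]
    hits <- sum(ev$gene_id %in% genes)
    motifs <- sum(mt$per_gene$motif_count[mt$per_gene$gene_id %in% genes])
    hits / motifs
  }
  ratio <- per_cat(cfg$hot_category) / per_cat("carbohydrates")
  expect_gt(ratio, 5)
  # without-replacement mode draws distinct sites and checks capacity
  ev2 <- simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg,
                                            n_events = 200)
  expect_false(any(duplicated(ev2$position)))
  expect_error(
    simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg,
                                       n_events = 10^6),
    "exceeds")
})

test_that("preference-free targeting is proportional to NYSRN density", {
  cfg <- sim_config(seed = 94, hot_multiplier = 1, cold_multiplier = 1)
  sim <- make_lysogen(cfg)
  sites <- scan_nysrn(sim$lysogen$host)
  mt <- motif_count_per_gene(sites, sim$annotations, sim$lysogen$host)
  ev <- do.call(rbind, lapply(1:3, function(s)
    simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg,
                                       n_events = 2000, replace = TRUE,
                                       seed = 94 + s)))
  counts <- vapply(sim$annotations$gene_id, function(g)
    sum(ev$gene_id == g, na.rm = TRUE), numeric(1))
  # chi-square goodness of fit against per-gene motif proportions,
  # restricted to genic events
  p <- mt$per_gene$motif_count / sum(mt$per_gene$motif_count)
  keep <- p > 0
  gof <- suppressWarnings(chisq.test(counts[keep], p = p[keep],
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 1e-3)
})

test_that("headful packaging emits one molecule per transposon copy", {
  cfg <- sim_config(seed = 95, n_events = 5)
  sim <- make_lysogen(cfg)
  ev0 <- simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg,
                                            n_events = 0)
  m0 <- simulate_headful_packaging(sim$lysogen, ev0, cfg)
  expect_length(m0, 1)
  expect_equal(names(m0), "original")
  ev <- simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg)
  mols <- simulate_headful_packaging(sim$lysogen, ev, cfg)
  expect_length(mols, 6)
  FC <- cfg$flank_capture
  mu <- sim$lysogen$prophages[[1]]
  expect_true(all(nchar(mols) == 2 * FC + nchar(mu$genome)))
  # six distinct left flaps when sites are distinct
  left_flaps <- substr(mols, FC - 19, FC)
  expect_length(unique(left_flaps), 6)
  # flanks embed the prophage genome between them
  expect_true(all(substr(mols, FC + 1, FC + nchar(mu$genome)) == mu$genome))
})

test_that("read simulation is seeded, covers junctions, and respects lengths", {
  cfg <- sim_config(seed = 96, n_events = 2, depth = 60)
  sim <- make_lysogen(cfg)
  ev <- simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg)
  mols <- simulate_headful_packaging(sim$lysogen, ev, cfg)
  r1 <- simulate_reads(mols, cfg)
  r2 <- simulate_reads(mols, cfg)
  expect_identical(r1, r2)
  expect_true(all(nchar(r1) == cfg$read_length))
  # FASTQ bytes identical under the same seed
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  write_reads(r1, p1); write_reads(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # saturating depth covers every junction: all planted flaps recovered
  pro <- sim$lysogen$prophages[[1]]
  fl <- map_flaps(extract_flaps(r1, pro), sim$lysogen$host)
  got <- unique(fl$host_position)
  expect_true(all(event_flap_positions(ev) %in% got))
  # emitted FASTQ re-parses through the reader
  back <- read_reads(p1)
  expect_identical(unname(back), unname(r1))
})

test_that("metagenome tables follow the planted power law exactly at zero noise", {
  mg <- simulate_metagenome_counts(sim_config(seed = 97,
    metagenome = list(noise_sd = 0, slope = 0.7)))
  res <- loglog_slope(pair_stations(mg$table))
  expect_equal(res$slope, 0.7, tolerance = 1e-9)
  # table is internally consistent with the RPKM formula
  expect_equal(mg$table$rpkm,
               rpkm(mg$table$mapped_reads, mg$table$entity_length,
                    mg$table$sample_size_bp), tolerance = 1e-12)
})
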