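## synthetic_data: seeded, ground-truthed generators emulating the study's
## data at desk scale -- lysogens with Mu-like and integrase-type
## prophages, replicative transposition with planted gene-level target
## preferences, headful-packaged particle molecules, shotgun reads,
## cellular DNA with rare induction events, and paired host/phage
## metagenome abundance tables following a power law.

#' Simulation configuration
#'
#' Collects every tunable of the generator with the defaults used
#' throughout the package's tests.  All randomness flows from `seed`.
#'
#' Category design: genes are assigned to five functional categories.  The
#' designated hot category (`hot_category`, multiplier `hot_multiplier`,
#' default 10) emulates co-resident-prophage/hypothetical genes favoured by
#' Mu-type transposition; the designated cold category (`cold_category`,
#' multiplier `cold_multiplier`, default 0) emulates spared
#' respiration/protein-metabolism genes; every other gene and all
#' intergenic sites carry baseline weight 1.
#'
#' @param seed integer RNG seed.
#' @param genome_length naive chromosome length (bp), default 50000.
#' @param n_genes number of genes, default 40.
#' @param gene_length length of each gene (bp), default 400.
#' @param hot_category,cold_category category labels.
#' @param hot_multiplier,cold_multiplier target-site weight multipliers.
#' @param mu_genome_length,ss_genome_length prophage genome lengths (bp).
#' @param attP_length attachment-core length for the site-specific
#'   prophage, default 15.
#' @param cos cos sequence planted in the site-specific prophage genome
#'   (default: the 19-nt P2-like cos).
#' @param n_events planted replicative-transposition events.
#' @param flank_capture host bp packaged per end (>= 20), default 150.
#' @param read_length,depth,error_rate shotgun-read parameters.
#' @param spi_rate fraction of cellular reads drawn from induction
#'   molecules.
#' @param cell_depth coverage for cellular-DNA simulation, default 100.
#' @param metagenome list: n_stations, slope, log_intercept, noise_sd,
#'   host_log_mean, host_log_sd, host_length, phage_length, sample_size_bp.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 50000L,
                       n_genes = 40L,
                       gene_length = 400L,
                       hot_category = "phage_related",
                       cold_category = "respiration",
                       hot_multiplier = 10,
                       cold_multiplier = 0,
                       mu_genome_length = 5000L,
                       ss_genome_length = 5000L,
                       attP_length = 15L,
                       cos = cos_sites()[["phiD"]],
                       n_events = 5L,
                       flank_capture = 150L,
                       read_length = 300L,
                       depth = 30,
                       error_rate = 0,
                       spi_rate = 0,
                       cell_depth = 100,
                       metagenome = list()) {
  stopifnot(flank_capture >= 20L, n_events >= 0L,
            hot_multiplier >= 0, cold_multiplier >= 0,
            spi_rate >= 0, spi_rate <= 1)
  mg <- modifyList(list(n_stations = 60L, slope = 0.5, log_intercept = 0.5,
                        noise_sd = 0.2, host_log_mean = 0.6,
                        host_log_sd = 0.5, host_length = 3.2e6,
                        phage_length = 38000, sample_size_bp = 1e9),
                   metagenome)
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_genes = n_genes, gene_length = gene_length,
                 hot_category = hot_category, cold_category = cold_category,
                 hot_multiplier = hot_multiplier,
                 cold_multiplier = cold_multiplier,
                 mu_genome_length = mu_genome_length,
                 ss_genome_length = ss_genome_length,
                 attP_length = attP_length, cos = toupper(cos),
                 n_events = n_events, flank_capture = flank_capture,
                 read_length = read_length, depth = depth,
                 error_rate = error_rate, spi_rate = spi_rate,
                 cell_depth = cell_depth, metagenome = mg),
            class = "sim_config")
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## default category assignment: 25% hot, 25% cold, 20% hypothetical,
## remainder split between two neutral categories; order shuffled.
assign_categories <- function(cfg) {
  n <- cfg$n_genes
  n_hot <- round(0.25 * n); n_cold <- round(0.25 * n)
  n_hyp <- round(0.20 * n)
  rest <- n - n_hot - n_cold - n_hyp
  cats <- c(rep(cfg$hot_category, n_hot), rep(cfg$cold_category, n_cold),
            rep("hypothetical", n_hyp),
            rep("carbohydrates", ceiling(rest / 2)),
            rep("membrane_transport", floor(rest / 2)))
  sample(cats)
}

#' Build a synthetic polylysogen with ground truth
#'
#' Generates a uniform-random circular chromosome with non-overlapping,
#' evenly spaced genes; integrates a Mu-like prophage at an intergenic
#' NYSRN site with the 5-bp target duplicated on both sides; and
#' integrates a site-specific prophage at a distinct intergenic locus,
#' taking the resident host sequence there as attB (= attP core), so the
#' integrated form is flanked by one core copy per side (attL/attR).  The
#' site-specific genome carries the configured cos sequence at a recorded
#' position.  [reconstruct_attB_reference()] on the result returns the
#' naive chromosome bit-exactly.
#'
#' @param config a [sim_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return list with `lysogen`, `annotations` (coordinates on the lysogen
#'   chromosome), and `truth` (naive genome, insertion sites, cos
#'   position, naive annotations).
#' @export
make_lysogen <- function(config = sim_config(), seed = NULL) {
  cfg <- config
  set.seed(seed %||% cfg$seed)
  L <- cfg$genome_length
  spacing <- L %/% cfg$n_genes
  if (spacing <= cfg$gene_length + 60L)
    stop("genome too small for the requested genes", call. = FALSE)
  if (L < cfg$mu_genome_length + cfg$ss_genome_length)
    stop("genome too small for the requested prophages", call. = FALSE)
  naive <- random_dna(L)
  offs <- vapply(seq_len(cfg$n_genes), function(i)
    sample.int(spacing - cfg$gene_length - 40L, 1L) + 20L, integer(1))
  starts <- (seq_len(cfg$n_genes) - 1L) * spacing + offs
  ann <- data.frame(gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
                    start = starts, end = starts + cfg$gene_length,
                    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
                    category = assign_categories(cfg),
                    stringsAsFactors = FALSE)
  naive_ann <- ann

  in_gene_zone <- function(pos, width, ann) {
    any(pos + width > ann$start - 25L & pos < ann$end + 25L)
  }

  ## --- Mu-like prophage at an intergenic NYSRN site -----------------------
  margin <- max(60L, min(1000L, L %/% 10L))
  sites <- scan_nysrn(genome_record("naive", naive, "circular"))
  cand <- sites[sites > margin & sites < L - margin]
  cand <- cand[!vapply(cand, in_gene_zone, logical(1), width = 5L, ann = ann)]
  if (length(cand) == 0L) stop("no intergenic NYSRN site available", call. = FALSE)
  p <- cand[sample.int(length(cand), 1L)]
  mu_genome <- random_dna(cfg$mu_genome_length)
  dup5 <- substr(naive, p + 1L, p + 5L)
  chrom <- paste0(substr(naive, 1L, p + 5L), mu_genome,
                  substr(naive, p + 1L, L))
  mu_left <- p + 5L
  mu_right <- mu_left + cfg$mu_genome_length
  shift1 <- cfg$mu_genome_length + 5L
  ann$start <- ann$start + ifelse(ann$start >= p, shift1, 0L)
  ann$end <- ann$end + ifelse(ann$end > p, shift1, 0L)

  ## --- site-specific prophage at a distinct intergenic locus --------------
  a <- cfg$attP_length
  Lc <- nchar(chrom)
  tries <- 0L
  repeat {
    tries <- tries + 1L
    if (tries > 1000L)
      stop("could not place the site-specific prophage", call. = FALSE)
    q <- sample.int(Lc - 2L * margin, 1L) + margin - 1L
    if (in_gene_zone(q, a, ann)) next
    if (q + a > mu_left - 200L && q < mu_right + 200L) next
    attP <- substr(chrom, q + 1L, q + a)
    if (grepl("N", attP, fixed = TRUE)) next
    break
  }
  ss_genome <- random_dna(cfg$ss_genome_length)
  cos_pos <- sample.int(cfg$ss_genome_length - nchar(cfg$cos) - 200L, 1L) + 100L
  substr(ss_genome, cos_pos + 1L, cos_pos + nchar(cfg$cos)) <- cfg$cos
  chrom <- paste0(substr(chrom, 1L, q + a), ss_genome,
                  substr(chrom, q + 1L, Lc))
  ss_left <- q + a
  ss_right <- ss_left + cfg$ss_genome_length
  shift2 <- cfg$ss_genome_length + a
  ann$start <- ann$start + ifelse(ann$start >= q, shift2, 0L)
  ann$end <- ann$end + ifelse(ann$end > q, shift2, 0L)
  if (q < mu_left) { mu_left <- mu_left + shift2; mu_right <- mu_right + shift2 }

  host <- genome_record("synthetic_host", chrom, "circular")
  mu <- prophage_record("phiMu_sim", host$id, mu_left, mu_right,
                        "transposition", mu_genome, target_dup = dup5)
  ss <- prophage_record("phiSS_sim", host$id, ss_left, ss_right,
                        "site_specific", ss_genome, attP = attP,
                        cos = cfg$cos)
  lys <- lysogen(host, list(mu, ss))
  list(lysogen = lys, annotations = ann,
       truth = list(naive_genome = genome_record("synthetic_host", naive,
                                                 "circular"),
                    naive_annotations = naive_ann,
                    mu_site = p, mu_target_dup = dup5, ss_site = q,
                    attP = attP, cos_position = cos_pos))
}

## per-site transposition weights on the lysogen chromosome
site_weights <- function(sites, lys, annotations, cfg) {
  mult <- setNames(rep(1, nrow(annotations)), annotations$gene_id)
  mult[annotations$category == cfg$hot_category] <- cfg$hot_multiplier
  mult[annotations$category == cfg$cold_category] <- cfg$cold_multiplier
  gene_of <- rep(NA_character_, length(sites))
  for (i in seq_len(nrow(annotations))) {
    inside <- sites >= annotations$start[i] &
      sites + 5L <= annotations$end[i]
    gene_of[inside] <- annotations$gene_id[i]
  }
  w <- ifelse(is.na(gene_of), 1, mult[gene_of])
  ## self-immunity: no transposition into the resident Mu-like prophage
  for (p in lys$prophages) {
    if (p$mechanism != "transposition") next
    span0 <- p$left - nchar(p$target_dup)
    span1 <- p$right + nchar(p$target_dup)
    w[sites + 5L > span0 & sites < span1] <- 0
  }
  list(w = as.numeric(w), gene_of = gene_of)
}

#' Simulate replicative transposition with planted target preferences
#'
#' Draws `n_events` NYSRN target sites on the lysogen chromosome with
#' probability proportional to the containing gene's multiplier (hot x10,
#' cold x0, baseline 1; intergenic sites weight 1).  Sites inside the
#' resident Mu-like prophage have weight 0 (transposition immunity).
#' `replace = FALSE` (default) draws distinct sites so the burst identity
#' 1 + n is exact; `replace = TRUE` preserves the planted rate ratios when
#' `n_events` approaches the number of available sites (the regime of the
#' TTP analysis, where a 3-Mb chromosome's events are emulated on a 50-kb
#' one).
#'
#' @param lys a [lysogen()] from [make_lysogen()].
#' @param annotations gene annotations on the lysogen chromosome.
#' @param config a [sim_config()].
#' @param n_events number of events (default `config$n_events`).
#' @param replace draw with replacement?
#' @param seed optional seed overriding `config$seed`.
#' @return data.frame (one row per event): position (0-based NYSRN start),
#'   target_dup, gene_id (NA if intergenic), category,
#'   left_flank/right_flank (20-nt planted flap sequences).
#' @export
simulate_replicative_transposition <- function(lys, annotations,
                                               config = sim_config(),
                                               n_events = NULL,
                                               replace = FALSE,
                                               seed = NULL) {
  cfg <- config
  set.seed(seed %||% cfg$seed)
  n_events <- n_events %||% cfg$n_events
  chrom <- lys$host$sequence
  sites <- scan_nysrn(lys$host)
  sw <- site_weights(sites, lys, annotations, cfg)
  avail <- sum(sw$w > 0)
  if (!replace && n_events > avail)
    stop(sprintf("n_events (%d) exceeds the %d available weighted sites",
                 n_events, avail), call. = FALSE)
  if (n_events == 0L) {
    return(data.frame(position = integer(0), target_dup = character(0),
                      gene_id = character(0), category = character(0),
                      left_flank = character(0), right_flank = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- sample.int(length(sites), n_events, replace = replace, prob = sw$w)
  pos <- sites[idx]
  gid <- sw$gene_of[idx]
  cat_of <- annotations$category[match(gid, annotations$gene_id)]
  data.frame(
    position = pos,
    target_dup = vapply(pos, function(p) cstr(chrom, p, 5L), character(1)),
    gene_id = gid,
    category = ifelse(is.na(gid), NA_character_, cat_of),
    left_flank = vapply(pos, function(p) cstr(chrom, p + 5L - 20L, 20L),
                        character(1)),
    right_flank = vapply(pos, function(p) cstr(chrom, p, 20L), character(1)),
    stringsAsFactors = FALSE)
}

#' Planted new-flap start positions for a set of transposition events
#'
#' Each event at NYSRN site `p` plants an L flap occupying
#' `[p + dup_len - flap_len, p + dup_len)` (ending at the duplicated
#' target) and an R flap occupying `[p, p + flap_len)`.
#'
#' @param events data.frame from [simulate_replicative_transposition()].
#' @param flap_len flap length, default 20.
#' @param dup_len target-duplication length, default 5.
#' @return integer vector of 0-based flap start positions (2 per event).
#' @export
event_flap_positions <- function(events, flap_len = 20L, dup_len = 5L) {
  as.integer(c(events$position + dup_len - flap_len, events$position))
}

#' Simulate headful packaging of Mu-like particles
#'
#' One packaged molecule per transposon copy: the original locus plus each
#' replicative-transposition event, each molecule `flank_capture` nt of
#' host context + prophage genome + `flank_capture` nt of host context.
#' Molecule count = n_events + 1 (each mature particle corresponds to one
#' transposon copy).
#'
#' @param lys a [lysogen()].
#' @param events event data.frame (may have 0 rows).
#' @param config a [sim_config()] (uses `flank_capture`).
#' @param prophage which resident prophage is packaged (default: the first
#'   transposition-type one).
#' @return named character vector of molecules
#'   (`"original"`, `"event_001"`, ...).
#' @export
simulate_headful_packaging <- function(lys, events, config = sim_config(),
                                       prophage = NULL) {
  cfg <- config
  if (is.null(prophage)) {
    mech <- vapply(lys$prophages, `[[`, character(1), "mechanism")
    prophage <- lys$prophages[[which(mech == "transposition")[1]]]
  }
  chrom <- lys$host$sequence
  FC <- cfg$flank_capture
  mol <- c(original = paste0(cstr(chrom, prophage$left - FC, FC),
                             prophage$genome,
                             cstr(chrom, prophage$right, FC)))
  if (nrow(events) > 0L) {
    ev <- vapply(seq_len(nrow(events)), function(i) {
      p <- events$position[i]
      paste0(cstr(chrom, p + 5L - FC, FC), prophage$genome, cstr(chrom, p, FC))
    }, character(1))
    names(ev) <- sprintf("event_%03d", seq_len(nrow(events)))
    mol <- c(mol, ev)
  }
  mol
}

## substitution-only error model: mutate each base independently
apply_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  widths <- nchar(reads)
  nerr <- rbinom(length(reads), widths, error_rate)
  for (i in which(nerr > 0L)) {
    pos <- sample.int(widths[i], nerr[i])
    ch <- strsplit(reads[[i]], "", fixed = TRUE)[[1]]
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    reads[[i]] <- paste0(ch, collapse = "")
  }
  reads
}

#' Simulate shotgun reads from molecules
#'
#' Uniform fragment starts at the stated depth, per-base substitution
#' errors at `error_rate`, no indels (the downstream pipeline is
#' exact-match, so indels would be pure noise).  Deterministic under seed.
#'
#' @param molecules named character vector of template molecules.
#' @param config a [sim_config()] (read_length, depth, error_rate).
#' @param seed optional seed overriding `config$seed`.
#' @return named character vector of reads.
#' @export
simulate_reads <- function(molecules, config = sim_config(), seed = NULL) {
  cfg <- config
  set.seed(seed %||% cfg$seed)
  rl <- cfg$read_length
  out <- list()
  for (i in seq_along(molecules)) {
    m <- molecules[[i]]
    Lm <- nchar(m)
    if (Lm < rl)
      stop("read_length exceeds molecule length", call. = FALSE)
    nr <- max(1L, ceiling(cfg$depth * Lm / rl))
    starts <- sample.int(Lm - rl + 1L, nr, replace = TRUE)
    rd <- substring(m, starts, starts + rl - 1L)
    names(rd) <- sprintf("%s_r%05d", names(molecules)[i], seq_len(nr))
    out[[i]] <- rd
  }
  reads <- unlist(out)
  apply_errors(reads, cfg$error_rate)
}

#' Simulate cellular DNA from a lysogen with rare induction events
#'
#' Emits shotgun reads of the lysogen chromosome at `cell_depth`; each
#' read is drawn, with probability `spi_rate`, from an induction molecule
#' instead: for the Mu-like prophage a replicative-transposition junction
#' molecule at a random permitted NYSRN site, for the site-specific
#' prophage the excised circle (genome + attP, circular, i.e. every
#' rotation including the L-attP-R junction).  `spi_rate = 0` is the
#' negative control: no induction molecules, so both detectors must report
#' zero evidence.
#'
#' @param sim a [make_lysogen()] result (lysogen + annotations).
#' @param config a [sim_config()] (cell_depth, read_length, error_rate,
#'   spi_rate).
#' @param seed optional seed overriding `config$seed`.
#' @return list: `reads` (named character vector), `truth` (n_induced per
#'   mechanism, drawn Mu target sites).
#' @export
simulate_cellular_dna <- function(sim, config = sim_config(), seed = NULL) {
  cfg <- config
  set.seed(seed %||% cfg$seed)
  lys <- sim$lysogen
  chrom <- lys$host$sequence
  Lc <- nchar(chrom)
  rl <- cfg$read_length
  FC <- cfg$flank_capture
  mech <- vapply(lys$prophages, `[[`, character(1), "mechanism")
  mu <- if (any(mech == "transposition"))
    lys$prophages[[which(mech == "transposition")[1]]] else NULL
  ss <- if (any(mech == "site_specific"))
    lys$prophages[[which(mech == "site_specific")[1]]] else NULL

  sites <- scan_nysrn(lys$host)
  sw <- site_weights(sites, lys, sim$annotations, cfg)
  ok_sites <- sites[sw$w > 0]
  circle <- if (!is.null(ss)) paste0(ss$genome, ss$attP) else NULL

  n_reads <- max(1L, round(cfg$cell_depth * Lc / rl))
  src <- runif(n_reads) < cfg$spi_rate
  mechs_avail <- c(if (!is.null(mu)) "mu", if (!is.null(ss)) "ss")
  reads <- character(n_reads)
  mu_sites_drawn <- integer(0)
  n_induced <- c(mu = 0L, ss = 0L)
  ## chromosomal reads (circular, uniform starts)
  chrom_idx <- which(!src)
  if (length(chrom_idx)) {
    starts <- sample.int(Lc, length(chrom_idx), replace = TRUE) - 1L
    ext <- paste0(chrom, substr(chrom, 1L, rl))  # circular wrap
    reads[chrom_idx] <- substring(ext, starts + 1L, starts + rl)
  }
  ## an induced transposed copy lies in full chromosomal context, so its
  ## simulated molecule carries at least one read length of host flank
  ## (flank_capture only limits *packaged* particles)
  cell_flank <- max(FC, rl)
  for (i in which(src)) {
    mchoice <- sample(mechs_avail, 1L)
    if (mchoice == "mu") {
      p <- ok_sites[sample.int(length(ok_sites), 1L)]
      mol <- paste0(cstr(chrom, p + 5L - cell_flank, cell_flank), mu$genome,
                    cstr(chrom, p, cell_flank))
      s <- sample.int(nchar(mol) - rl + 1L, 1L)
      reads[i] <- substr(mol, s, s + rl - 1L)
      mu_sites_drawn <- c(mu_sites_drawn, p)
      n_induced["mu"] <- n_induced["mu"] + 1L
    } else {
      s <- sample.int(nchar(circle), 1L) - 1L
      reads[i] <- cstr(circle, s, rl)
      n_induced["ss"] <- n_induced["ss"] + 1L
    }
  }
  names(reads) <- sprintf("cell_r%06d", seq_len(n_reads))
  reads <- apply_errors(reads, cfg$error_rate)
  list(reads = reads,
       truth = list(n_induced = n_induced, mu_sites = mu_sites_drawn))
}

#' Simulate reads from cos-cut packaged genomes (terminus pile-up)
#'
#' Models a population of virion genomes, each the phage circle (genome +
#' attP for integrase-type phages) linearized at the cos cut site.  Each
#' copy is fragmented at random breakpoints; every fragment yields a
#' forward read from its left end and a reverse-complement read from its
#' right end.  Because every molecule's outermost fragments end exactly at
#' the cos cut, read 5' starts pile up there -- the signal
#' [detect_termini()] looks for.
#'
#' @param prophage a [prophage_record()] with a `cos` sequence.
#' @param n_genomes number of packaged genome copies, default 400.
#' @param mean_frag mean fragment length (bp), default 800.
#' @param read_length read length, default 150.
#' @param seed RNG seed.
#' @return list: `reads`, `circle` (the reference [genome_record()], with
#'   circular topology), `cut_position` (0-based cos cut site on the
#'   circle).
#' @export
simulate_packaged_termini <- function(prophage, n_genomes = 400L,
                                      mean_frag = 800L, read_length = 150L,
                                      seed = 1L) {
  set.seed(seed)
  stopifnot(inherits(prophage, "prophage_record"), !is.null(prophage$cos))
  circle <- paste0(prophage$genome,
                   if (!is.null(prophage$attP)) prophage$attP else "")
  m <- gregexpr(prophage$cos, circle, fixed = TRUE)[[1]]
  if (m[1] == -1L || length(m) != 1L)
    stop("cos sequence must occur exactly once on the phage circle",
         call. = FALSE)
  cut <- as.integer(m[1]) - 1L
  Lc <- nchar(circle)
  linear <- cstr(circle, cut, Lc)
  reads <- list()
  for (g in seq_len(n_genomes)) {
    nb <- rpois(1L, Lc / mean_frag)
    bp <- sort(unique(if (nb > 0) sample.int(Lc - 1L, min(nb, Lc - 1L)) else
      integer(0)))
    bounds <- c(0L, bp, Lc)
    for (f in seq_len(length(bounds) - 1L)) {
      a <- bounds[f]; b <- bounds[f + 1L]
      if (b - a < 20L) next
      fwd <- substr(linear, a + 1L, min(a + read_length, b))
      rev <- revcomp(substr(linear, max(b - read_length + 1L, a + 1L), b))
      reads[[length(reads) + 1L]] <- c(fwd, rev)
    }
  }
  reads <- unlist(reads)
  names(reads) <- sprintf("frag_r%06d", seq_along(reads))
  list(reads = reads,
       circle = genome_record(paste0(prophage$id, "_circle"), circle,
                              "circular"),
       cut_position = cut)
}

#' Simulate paired host/phage metagenome abundance tables
#'
#' Per station, host log10 abundance is drawn from a normal; phage log10
#' abundance follows the power law `log10(phage) = log_intercept +
#' slope * log10(host) + Normal(0, noise_sd)`.  Abundances are emitted as
#' a count table consistent with the RPKM formula (mapped read mass is
#' real-valued so the emitted table reproduces the drawn abundances
#' exactly; with `noise_sd = 0` the fitted slope equals `slope` to
#' machine precision).  Hosts are measured in the cellular fraction,
#' prophages in the virion fraction.
#'
#' @param config a [sim_config()] (uses `metagenome`).
#' @param seed optional seed overriding `config$seed`.
#' @return list: `table` (count table as in [read_count_table()], with
#'   rpkm), `true_slope`.
#' @export
simulate_metagenome_counts <- function(config = sim_config(), seed = NULL) {
  cfg <- config$metagenome
  set.seed(seed %||% config$seed)
  if (cfg$n_stations < 3L) stop("need n_stations >= 3", call. = FALSE)
  hl <- rnorm(cfg$n_stations, cfg$host_log_mean, cfg$host_log_sd)
  pl <- cfg$log_intercept + cfg$slope * hl + rnorm(cfg$n_stations, 0, cfg$noise_sd)
  host_rpkm <- 10^hl
  phage_rpkm <- 10^pl
  stations <- sprintf("station_%03d", seq_len(cfg$n_stations))
  mk <- function(fraction, entity_id, entity_type, rp, len) {
    data.frame(sample_id = paste0(stations, "_", fraction),
               station = stations, fraction = fraction,
               entity_id = entity_id, entity_type = entity_type,
               mapped_reads = rp * (len / 1e3) * (cfg$sample_size_bp / 1e6),
               entity_length = len, sample_size_bp = cfg$sample_size_bp,
               rpkm = rp, stringsAsFactors = FALSE)
  }
  tab <- rbind(mk("cellular", "host_sim", "host", host_rpkm, cfg$host_length),
               mk("virion", "phage_sim", "prophage", phage_rpkm,
                  cfg$phage_length))
  rownames(tab) <- NULL
  list(table = tab, true_slope = cfg$slope)
}
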