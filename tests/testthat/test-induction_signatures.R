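test_that("attP junction is R-terminus + attP + L-terminus", {
  ss <- toy_ss_lysogen()
  pro <- ss$lysogen$prophages[[1]]
  sig <- build_attP_junction(pro, ss$lysogen$host)
  expect_equal(sig$junction_sequence,
               paste0(substr(ss$SS, nchar(ss$SS) - 19, nchar(ss$SS)),
                      ss$attP, substr(ss$SS, 1, 20)))
  expect_gt(length(sig$signature_kmers), 0)
  # every signature k-mer spans the full attP and is chromosome-free
  chrom <- ss$lysogen$host$sequence
  for (km in sig$signature_kmers) {
    expect_true(grepl(km, sig$junction_sequence, fixed = TRUE))
    expect_false(grepl(km, chrom, fixed = TRUE))
    expect_false(grepl(revcomp(km), chrom, fixed = TRUE))
  }
  # k-mers that stop exactly at an attP boundary also occur at attL/attR on
  # the chromosome and must have been screened out
  a <- nchar(ss$attP)
  attR_window <- paste0(substr(ss$SS, nchar(ss$SS) - (20 - a) + 1,
                               nchar(ss$SS)), ss$attP)   # ends at attP end
  attL_window <- paste0(ss$attP, substr(ss$SS, 1, 20 - a)) # starts at attP
  expect_false(attR_window %in% sig$signature_kmers)
  expect_false(attL_window %in% sig$signature_kmers)
})

test_that("degenerate signatures warn and the detector refuses them", {
  # host that contains the whole junction (prophage copy elsewhere):
  set.seed(61)
  SS <- rand_dna(200)
  attP <- "ACGTACGTACGT"
  junction_context <- paste0(substr(SS, 181, 200), attP, substr(SS, 1, 20))
  host_seq <- paste0(rand_dna(200), attP, SS, attP, rand_dna(50),
                     junction_context, rand_dna(50))
  host <- genome_record("h", host_seq, "linear")
  pro <- prophage_record("p", "h", 212, 412, "site_specific", SS, attP = attP)
  expect_warning(sig <- build_attP_junction(pro, host), "re-occurs")
  expect_length(sig$signature_kmers, 0)
  expect_error(detect_integrase_induction(c(r = rand_dna(100)), sig), "empty")
})

test_that("integrase detector counts junction-bearing reads only", {
  ss <- toy_ss_lysogen()
  pro <- ss$lysogen$prophages[[1]]
  host <- ss$lysogen$host
  sig <- build_attP_junction(pro, host)
  # negative control: reads copied from the chromosome itself
  set.seed(62)
  starts <- sample.int(nchar(host$sequence) - 100, 50)
  neg <- substring(host$sequence, starts, starts + 99)
  names(neg) <- sprintf("n%02d", seq_along(neg))
  rep_neg <- detect_integrase_induction(neg, sig)
  expect_equal(rep_neg$evidence_count, 0)
  expect_false(rep_neg$induced)
  # one read copied from the junction molecule (and one reversed)
  pos <- c(neg, j1 = sig$junction_sequence,
           j2 = revcomp(sig$junction_sequence))
  rep_pos <- detect_integrase_induction(pos, sig)
  expect_equal(rep_pos$evidence_count, 2)
  expect_true(rep_pos$induced)
})

test_that("Mu detector counts new flaps and ignores the native locus", {
  toy <- toy_mu_lysogen()
  pro <- toy$lysogen$prophages[[1]]
  host <- toy$lysogen$host
  native_span <- paste0(substr(host$sequence, pro$left - 29, pro$left),
                        substr(pro$genome, 1, 40))
  rep0 <- detect_mu_induction(c(r = native_span), pro, host)
  expect_equal(rep0$evidence_count, 0)
  expect_false(rep0$induced)
  # a transposed junction: distal host 20-mer + prophage start
  transposed <- paste0(substr(toy$X, 101, 130), substr(pro$genome, 1, 40))
  rep1 <- detect_mu_induction(c(r = native_span, t = transposed), pro, host)
  expect_equal(rep1$evidence_count, 1)
  expect_true(rep1$induced)
})

test_that("the two detectors are mechanism-independent on mixtures", {
  cfg <- sim_config(seed = 63, spi_rate = 0.01, cell_depth = 60)
  sim <- make_lysogen(cfg)
  mu <- sim$lysogen$prophages[[1]]
  ss <- sim$lysogen$prophages[[2]]
  sig <- build_attP_junction(ss, sim$lysogen$host)
  # integrase-only induction must not trigger the Mu detector and vice versa
  circle <- paste0(ss$genome, ss$attP)
  set.seed(64)
  s0 <- sample.int(nchar(circle), 300, replace = TRUE) - 1L
  ss_reads <- vapply(s0, function(s) {
    paste0(substr(paste0(circle, circle), s + 1, s + 300))
  }, character(1))
  names(ss_reads) <- sprintf("ss%03d", seq_along(ss_reads))
  expect_equal(detect_mu_induction(ss_reads, mu,
                                   sim$lysogen$host)$evidence_count, 0)
  expect_gt(detect_integrase_induction(ss_reads, sig)$evidence_count, 0)

  ev <- simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg,
                                           n_events = 3)
  mols <- simulate_headful_packaging(sim$lysogen, ev, cfg)
  mu_reads <- simulate_reads(mols, sim_config(seed = 65, depth = 10))
  expect_equal(detect_integrase_induction(mu_reads, sig)$evidence_count, 0)
  expect_gt(detect_mu_induction(mu_reads, mu,
                                sim$lysogen$host)$evidence_count, 0)
})

test_that("read-start histogram locates 5' ends on both strands", {
  g <- genome_record("g", rand_dna(500, seed = 66), "circular")
  fwd_read <- substr(g$sequence, 101, 180)      # 5' at 100, strand +
  rev_read <- revcomp(substr(g$sequence, 201, 280))  # 5' at 279, strand -
  h <- read_start_histogram(c(a = fwd_read, b = rev_read, c = fwd_read), g)
  expect_equal(h$count[h$position == 100 & h$strand == "+"], 2L)
  expect_equal(h$count[h$position == 279 & h$strand == "-"], 1L)
})

test_that("terminus detection: uniform starts give none, pile-ups are found", {
  uniform <- data.frame(position = 0:99, strand = "+",
                        count = rep(5L, 100))
  expect_equal(nrow(detect_termini(uniform)$candidates), 0)
  peak <- rbind(uniform,
                data.frame(position = 42, strand = "+", count = 1000L))
  res <- detect_termini(peak)
  expect_equal(res$candidates$position, 42)   # 1000 >= 20 * median 5
  expect_equal(nrow(detect_termini(
    data.frame(position = integer(0), strand = character(0),
               count = integer(0)))$candidates), 0)
})

test_that("cos-cut genome populations reveal the planted cut site", {
  sim <- make_lysogen(sim_config(seed = 67))
  ss <- sim$lysogen$prophages[[2]]
  tm <- simulate_packaged_termini(ss, seed = 68)
  h <- read_start_histogram(tm$reads, tm$circle)
  res <- detect_termini(h, genome_length = nchar(tm$circle$sequence))
  expect_true(tm$cut_position %in% res$candidates$position)
  expect_true(tm$cut_position %in% res$cos_pairs$cut_position)
})

test_that("spontaneous induction: evidence appears at spi > 0, never at 0", {
  sim <- make_lysogen(sim_config(seed = 69))
  mu <- sim$lysogen$prophages[[1]]
  ss <- sim$lysogen$prophages[[2]]
  sig <- build_attP_junction(ss, sim$lysogen$host)
  cfg_pos <- sim_config(seed = 70, spi_rate = 0.05, cell_depth = 40)
  cd <- simulate_cellular_dna(sim, cfg_pos)
  expect_gt(detect_mu_induction(cd$reads, mu, sim$lysogen$host)$evidence_count, 0)
  expect_gt(detect_integrase_induction(cd$reads, sig)$evidence_count, 0)
  for (seed in 71:73) {
    cd0 <- simulate_cellular_dna(sim, sim_config(seed = seed, spi_rate = 0,
                                                 cell_depth = 20))
    expect_equal(detect_mu_induction(cd0$reads, mu,
                                     sim$lysogen$host)$evidence_count, 0)
    expect_equal(detect_integrase_induction(cd0$reads, sig)$evidence_count, 0)
  }
})
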