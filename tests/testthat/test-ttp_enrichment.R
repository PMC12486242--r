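make_scored <- function(scores, motifs = NULL, cats = NULL) {
  n <- length(scores)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             category = cats %||% rep("hypothetical", n),
             gene_length = 400L,
             flap_hits = NA_integer_,
             motif_count = motifs %||% rep(4L, n),
             ttp_score = scores,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TTP scores are flap hits over motif counts, motif-free genes excluded", {
  g <- genome_record("g", rand_dna(3000, seed = 41), "linear")
  ann <- data.frame(gene_id = c("a", "b"), start = c(0L, 1000L),
                    end = c(600L, 1600L), strand = "+",
                    category = c("x", "y"))
  mt <- motif_count_per_gene(scan_nysrn(g), ann, g)
  # 8 flap windows fully inside gene a
  pos <- rep(c(10L, 40L, 80L, 120L), 2)
  rows <- ttp_scores(pos, ann, mt)
  a <- rows[rows$gene_id == "a", ]
  expect_equal(a$flap_hits, 8L)
  expect_equal(a$ttp_score, 8 / a$motif_count)
  # force a zero-motif gene via masking
  g2 <- mask_regions(g, data.frame(start = 1000L, end = 1600L))
  mt2 <- motif_count_per_gene(scan_nysrn(g2), ann, g2)
  rows2 <- ttp_scores(pos, ann, mt2)
  expect_false("b" %in% rows2$gene_id)
  expect_equal(attr(rows2, "unscored")$gene_id, "b")
  expect_error(ttp_scores(pos, ann[0, ], mt), "empty")
})

test_that("flap crediting uses full 20-nt containment", {
  g <- genome_record("g", rand_dna(500, seed = 42), "linear")
  ann <- data.frame(gene_id = "a", start = 100L, end = 200L, strand = "+",
                    category = "x")
  mt <- motif_count_per_gene(scan_nysrn(g), ann, g)
  rows <- ttp_scores(c(100L, 180L, 181L, 99L), ann, mt)  # [181,201) leaks out
  expect_equal(rows$flap_hits, 2L)
})

test_that("ranking and binning: remainder rule, ties, scale invariance", {
  rows <- make_scored(scores = 12:1)
  b <- bin_genes(rows, n_bins = 6)
  expect_equal(as.vector(table(b$bin)), rep(2L, 6))
  expect_equal(b$gene_id[b$bin == 1], c("g001", "g002"))

  rows13 <- make_scored(scores = 13:1)
  b13 <- bin_genes(rows13, n_bins = 6)
  expect_equal(as.vector(table(b13$bin)), c(3L, 2L, 2L, 2L, 2L, 2L))

  # all-equal scores: deterministic tie-break, identical across runs
  tied <- make_scored(scores = rep(1, 12), motifs = rep(c(5L, 2L), 6))
  t1 <- bin_genes(tied); t2 <- bin_genes(tied)
  expect_identical(t1, t2)
  expect_true(all(t1$motif_count[t1$bin <= 3] == 5L))

  # multiplying flap hits by 7 rescales scores but preserves ranks and bins
  r1 <- bin_genes(make_scored(scores = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10, 11, 12)))
  r7 <- bin_genes(make_scored(scores = 7 * c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10, 11, 12)))
  expect_equal(r1$gene_id, r7$gene_id)
  expect_equal(r1$bin, r7$bin)

  expect_error(bin_genes(make_scored(scores = 1:5), n_bins = 6), "at least")
})

test_that("hypergeometric tails match exhaustive enumeration (N <= 25)", {
  worst <- 0
  for (N in c(2:25)) {
    for (K in 0:N) {
      for (m in 0:N) {
        ks <- max(0L, K + m - N):min(K, m)
        for (k in ks) {
          o <- oracle_hyper_tails(N, K, m, k)
          pe <- phyper(k - 1, K, N - K, m, lower.tail = FALSE)
          pd <- phyper(k, K, N - K, m)
          worst <- max(worst, abs(pe - o$enrich), abs(pd - o$deplete))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("worked enrichment cells and the tail identity reproduce", {
  rows <- make_scored(scores = 20:1,
                      cats = c(rep("A", 5), rep("B", 15)))
  b <- bin_genes(rows, n_bins = 4)   # bins of 5; all A genes in bin 1
  enr <- category_enrichment(b, alpha = 0.01)
  cell <- enr[enr$category == "A" & enr$bin == 1, ]
  expect_equal(cell$k, 5L)
  expect_equal(cell$p_enrich, 1 / 15504, tolerance = 1e-12)  # C(20,5) worked case
  low <- enr[enr$category == "A" & enr$bin == 4, ]
  expect_equal(low$k, 0L)
  expect_equal(low$p_deplete, 3003 / 15504, tolerance = 1e-12)
  # degenerate K = 0 category
  rows0 <- make_scored(scores = 12:1, cats = rep("B", 12))
  enr0 <- category_enrichment(bin_genes(rows0))
  expect_true(all(enr0$p_enrich[enr0$k == 0 & enr0$K == 0] == 1))
  # p_enrich(k) + p_deplete(k) = 1 + P[X = k] for every cell
  pmf <- choose(enr$K, enr$k) * choose(enr$N - enr$K, enr$m - enr$k) /
    choose(enr$N, enr$m)
  expect_equal(enr$p_enrich + enr$p_deplete, 1 + pmf, tolerance = 1e-12)
})

test_that("spot calling applies the hot/cold rule in both modes", {
  # per-bin mode on synthetic per-cell results: enriched bin 1, depleted bin 6
  res <- data.frame(category = "A", bin = 1:6, N = 600L, K = 100L, m = 100L,
                    k = c(60L, 20L, 10L, 5L, 3L, 2L))
  res$p_enrich <- phyper(res$k - 1, res$K, res$N - res$K, res$m,
                         lower.tail = FALSE)
  res$p_deplete <- phyper(res$k, res$K, res$N - res$K, res$m)
  call_pb <- call_spots(res, method = "per_bin")
  expect_equal(call_pb$call, "hot")
  call_pooled <- call_spots(res, method = "pooled")
  expect_equal(call_pooled$call, "hot")
  # mirrored pattern -> cold
  res_cold <- res
  res_cold$k <- rev(res$k)
  res_cold$p_enrich <- phyper(res_cold$k - 1, res_cold$K,
                              res_cold$N - res_cold$K, res_cold$m,
                              lower.tail = FALSE)
  res_cold$p_deplete <- phyper(res_cold$k, res_cold$K,
                               res_cold$N - res_cold$K, res_cold$m)
  expect_equal(call_spots(res_cold, method = "per_bin")$call, "cold")
  expect_equal(call_spots(res_cold, method = "pooled")$call, "cold")
  # flat distribution -> none
  res_flat <- res
  res_flat$k <- rep(17L, 6)
  res_flat$p_enrich <- phyper(res_flat$k - 1, res_flat$K,
                              res_flat$N - res_flat$K, res_flat$m,
                              lower.tail = FALSE)
  res_flat$p_deplete <- phyper(res_flat$k, res_flat$K,
                               res_flat$N - res_flat$K, res_flat$m)
  expect_equal(call_spots(res_flat, method = "per_bin")$call, "none")
  expect_equal(call_spots(res_flat, method = "pooled")$call, "none")
})

test_that("NYSRN density predicts preference-free transposition incidence", {
  cfg <- sim_config(seed = 51, hot_multiplier = 1, cold_multiplier = 1)
  sim <- make_lysogen(cfg)
  ev <- simulate_replicative_transposition(sim$lysogen, sim$annotations, cfg,
                                           n_events = 8000, replace = TRUE)
  mt <- motif_count_per_gene(scan_nysrn(sim$lysogen$host), sim$annotations,
                             sim$lysogen$host)
  incidence <- vapply(sim$annotations$gene_id, function(g)
    sum(ev$gene_id == g, na.rm = TRUE), numeric(1))
  ct <- suppressWarnings(
    cor.test(mt$per_gene$motif_count, incidence, method = "spearman",
             exact = FALSE))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
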