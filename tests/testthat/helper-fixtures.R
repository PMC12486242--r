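# Fixture builders shared across tests. Everything is generated in code;
# oracles here are deliberately naive implementations kept independent of
# the package's vectorized code paths.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force NYSRN scan oracle: per-window membership test in a plain loop.
oracle_scan_nysrn <- function(seq, circular = FALSE) {
  L <- nchar(seq)
  ext <- if (circular) paste0(seq, substr(seq, 1, 4)) else seq
  n <- if (circular) L else L - 4
  hits <- integer(0)
  for (i in seq_len(max(n, 0))) {
    w <- strsplit(substr(ext, i, i + 4), "")[[1]]
    ok <- w[1] %in% c("A", "C", "G", "T") &&
      w[2] %in% c("C", "T") && w[3] %in% c("G", "C") &&
      w[4] %in% c("A", "G") && w[5] %in% c("A", "C", "G", "T")
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# Exhaustive hypergeometric tail oracle via choose(); independent of phyper.
oracle_hyper_tails <- function(N, K, m, k) {
  ks <- max(0L, K + m - N):min(K, m)
  pmf <- choose(K, ks) * choose(N - K, m - ks) / choose(N, m)
  list(enrich = sum(pmf[ks >= k]), deplete = sum(pmf[ks <= k]))
}

# Hand-built Mu-type toy lysogen: host = X + dup5 + MU + dup5 + Y.
toy_mu_lysogen <- function(seed = 11, x_len = 400, y_len = 400,
                           mu_len = 200, dup5 = "ATCGA") {
  set.seed(seed)
  X <- rand_dna(x_len)
  Y <- rand_dna(y_len)
  MU <- rand_dna(mu_len)
  host_seq <- paste0(X, dup5, MU, dup5, Y)
  host <- genome_record("toy_host", host_seq, "linear")
  pro <- prophage_record("toy_mu", "toy_host",
                         left = x_len + 5L, right = x_len + 5L + mu_len,
                         mechanism = "transposition", genome = MU,
                         target_dup = dup5)
  list(lysogen = lysogen(host, list(pro)), X = X, Y = Y, MU = MU,
       dup5 = dup5, naive = paste0(X, dup5, Y))
}

# Hand-built site-specific toy lysogen: host = P + attP + SS + attP + Q.
toy_ss_lysogen <- function(seed = 12, p_len = 400, q_len = 400,
                           ss_len = 200, attP = "ACGTACGTACGT") {
  set.seed(seed)
  P <- rand_dna(p_len)
  Q <- rand_dna(q_len)
  SS <- rand_dna(ss_len)
  a <- nchar(attP)
  host_seq <- paste0(P, attP, SS, attP, Q)
  host <- genome_record("toy_host2", host_seq, "linear")
  pro <- prophage_record("toy_ss", "toy_host2",
                         left = p_len + a, right = p_len + a + ss_len,
                         mechanism = "site_specific", genome = SS,
                         attP = attP)
  list(lysogen = lysogen(host, list(pro)), P = P, Q = Q, SS = SS,
       attP = attP, naive = paste0(P, attP, Q))
}
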