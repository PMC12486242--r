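## ttp_enrichment: per-gene transposition target preference (TTP) scores,
## six-bin ranking, and hypergeometric hot/cold spot calling.
##
## TTP score = (new 5'flap hits credited to the gene) / (NYSRN motif count
## in the gene).  Genes are ranked by score and cut into equal-size bins;
## functional-category enrichment/depletion per bin uses hypergeometric tail
## probabilities at raw P < .01 (no multiplicity correction).  A hot spot is
## a category over-represented among top-ranked genes and under-represented
## among low-ranked genes; a cold spot shows the mirrored pattern.

#' Per-gene TTP scores
#'
#' A new flap is credited to a gene iff its mapped `flap_len`-nt window lies
#' fully within the gene interval -- the same containment rule that credits
#' NYSRN motifs, so numerator and denominator count the same kind of event.
#' Genes with zero motifs cannot host NYSRN-targeted insertions and are
#' excluded from scoring (returned in the `"unscored"` attribute).
#'
#' @param flap_positions 0-based start positions of mapped new flaps
#'   (integer vector), or a mapped flap data.frame with `host_position` and
#'   `flap_class` (rows with class `"new"` are used).
#' @param annotations annotation data.frame.
#' @param motif_table [motif_count_per_gene()] output for the same
#'   chromosome.
#' @param flap_len flap window length, default 20.
#' @return data.frame (one row per scored gene): gene_id, category,
#'   gene_length, flap_hits, motif_count, ttp_score; attribute `"unscored"`
#'   holds the motif-free genes.
#' @export
ttp_scores <- function(flap_positions, annotations, motif_table,
                       flap_len = 20L) {
  validate_annotations(annotations)
  stopifnot(inherits(motif_table, "motif_table"))
  if (is.data.frame(flap_positions)) {
    keep <- if ("flap_class" %in% names(flap_positions))
      flap_positions$flap_class == "new" else rep(TRUE, nrow(flap_positions))
    flap_positions <- flap_positions$host_position[keep]
  }
  flap_positions <- as.integer(flap_positions[!is.na(flap_positions)])
  hits <- vapply(seq_len(nrow(annotations)), function(i) {
    sum(flap_positions >= annotations$start[i] &
          flap_positions + flap_len <= annotations$end[i])
  }, integer(1))
  mt <- motif_table$per_gene
  m <- mt$motif_count[match(annotations$gene_id, mt$gene_id)]
  if (anyNA(m))
    stop("motif table does not cover every annotated gene", call. = FALSE)
  rows <- data.frame(gene_id = annotations$gene_id,
                     category = annotations$category,
                     gene_length = annotations$end - annotations$start,
                     flap_hits = hits, motif_count = m,
                     stringsAsFactors = FALSE)
  scored <- rows[rows$motif_count >= 1L, , drop = FALSE]
  unscored <- rows[rows$motif_count == 0L, , drop = FALSE]
  scored$ttp_score <- scored$flap_hits / scored$motif_count
  rownames(scored) <- NULL
  attr(scored, "unscored") <- unscored
  scored
}

#' Rank scored genes and assign them to bins
#'
#' Genes are sorted by TTP score descending (ties: motif_count descending,
#' then gene_id), then partitioned into `n_bins` contiguous rank blocks
#' with sizes as equal as possible, earlier bins taking the extra gene.
#'
#' @param rows output of [ttp_scores()].
#' @param n_bins number of bins, default 6.
#' @return `rows` sorted, with 1-based `rank` and `bin` columns added.
#' @export
bin_genes <- function(rows, n_bins = 6L) {
  stopifnot(is.data.frame(rows), n_bins >= 1L)
  n <- nrow(rows)
  if (n < n_bins)
    stop(sprintf("need at least %d scored genes for %d bins (got %d)",
                 n_bins, n_bins, n), call. = FALSE)
  o <- order(-rows$ttp_score, -rows$motif_count, rows$gene_id)
  rows <- rows[o, , drop = FALSE]
  rows$rank <- seq_len(n)
  base <- n %/% n_bins
  sizes <- base + as.integer(seq_len(n_bins) <= n %% n_bins)
  rows$bin <- rep(seq_len(n_bins), times = sizes)
  rownames(rows) <- NULL
  rows
}

#' Hypergeometric category enrichment per bin
#'
#' For each (category, bin) cell with population `N` (all scored genes),
#' category size `K`, bin size `m` and observed overlap `k`:
#' `p_enrich = P[X >= k]`, `p_deplete = P[X <= k]` under
#' Hypergeometric(N, K, m).  Raw alpha threshold, no multiple-testing
#' correction (an optional Benjamini-Hochberg mode is available).
#'
#' @param binned_rows output of [bin_genes()].
#' @param alpha significance threshold, default 0.01.
#' @param fdr if `TRUE`, significance flags use BH-adjusted p-values
#'   (off by default).
#' @return data.frame: category, bin, N, K, m, k, p_enrich, p_deplete,
#'   sig_enrich, sig_deplete.
#' @export
category_enrichment <- function(binned_rows, alpha = 0.01, fdr = FALSE) {
  stopifnot(all(c("category", "bin") %in% names(binned_rows)))
  N <- nrow(binned_rows)
  cats <- sort(unique(binned_rows$category))
  bins <- sort(unique(binned_rows$bin))
  grid <- expand.grid(category = cats, bin = bins,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  K <- vapply(grid$category, function(cc) sum(binned_rows$category == cc),
              integer(1))
  m <- vapply(grid$bin, function(b) sum(binned_rows$bin == b), integer(1))
  k <- vapply(seq_len(nrow(grid)), function(i)
    sum(binned_rows$category == grid$category[i] &
          binned_rows$bin == grid$bin[i]), integer(1))
  p_enrich <- phyper(k - 1L, K, N - K, m, lower.tail = FALSE)
  p_deplete <- phyper(k, K, N - K, m)
  res <- data.frame(category = grid$category, bin = grid$bin,
                    N = N, K = K, m = m, k = k,
                    p_enrich = p_enrich, p_deplete = p_deplete,
                    stringsAsFactors = FALSE)
  pe <- if (fdr) stats::p.adjust(res$p_enrich, "BH") else res$p_enrich
  pd <- if (fdr) stats::p.adjust(res$p_deplete, "BH") else res$p_deplete
  res$sig_enrich <- pe < alpha
  res$sig_deplete <- pd < alpha
  res
}

#' Call transposition hot and cold spots
#'
#' A hot spot is a category significantly enriched among top-ranking bins
#' and depleted among low-ranking bins; a cold spot the mirror image.  Two
#' assessment modes:
#'
#' * `"pooled"` (default): the top bins are pooled into a single
#'   hypergeometric test (as are the low bins), using the counts carried in
#'   `results`; robust at small gene numbers, where a single bin's depletion
#'   tail has a floor of `P[X = 0]` that can exceed `alpha` for any
#'   moderate category size.
#' * `"per_bin"`: significance in at least one top bin and at least one low
#'   bin, read directly off the per-cell p-values.
#'
#' @param results data.frame from [category_enrichment()].
#' @param top_bins bins counted as "top-ranking" (default 1-2).
#' @param low_bins bins counted as "lower" (default 4-6).
#' @param alpha significance threshold, default 0.01.
#' @param method `"pooled"` or `"per_bin"`.
#' @return data.frame: category, call (`hot`/`cold`/`none`), plus the
#'   supporting tail probabilities (pooled mode) or supporting bins.
#' @export
call_spots <- function(results, top_bins = c(1L, 2L), low_bins = c(4L, 5L, 6L),
                       alpha = 0.01, method = c("pooled", "per_bin")) {
  method <- match.arg(method)
  stopifnot(all(c("category", "bin", "p_enrich", "p_deplete") %in% names(results)))
  cats <- sort(unique(results$category))
  calls <- lapply(cats, function(cc) {
    sub <- results[results$category == cc, , drop = FALSE]
    if (method == "pooled") {
      pool <- function(bins) {
        s <- sub[sub$bin %in% bins, , drop = FALSE]
        list(k = sum(s$k), m = sum(s$m), K = s$K[1], N = s$N[1])
      }
      tp <- pool(top_bins); lp <- pool(low_bins)
      top_enr <- phyper(tp$k - 1L, tp$K, tp$N - tp$K, tp$m, lower.tail = FALSE)
      top_dep <- phyper(tp$k, tp$K, tp$N - tp$K, tp$m)
      low_enr <- phyper(lp$k - 1L, lp$K, lp$N - lp$K, lp$m, lower.tail = FALSE)
      low_dep <- phyper(lp$k, lp$K, lp$N - lp$K, lp$m)
      hot <- top_enr < alpha && low_dep < alpha
      cold <- low_enr < alpha && top_dep < alpha
      call <- if (hot && cold) "none" else if (hot) "hot" else
        if (cold) "cold" else "none"
      data.frame(category = cc, call = call,
                 p_top_enrich = top_enr, p_top_deplete = top_dep,
                 p_low_enrich = low_enr, p_low_deplete = low_dep,
                 stringsAsFactors = FALSE)
    } else {
      top <- sub[sub$bin %in% top_bins, , drop = FALSE]
      low <- sub[sub$bin %in% low_bins, , drop = FALSE]
      hot <- any(top$p_enrich < alpha) && any(low$p_deplete < alpha)
      cold <- any(low$p_enrich < alpha) && any(top$p_deplete < alpha)
      call <- if (hot && cold) "none" else if (hot) "hot" else
        if (cold) "cold" else "none"
      support <- paste(c(
        sprintf("enrich:bin%d", top$bin[top$p_enrich < alpha]),
        sprintf("deplete:bin%d", low$bin[low$p_deplete < alpha]),
        sprintf("enrich:bin%d", low$bin[low$p_enrich < alpha]),
        sprintf("deplete:bin%d", top$bin[top$p_deplete < alpha])),
        collapse = ",")
      data.frame(category = cc, call = call, supporting = support,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
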