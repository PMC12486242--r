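## induction_signatures: spontaneous-induction evidence in cellular DNA.
##
## Mu-type prophages: induction proceeds by replicative transposition, so
## cellular reads carrying *new* 5'flaps (L_NEW / R_NEW) are direct
## evidence.  Integrase-type prophages: excision and circularization
## restore attP, joining the two prophage termini; 20-mers spanning that
## L-attP-R junction, absent from the lysogen chromosome, are the
## signature.  A simple read-start pile-up detector locates cos-type
## packaging termini.

#' Build the attP junction signature for a site-specific prophage
#'
#' The excised-circle junction is `last J nt of the prophage genome + attP +
#' first J nt`.  Signature k-mers are all `k`-mers of that junction that
#' (a) contain the full attP when `attP <= k` nt (else cover the junction
#' midpoint, with a warning), and (b) never occur on the lysogen chromosome
#' or its reverse complement -- screening out attL/attR-derived false
#' positives before any read is counted.
#'
#' @param prophage a site-specific [prophage_record()] with `attP`.
#' @param chromosome the lysogen chromosome ([genome_record()]) used for the
#'   uniqueness screen.
#' @param J terminal context length on each side of attP, default 20.
#' @param k signature k-mer length, default 20.
#' @return object of class `junction_signature`: list with `prophage_id`,
#'   `junction_sequence`, `signature_kmers` (character vector, possibly
#'   empty with a warning).
#' @export
build_attP_junction <- function(prophage, chromosome, J = 20L, k = 20L) {
  stopifnot(inherits(prophage, "prophage_record"),
            inherits(chromosome, "genome_record"))
  if (prophage$mechanism != "site_specific" || is.null(prophage$attP))
    stop("attP junction requires a site-specific prophage with attP",
         call. = FALSE)
  g <- prophage$genome
  G <- nchar(g)
  if (G < J) stop("prophage genome shorter than terminal context J", call. = FALSE)
  attP <- prophage$attP
  a <- nchar(attP)
  junction <- paste0(substr(g, G - J + 1L, G), attP, substr(g, 1L, J))
  jl <- nchar(junction)
  ## 0-based: attP occupies [J, J+a) within the junction
  if (a <= k) {
    s0 <- max(0L, J + a - k)
    s1 <- min(J, jl - k)
  } else {
    warning(sprintf(
      "attP (%d nt) longer than k = %d: falling back to junction-midpoint coverage",
      a, k))
    mid <- J + a %/% 2L
    s0 <- max(0L, mid - k + 1L)
    s1 <- min(mid, jl - k)
  }
  if (s1 < s0) stop("junction too short for any signature k-mer", call. = FALSE)
  cand <- unique(vapply(s0:s1, function(s) substr(junction, s + 1L, s + k),
                        character(1)))
  chrom_kmers <- genome_kmer_index(chromosome, k)
  present <- cand %in% chrom_kmers | revcomp(cand) %in% chrom_kmers
  sig <- cand[!present]
  if (length(sig) == 0L)
    warning(sprintf(
      "prophage '%s': every candidate junction %d-mer re-occurs on the chromosome; empty signature",
      prophage$id, k))
  structure(list(prophage_id = prophage$id, junction_sequence = junction,
                 signature_kmers = sig),
            class = "junction_signature")
}

#' @export
print.junction_signature <- function(x, ...) {
  cat(sprintf("<junction_signature> %s: %d signature k-mers over a %d-nt junction\n",
              x$prophage_id, length(x$signature_kmers),
              nchar(x$junction_sequence)))
  invisible(x)
}

#' Detect integrase-type induction from cellular reads
#'
#' Evidence is the number of reads (either orientation) containing at least
#' one signature k-mer by exact match; sequencing errors therefore reduce
#' sensitivity, never specificity.
#'
#' @param cell_reads named character vector or `DNAStringSet`.
#' @param signature a [build_attP_junction()] result.
#' @param min_evidence reads required to flag induction, default 1.
#' @return object of class `induction_report`: prophage_id, mechanism,
#'   evidence_count, induced.
#' @export
detect_integrase_induction <- function(cell_reads, signature,
                                       min_evidence = 1L) {
  stopifnot(inherits(signature, "junction_signature"))
  if (length(signature$signature_kmers) == 0L)
    stop(paste0("empty junction signature for '", signature$prophage_id,
                "': rebuild with build_attP_junction() and heed its warning"),
         call. = FALSE)
  reads <- as_read_vector(cell_reads)
  pats <- unique(c(signature$signature_kmers,
                   revcomp(signature$signature_kmers)))
  hit <- rep(FALSE, length(reads))
  for (p in pats) hit <- hit | grepl(p, reads, fixed = TRUE)
  ev <- sum(hit)
  structure(list(prophage_id = signature$prophage_id,
                 mechanism = "site_specific",
                 evidence_count = ev,
                 induced = ev >= min_evidence,
                 evidence_reads = names(reads)[hit]),
            class = "induction_report")
}

#' Detect Mu-type induction from cellular reads
#'
#' Delegates to the flap pipeline: flaps are extracted against the resident
#' Mu-like prophage, mapped to the lysogen chromosome and classified.
#' Original flaps come from reads spanning the native locus and are
#' expected in any lysogen; only *new* flaps (y) count as evidence of
#' replicative transposition.
#'
#' @param cell_reads named character vector or `DNAStringSet`.
#' @param prophage the Mu-like [prophage_record()].
#' @param chromosome the lysogen chromosome ([genome_record()]).
#' @param min_evidence new-flap count required to flag induction, default 1.
#' @param flap_len,anchor_len see [extract_flaps()].
#' @return an `induction_report` (with the `flap_counts` in `$counts`).
#' @export
detect_mu_induction <- function(cell_reads, prophage, chromosome,
                                min_evidence = 1L, flap_len = 20L,
                                anchor_len = 20L) {
  stopifnot(inherits(prophage, "prophage_record"))
  if (prophage$mechanism != "transposition")
    stop("Mu-type detector requires a transposition-mechanism prophage",
         call. = FALSE)
  fl <- extract_flaps(cell_reads, prophage$genome, flap_len = flap_len,
                      anchor_len = anchor_len)
  fl <- map_flaps(fl, chromosome)
  counts <- classify_flaps(fl, prophage)
  structure(list(prophage_id = prophage$id,
                 mechanism = "transposition",
                 evidence_count = counts$y,
                 induced = counts$y >= min_evidence,
                 counts = counts),
            class = "induction_report")
}

#' @export
print.induction_report <- function(x, ...) {
  cat(sprintf("<induction_report> %s (%s): evidence = %d, induced = %s\n",
              x$prophage_id, x$mechanism, x$evidence_count, x$induced))
  invisible(x)
}

#' Histogram of read 5'-start positions on a genome
#'
#' Each read's leading `k`-mer is located on the genome by unique exact
#' match (both strands, circular-aware).  On the forward strand the 5' end
#' is the match start; on the reverse strand it is the last base of the
#' matched forward window.  Reads whose leading k-mer is absent or
#' multi-mapping are dropped.
#'
#' @param reads named character vector or `DNAStringSet`.
#' @param genome a [genome_record()].
#' @param k leading k-mer length, default 20.
#' @return data.frame: position (0-based), strand, count.
#' @export
read_start_histogram <- function(reads, genome, k = 20L) {
  reads <- as_read_vector(reads)
  reads <- reads[nchar(reads) >= k]
  empty <- data.frame(position = integer(0), strand = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (length(reads) == 0L) return(empty)
  lead <- substr(reads, 1L, k)
  kmers <- genome_kmer_index(genome, k)
  tab <- table(kmers)
  occ <- function(x) { v <- as.integer(tab[x]); v[is.na(v)] <- 0L; v }
  rc <- revcomp(lead)
  of <- occ(lead); orv <- occ(rc)
  tot <- of + orv
  pos <- integer(0); strand <- character(0)
  uf <- tot == 1L & of == 1L
  ur <- tot == 1L & orv == 1L
  L <- genome_length(genome)
  if (any(uf)) {
    pos <- c(pos, match(lead[uf], kmers) - 1L)
    strand <- c(strand, rep("+", sum(uf)))
  }
  if (any(ur)) {
    p <- (match(rc[ur], kmers) - 1L + k - 1L) %% L
    pos <- c(pos, p)
    strand <- c(strand, rep("-", sum(ur)))
  }
  if (length(pos) == 0L) return(empty)
  agg <- stats::aggregate(list(count = rep(1L, length(pos))),
                          by = list(position = pos, strand = strand), FUN = sum)
  agg[order(agg$strand, agg$position), , drop = FALSE]
}

#' Detect candidate packaging termini from a read-start histogram
#'
#' A deliberately simple stand-in for full terminal-redundancy analysis: a
#' position is a candidate terminus when its 5'-start count reaches `fold`
#' times the median nonzero start count on its strand.  Opposite-strand
#' peak pairs whose positions are circularly adjacent (within `max_gap`)
#' are reported as candidate cos ends: a genome population cut at position
#' `c` piles up forward starts at `c` and reverse 5' ends at `c - 1`.
#'
#' @param hist data.frame from [read_start_histogram()].
#' @param fold peak threshold as a multiple of the median nonzero count,
#'   default 20.
#' @param genome_length chromosome length for circular adjacency; if `NULL`
#'   adjacency is linear.
#' @param max_gap maximum peak-pair separation, default 5.
#' @return list with `candidates` (position, strand, count) and `cos_pairs`
#'   (plus_pos, minus_pos, cut_position).
#' @export
detect_termini <- function(hist, fold = 20, genome_length = NULL, max_gap = 5L) {
  stopifnot(is.data.frame(hist))
  empty <- list(candidates = data.frame(position = integer(0),
                                        strand = character(0),
                                        count = integer(0)),
                cos_pairs = data.frame(plus_pos = integer(0),
                                       minus_pos = integer(0),
                                       cut_position = integer(0)))
  hist <- hist[hist$count > 0L, , drop = FALSE]
  if (nrow(hist) == 0L) return(empty)
  cands <- do.call(rbind, lapply(split(hist, hist$strand), function(h) {
    med <- median(h$count)
    h[h$count >= fold * med, , drop = FALSE]
  }))
  if (is.null(cands) || nrow(cands) == 0L) return(empty)
  rownames(cands) <- NULL
  plus <- cands[cands$strand == "+", , drop = FALSE]
  minus <- cands[cands$strand == "-", , drop = FALSE]
  pairs <- list()
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      expected <- plus$position[i] - 1L
      d <- abs(minus$position[j] - expected)
      if (!is.null(genome_length))
        d <- min(d, genome_length - d)
      if (d <= max_gap)
        pairs[[length(pairs) + 1L]] <- data.frame(
          plus_pos = plus$position[i], minus_pos = minus$position[j],
          cut_position = plus$position[i])
    }
  }
  list(candidates = cands,
       cos_pairs = if (length(pairs)) do.call(rbind, pairs) else
         empty$cos_pairs)
}

#' cos sequences of the two integrase-type citromicrobial prophage genera
#'
#' Documented fixture constants for tests and examples: the packaging
#' cut-site sequences of the P2-like genus (19 nt) and the chimeric genus
#' (11 nt).
#'
#' @return named character vector with elements `phiD` and `phiE`.
#' @export
cos_sites <- function() {
  c(phiD = "GGCGTGGCGTGGGGGCGAG",
    phiE = "CTACGCCCCAC")
}
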