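## motif_scan: NYSRN consensus scanning and per-gene motif tabulation.
##
## NYSRN is the degenerate 5-bp target consensus duplicated by Mu-type
## transposition: N any base, Y = C/T, S = G/C, R = A/G.  The pattern is its
## own reverse complement, so single-strand scanning captures both strands'
## sites (window starts map as i <-> L-5-i under reverse complement).

NYSRN_SLOTS <- list(
  c("A", "C", "G", "T"),  # N -- genome N is unknown, matches nothing
  c("C", "T"),            # Y
  c("G", "C"),            # S
  c("A", "G"),            # R
  c("A", "C", "G", "T")   # N
)

#' Does a 5-mer match the NYSRN consensus?
#' @param x character vector of 5-nt strings.
#' @return logical vector.
#' @export
is_nysrn <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) != 5L) return(FALSE)
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    all(vapply(1:5, function(i) ch[i] %in% NYSRN_SLOTS[[i]], logical(1)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Scan a genome for NYSRN target sites
#'
#' Returns the sorted 0-based start positions of every 5-mer window matching
#' the consensus.  Overlapping occurrences are all reported.  Windows
#' containing `N` never match (masked regions contribute zero motifs).  On
#' circular genomes windows crossing the origin are included (starts in
#' `[L-4, L)` wrap around).
#'
#' @param genome a [genome_record()] or plain DNA string (treated linear).
#' @return integer vector of 0-based start positions.
#' @export
scan_nysrn <- function(genome) {
  if (is.character(genome)) genome <- genome_record("query", genome)
  stopifnot(inherits(genome, "genome_record"))
  s <- genome$sequence
  L <- nchar(s)
  circular <- genome$topology == "circular"
  if (!circular && L < 5L) return(integer(0))
  ext <- if (circular) paste0(s, substr(s, 1L, 4L)) else s
  ch <- strsplit(ext, "", fixed = TRUE)[[1]]
  n <- if (circular) L else L - 4L
  if (n < 1L) return(integer(0))
  idx <- seq_len(n)
  ok <- ch[idx] %in% NYSRN_SLOTS[[1]] &
    ch[idx + 1L] %in% NYSRN_SLOTS[[2]] &
    ch[idx + 2L] %in% NYSRN_SLOTS[[3]] &
    ch[idx + 3L] %in% NYSRN_SLOTS[[4]] &
    ch[idx + 4L] %in% NYSRN_SLOTS[[5]]
  which(ok) - 1L
}

#' Tabulate NYSRN occurrences per gene
#'
#' A motif occurrence is credited to a gene iff its full 5-nt span lies
#' within the gene interval (the same full-containment rule used for flap
#' crediting, keeping the TTP numerator and denominator symmetric).
#' Occurrences in intergenic space count toward the genome-wide total but
#' are credited to no gene.
#'
#' @param positions 0-based start positions from [scan_nysrn()] on the same
#'   genome.
#' @param annotations annotation data.frame (gene_id, start, end, strand,
#'   category).
#' @param genome optional `genome_record` for bounds validation.
#' @return object of class `motif_table`: list with `per_gene` (data.frame
#'   gene_id, gene_length, motif_count, category), `positions`, `total`.
#' @export
motif_count_per_gene <- function(positions, annotations, genome = NULL) {
  validate_annotations(annotations, genome)
  positions <- as.integer(positions)
  counts <- vapply(seq_len(nrow(annotations)), function(i) {
    sum(positions >= annotations$start[i] & positions + 5L <= annotations$end[i])
  }, integer(1))
  per_gene <- data.frame(
    gene_id = annotations$gene_id,
    gene_length = annotations$end - annotations$start,
    motif_count = counts,
    category = annotations$category,
    stringsAsFactors = FALSE)
  structure(list(per_gene = per_gene, positions = positions,
                 total = length(positions)),
            class = "motif_table")
}

#' @export
print.motif_table <- function(x, ...) {
  cat(sprintf("<motif_table> %d NYSRN sites genome-wide, %d genes (%d genic hits)\n",
              x$total, nrow(x$per_gene), sum(x$per_gene$motif_count)))
  invisible(x)
}

#' Write a motif table as TSV (gene_id, gene_length, motif_count)
#' @param x a `motif_table`.
#' @param path output path.
#' @export
write_motif_table <- function(x, path) {
  write.table(x$per_gene, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
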