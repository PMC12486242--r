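## flap_analysis: 20-nt host 5'flap extraction from Mu-like particle reads,
## exact mapping to the host chromosome, original/new classification, and
## burst-size estimation.
##
## Headful packaging places host DNA beyond both ends of every packaged
## Mu-like genome.  The flaps at the native prophage locus are "original";
## flaps at replicative-transposition targets are "new".  With x original
## and y new flaps, the average burst size is (x+y)/x = 1 + n, n the number
## of duplicated transposon copies per cell.

#' Extract 20-nt host 5'flaps from phage-particle reads
#'
#' A flap is emitted when a read (or its reverse complement) contains an
#' exact `anchor_len`-nt match to a prophage terminal segment with at least
#' `flap_len` nt of sequence on the outward side; the outward `flap_len` nt
#' are the flap.  Matching is exact (no mismatches), mirroring the
#' 100%-identity stance of the analysis; reads are canonicalized against
#' the prophage strand before anchoring.  Reads shorter than
#' `anchor_len + flap_len` cannot yield a flap and are skipped.
#'
#' @param reads named character vector or `DNAStringSet`.
#' @param prophage_genome DNA string of the prophage genome (or a
#'   [prophage_record()], whose `genome` is used).
#' @param flap_len flap length (nt), default 20.
#' @param anchor_len terminal anchor length (nt), default 20.
#' @return data.frame with columns read_id, end ("L"/"R"), sequence,
#'   orientation ("+" read as-is, "-" reverse complement).
#' @export
extract_flaps <- function(reads, prophage_genome, flap_len = 20L,
                          anchor_len = 20L) {
  if (inherits(prophage_genome, "prophage_record"))
    prophage_genome <- prophage_genome$genome
  if (inherits(prophage_genome, "genome_record"))
    prophage_genome <- prophage_genome$sequence
  prophage_genome <- toupper(prophage_genome)
  G <- nchar(prophage_genome)
  if (G < anchor_len)
    stop("prophage genome shorter than anchor_len", call. = FALSE)
  reads <- as_read_vector(reads)
  anchors <- c(L = substr(prophage_genome, 1L, anchor_len),
               R = substr(prophage_genome, G - anchor_len + 1L, G))
  rows <- list()
  for (ori in c("+", "-")) {
    ss <- if (ori == "+") reads else setNames(revcomp(reads), names(reads))
    for (end_lab in c("L", "R")) {
      m <- gregexpr(anchors[[end_lab]], ss, fixed = TRUE)
      hit <- which(vapply(m, function(z) z[1] != -1L, logical(1)))
      for (i in hit) {
        for (p in as.integer(m[[i]])) {   # 1-based anchor start in the read
          if (end_lab == "L") {
            if (p - 1L < flap_len) next
            flap <- substr(ss[[i]], p - flap_len, p - 1L)
          } else {
            s0 <- p + anchor_len
            if (nchar(ss[[i]]) - s0 + 1L < flap_len) next
            flap <- substr(ss[[i]], s0, s0 + flap_len - 1L)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = names(ss)[i], end = end_lab, sequence = flap,
            orientation = ori, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(read_id = character(0), end = character(0),
                      sequence = character(0), orientation = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

## forward-strand k-mer index of a genome (circular-aware)
genome_kmer_index <- function(genome, k) {
  s <- genome$sequence
  L <- nchar(s)
  circular <- genome$topology == "circular"
  ext <- if (circular) paste0(s, substr(s, 1L, k - 1L)) else s
  n <- if (circular) L else L - k + 1L
  if (n < 1L) return(character(0))
  substring(ext, seq_len(n), seq_len(n) + k - 1L)
}

#' Map flaps to the host chromosome by exact substring match
#'
#' A flap is mapped iff its sequence occurs exactly once on the host
#' chromosome across both strands (wrap-around windows allowed on circular
#' chromosomes); multi-occurrence flaps are `ambiguous`, absent flaps
#' `unmapped`.  `host_position` is the 0-based forward-strand start of the
#' matched window regardless of strand.
#'
#' @param flaps data.frame from [extract_flaps()].
#' @param host_genome a [genome_record()].
#' @return the flap data.frame with `host_position`, `host_strand`,
#'   `flap_class` (`mapped`/`unmapped`/`ambiguous`) filled in.
#' @export
map_flaps <- function(flaps, host_genome) {
  stopifnot(inherits(host_genome, "genome_record"), is.data.frame(flaps))
  n <- nrow(flaps)
  flaps$host_position <- rep(NA_integer_, n)
  flaps$host_strand <- rep(NA_character_, n)
  flaps$flap_class <- rep("unmapped", n)
  if (n == 0L) return(flaps)
  k <- unique(nchar(flaps$sequence))
  if (length(k) != 1L) stop("flaps must share a single length", call. = FALSE)
  kmers <- genome_kmer_index(host_genome, k)
  tab <- table(kmers)
  occ <- function(x) {
    v <- as.integer(tab[x]); v[is.na(v)] <- 0L; v
  }
  fwd <- flaps$sequence
  rc <- revcomp(fwd)
  of <- occ(fwd); orv <- occ(rc)
  tot <- of + orv
  flaps$flap_class[tot > 1L] <- "ambiguous"
  uf <- tot == 1L & of == 1L
  ur <- tot == 1L & orv == 1L
  flaps$host_position[uf] <- match(fwd[uf], kmers) - 1L
  flaps$host_strand[uf] <- "+"
  flaps$host_position[ur] <- match(rc[ur], kmers) - 1L
  flaps$host_strand[ur] <- "-"
  flaps$flap_class[uf | ur] <- "mapped"
  flaps
}

#' Classify mapped flaps as original vs new and count them
#'
#' A flap is *original* iff it maps (forward strand) to the host window
#' immediately flanking the native prophage locus on the matching side:
#' an L flap to the `flap_len` nt upstream of the prophage's left boundary,
#' an R flap to the `flap_len` nt downstream of its right boundary.  Those
#' comparison windows abut the recorded `[left, right)` interval, which
#' excludes the duplicated target, so the native locus and true
#' re-insertions are handled by one rule.  Every other uniquely mapped flap
#' is *new*.  Ambiguous (multi-mapping) flaps are excluded from both counts.
#'
#' @param flaps mapped flap data.frame from [map_flaps()].
#' @param prophage the resident [prophage_record()] (coordinates on the same
#'   chromosome the flaps were mapped to).
#' @param dedupe if `TRUE`, identical (end, sequence) flaps are counted once
#'   (site-level counting); default `FALSE` counts every read occurrence,
#'   since read count is the particle proxy in the burst-size formula.
#' @return object of class `flap_counts`: list with `x` (original), `y`
#'   (new), `unmapped`, `ambiguous`, and the annotated `flaps` data.frame.
#' @export
classify_flaps <- function(flaps, prophage, dedupe = FALSE) {
  stopifnot(is.data.frame(flaps))
  if (!inherits(prophage, "prophage_record") || is.null(prophage$left))
    stop("prophage record with coordinates required", call. = FALSE)
  if (nrow(flaps) == 0L) {
    return(structure(list(x = 0L, y = 0L, unmapped = 0L, ambiguous = 0L,
                          flaps = flaps), class = "flap_counts"))
  }
  flap_len <- unique(nchar(flaps$sequence))
  orig_pos <- c(L = prophage$left - flap_len, R = prophage$right)
  mapped <- flaps$flap_class == "mapped"
  is_orig <- mapped & flaps$host_strand == "+" &
    flaps$host_position == unname(orig_pos[flaps$end])
  flaps$flap_class[mapped] <- ifelse(is_orig[mapped], "original", "new")
  counted <- flaps
  if (dedupe) {
    keep <- !duplicated(counted[, c("end", "sequence")])
    counted <- counted[keep, , drop = FALSE]
  }
  structure(list(
    x = sum(counted$flap_class == "original"),
    y = sum(counted$flap_class == "new"),
    unmapped = sum(counted$flap_class == "unmapped"),
    ambiguous = sum(counted$flap_class == "ambiguous"),
    flaps = flaps), class = "flap_counts")
}

#' @export
print.flap_counts <- function(x, ...) {
  cat(sprintf("<flap_counts> x (original) = %d, y (new) = %d, unmapped = %d, ambiguous = %d\n",
              x$x, x$y, x$unmapped, x$ambiguous))
  invisible(x)
}

#' Average burst size from flap counts
#'
#' `burst = (x + y) / x = 1 + y/x`, equivalently `1 + n` where `n` is the
#' number of duplicated transposon copies: each mature Mu-like particle
#' corresponds to one transposon copy, and the cell's transposon load is
#' one original copy plus `n` duplicates.
#'
#' @param counts a `flap_counts` object, or a list with numeric `x` and `y`.
#' @return positive real burst size.
#' @export
burst_size <- function(counts) {
  x <- counts$x
  y <- counts$y
  stopifnot(is.numeric(x), is.numeric(y), y >= 0)
  if (x < 1)
    stop("no original 5'flaps recovered (x = 0); burst size undefined",
         call. = FALSE)
  (x + y) / x
}

#' Write a flap table as TSV
#' @param flaps annotated flap data.frame (after classify).
#' @param path output path.
#' @export
write_flap_table <- function(flaps, path) {
  write.table(flaps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
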