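## genome_io: domain model and readers/writers for genomes, annotations,
## prophage records and reads; attB reference reconstruction and masking.
##
## All coordinates in this package are 0-based half-open. Circular
## chromosomes are stored linearly with topology = "circular"; operations
## that need wrap-around virtually extend the sequence.

#' Genome record
#'
#' A chromosome or phage genome: an id, an uppercase DNA sequence over
#' {A,C,G,T,N}, and a topology flag.  Bacterial host chromosomes are
#' typically circular; phage genome linearizations are linear.
#'
#' @param id character scalar.
#' @param sequence DNA string; lowercase input is uppercased; characters
#'   outside A,C,G,T,N are rejected.
#' @param topology `"linear"` or `"circular"`.
#' @return an object of class `genome_record` with fields `id`, `sequence`,
#'   `topology`.
#' @export
genome_record <- function(id, sequence, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("genome sequence must be non-empty", call. = FALSE)
  check_alphabet(sequence, sprintf("genome '%s'", id))
  structure(list(id = id, sequence = sequence, topology = topology),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s\n", x$id,
              format(nchar(x$sequence), big.mark = ","), x$topology))
  invisible(x)
}

genome_length <- function(g) nchar(g$sequence)

#' Prophage record
#'
#' Describes one integrated prophage: its half-open interval `[left, right)`
#' on the host chromosome (the prophage genome proper, excluding the
#' flanking repeat), its integration mechanism, and the mechanism-specific
#' attachment bookkeeping.  Transposition-type (Mu-like) prophages carry a
#' 5-bp duplicated target (`target_dup`, matching the NYSRN consensus) on
#' both sides of `[left, right)`; site-specific prophages carry one copy of
#' the attachment core (`attP`) on both sides (attL/attR core).  `cos`, if
#' present, is the packaging cut-site sequence inside the prophage genome.
#'
#' @param id,host_id character ids.
#' @param left,right 0-based half-open interval on the host chromosome.
#' @param mechanism `"transposition"` or `"site_specific"`.
#' @param genome DNA string of the integrated prophage, equal to
#'   `host[left:right)`.
#' @param target_dup 5-nt duplicated target (transposition only).
#' @param attP attachment-site core sequence (site_specific only).
#' @param cos optional cos sequence.
#' @return object of class `prophage_record`.
#' @export
prophage_record <- function(id, host_id, left, right,
                            mechanism = c("transposition", "site_specific"),
                            genome, target_dup = NULL, attP = NULL, cos = NULL) {
  mechanism <- match.arg(mechanism)
  stopifnot(left >= 0, right > left)
  genome <- toupper(genome)
  check_alphabet(genome, sprintf("prophage '%s' genome", id))
  if (nchar(genome) != right - left)
    stop("prophage genome length must equal right - left", call. = FALSE)
  if (mechanism == "transposition") {
    if (is.null(target_dup) || nchar(target_dup) != 5L)
      stop("transposition-type prophage requires a 5-nt target_dup", call. = FALSE)
    target_dup <- toupper(target_dup)
    if (!is_nysrn(target_dup))
      stop(sprintf("target_dup '%s' does not match the NYSRN consensus", target_dup),
           call. = FALSE)
  } else {
    if (is.null(attP) || !nzchar(attP))
      stop("site_specific prophage requires a non-empty attP", call. = FALSE)
    attP <- toupper(attP)
    check_alphabet(attP, "attP")
  }
  if (!is.null(cos)) cos <- toupper(cos)
  structure(list(id = id, host_id = host_id, left = as.integer(left),
                 right = as.integer(right), mechanism = mechanism,
                 genome = genome, target_dup = target_dup, attP = attP,
                 cos = cos),
            class = "prophage_record")
}

## the flanking repeat a mechanism duplicates on integration
flank_repeat <- function(p) {
  if (p$mechanism == "transposition") p$target_dup else p$attP
}

#' @export
print.prophage_record <- function(x, ...) {
  cat(sprintf("<prophage_record> %s on %s [%d, %d) %s, %s bp\n",
              x$id, x$host_id, x$left, x$right, x$mechanism,
              format(nchar(x$genome), big.mark = ",")))
  invisible(x)
}

#' Lysogen: a host genome plus its integrated prophages
#'
#' @param host a [genome_record()].
#' @param prophages list of [prophage_record()]s with non-overlapping
#'   intervals, all on `host$id`.
#' @return object of class `lysogen`.
#' @export
lysogen <- function(host, prophages = list()) {
  stopifnot(inherits(host, "genome_record"))
  if (inherits(prophages, "prophage_record")) prophages <- list(prophages)
  for (p in prophages) {
    stopifnot(inherits(p, "prophage_record"))
    if (p$host_id != host$id)
      stop(sprintf("prophage '%s' host_id '%s' does not match host '%s'",
                   p$id, p$host_id, host$id), call. = FALSE)
    if (p$right > genome_length(host))
      stop(sprintf("prophage '%s' extends beyond the host chromosome", p$id),
           call. = FALSE)
  }
  if (length(prophages) > 1L) {
    iv <- t(vapply(prophages, function(p) c(p$left, p$right), numeric(2)))
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("prophage intervals overlap", call. = FALSE)
  }
  structure(list(host = host, prophages = prophages), class = "lysogen")
}

#' @export
print.lysogen <- function(x, ...) {
  cat(sprintf("<lysogen> host %s (%s bp), %d prophage(s)\n", x$host$id,
              format(genome_length(x$host), big.mark = ","),
              length(x$prophages)))
  for (p in x$prophages) print(p)
  invisible(x)
}

## FASTA --------------------------------------------------------------------

#' Read genomes from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()].  Sequences are
#' uppercased; characters outside A,C,G,T,N are rejected with a format
#' error.  Returns a single [genome_record()] for a one-record file, else a
#' list of records preserving file order.
#'
#' @param path FASTA file.
#' @param topology topology flag applied to every record.
#' @return `genome_record` or list thereof.
#' @export
read_genome <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop(sprintf(
                    "cannot parse FASTA '%s': %s", path, conditionMessage(e)),
                    call. = FALSE))
  if (length(set) == 0L) stop(sprintf("FASTA '%s' contains no records", path),
                              call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  recs <- lapply(seq_along(set), function(i)
    genome_record(ids[i], as.character(set[[i]]), topology))
  if (length(recs) == 1L) recs[[1]] else recs
}

#' Write genomes to FASTA
#'
#' @param x a `genome_record` or list of them.
#' @param path output path.
#' @export
write_genome <- function(x, path) {
  if (inherits(x, "genome_record")) x <- list(x)
  set <- Biostrings::DNAStringSet(vapply(x, `[[`, character(1), "sequence"))
  names(set) <- vapply(x, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## Reads (FASTA/FASTQ) ------------------------------------------------------

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is chosen by extension (`.fastq`/`.fq` vs anything else).
#'
#' @param path input file.
#' @return named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  as_read_vector(set)
}

#' Write reads to FASTA or FASTQ
#'
#' FASTQ output carries a constant quality line ("I" = Q40), matching the
#' simulator's error model in which quality strings carry no information.
#'
#' @param reads named character vector.
#' @param path output path; extension selects the format.
#' @export
write_reads <- function(reads, path) {
  reads <- as_read_vector(reads)
  set <- Biostrings::DNAStringSet(reads)
  names(set) <- names(reads)
  if (grepl("\\.(fastq|fq)$", path)) {
    qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
    Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  } else {
    Biostrings::writeXStringSet(set, path)
  }
  invisible(path)
}

## Annotations --------------------------------------------------------------

#' Read gene annotations
#'
#' Two dialects:
#' * a 5-column TSV with header `gene_id, start, end, strand, category`,
#'   coordinates 0-based half-open (this package's native schema);
#' * GFF3, converted from 1-based inclusive to 0-based half-open, with the
#'   functional category taken from a configurable attribute key (default
#'   `"subsystem"`); features lacking the key get `"hypothetical"`.
#'
#' @param path TSV or GFF3 file (dialect by extension: `.gff`, `.gff3`).
#' @param category_key GFF3 attribute holding the subsystem category.
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return data.frame with columns gene_id, start, end, strand, category.
#' @export
read_annotations <- function(path, category_key = "subsystem",
                             feature_type = "gene") {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path)
    md <- as.data.frame(gr)
    if (!is.null(feature_type) && "type" %in% names(md))
      md <- md[md$type %in% feature_type, , drop = FALSE]
    gene_id <- if ("ID" %in% names(md)) md$ID else
      if ("gene_id" %in% names(md)) md$gene_id else
        sprintf("gene_%05d", seq_len(nrow(md)))
    category <- if (category_key %in% names(md)) {
      cc <- as.character(md[[category_key]])
      cc[is.na(cc) | !nzchar(cc)] <- "hypothetical"
      cc
    } else rep("hypothetical", nrow(md))
    ann <- data.frame(gene_id = as.character(gene_id),
                      start = md$start - 1L, end = md$end,
                      strand = as.character(md$strand),
                      category = category, stringsAsFactors = FALSE)
    ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  } else {
    ann <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "start", "end", "strand", "category")
    if (!all(need %in% names(ann)))
      stop(sprintf("annotation TSV must have columns: %s",
                   paste(need, collapse = ", ")), call. = FALSE)
    ann <- ann[, need]
  }
  validate_annotations(ann)
  ann
}

validate_annotations <- function(ann, genome = NULL) {
  stopifnot(is.data.frame(ann))
  if (nrow(ann) == 0L) stop("empty annotation set", call. = FALSE)
  if (any(ann$start < 0) || any(ann$end <= ann$start))
    stop("annotation intervals must satisfy 0 <= start < end", call. = FALSE)
  if (anyDuplicated(ann$gene_id))
    stop("duplicate gene_id in annotations", call. = FALSE)
  if (!is.null(genome) && any(ann$end > genome_length(genome)))
    stop("annotation interval extends beyond the genome", call. = FALSE)
  invisible(ann)
}

#' Write gene annotations (native TSV dialect)
#' @param ann annotation data.frame.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Prophage records (JSON schema) ------------------------------------------

#' Read/write prophage records (JSON)
#'
#' The on-disk schema is a JSON array of objects with fields `id, host_id,
#' left, right, mechanism, genome, target_dup, attP, cos` (absent fields
#' null), coordinates 0-based half-open, so the duplication/attachment
#' bookkeeping is explicit rather than inferred.
#'
#' @param path JSON file.
#' @return list of [prophage_record()]s.
#' @export
read_prophages <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(r)
    prophage_record(r$id, r$host_id, r$left, r$right, r$mechanism, r$genome,
                    target_dup = r$target_dup %||% NULL,
                    attP = r$attP %||% NULL, cos = r$cos %||% NULL))
}

#' @rdname read_prophages
#' @param prophages list of prophage records.
#' @export
write_prophages <- function(prophages, path) {
  if (inherits(prophages, "prophage_record")) prophages <- list(prophages)
  jsonlite::write_json(lapply(prophages, unclass), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

## attB reference reconstruction & masking ----------------------------------

#' Reconstruct the prophage-free (attB) reference chromosome
#'
#' Removes every prophage genome from the host chromosome while preserving
#' the natural attachment site.  For transposition-type prophages the 5-bp
#' target duplication flanking the prophage is collapsed back to a single
#' copy; for site-specific prophages the duplicated attachment core
#' (attL/attR) is collapsed to one attB copy.  Inverse of the simulator's
#' `integrate` step: on synthetic lysogens the original naive chromosome is
#' recovered bit-exactly.
#'
#' @param lys a [lysogen()].
#' @return a `genome_record` named `<host_id>_attB`.
#' @export
reconstruct_attB_reference <- function(lys) {
  stopifnot(inherits(lys, "lysogen"))
  seq <- lys$host$sequence
  if (length(lys$prophages) == 0L)
    return(genome_record(lys$host$id, seq, lys$host$topology))
  ord <- order(vapply(lys$prophages, `[[`, integer(1), "left"),
               decreasing = TRUE)
  for (p in lys$prophages[ord]) {
    rep_seq <- flank_repeat(p)
    w <- nchar(rep_seq)
    if (p$left - w < 0 || p$right + w > nchar(seq))
      stop(sprintf("prophage '%s' flanking repeat runs off the chromosome", p$id),
           call. = FALSE)
    up <- substr(seq, p$left - w + 1L, p$left)
    down <- substr(seq, p$right + 1L, p$right + w)
    if (up != rep_seq || down != rep_seq)
      stop(sprintf(
        "prophage '%s': flanking sequences do not both equal the recorded %s ('%s')",
        p$id, if (p$mechanism == "transposition") "target duplication" else "attP core",
        rep_seq), call. = FALSE)
    if (substr(seq, p$left + 1L, p$right) != p$genome)
      stop(sprintf("prophage '%s' genome does not match host[left:right)", p$id),
           call. = FALSE)
    ## delete the prophage plus the downstream repeat copy -> one attB copy left
    seq <- paste0(substr(seq, 1L, p$left), substr(seq, p$right + w + 1L, nchar(seq)))
  }
  genome_record(paste0(lys$host$id, "_attB"), seq, lys$host$topology)
}

#' Mask chromosome intervals with N
#'
#' Replaces every position in the given 0-based half-open intervals with
#' `N`, leaving the length unchanged -- the standard prophage-masking step
#' before read recruitment, so masked regions contribute neither motif
#' matches nor exact-match flap hits.
#'
#' @param genome a `genome_record`.
#' @param intervals data.frame/matrix with columns `start`, `end`
#'   (0-based half-open); an empty set of intervals is the identity.
#' @return masked `genome_record`.
#' @export
mask_regions <- function(genome, intervals) {
  stopifnot(inherits(genome, "genome_record"))
  intervals <- as.data.frame(intervals)
  if (nrow(intervals) == 0L) return(genome)
  stopifnot(all(c("start", "end") %in% names(intervals)))
  L <- genome_length(genome)
  if (any(intervals$start < 0) || any(intervals$end > L) ||
      any(intervals$end < intervals$start))
    stop("mask interval out of bounds", call. = FALSE)
  ch <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(intervals))) {
    s <- intervals$start[i]; e <- intervals$end[i]
    if (e > s) ch[(s + 1L):e] <- "N"
  }
  genome_record(genome$id, paste0(ch, collapse = ""), genome$topology)
}

#' Read mask intervals from BED
#'
#' BED is already 0-based half-open; returned as a data.frame usable by
#' [mask_regions()].
#'
#' @param path BED file.
#' @return data.frame with columns chrom, start, end.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- as.data.frame(gr)
  data.frame(chrom = as.character(df$seqnames), start = df$start - 1L,
             end = df$end, stringsAsFactors = FALSE)
}
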