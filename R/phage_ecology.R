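## phage_ecology: length-normalized relative abundance of co-induced
## phages, RPKM, abundance filtering, virus-to-host ratios, and log-log
## slope classification for Piggyback-the-Winner inference.

#' Length-normalized relative abundance
#'
#' Given per-entity mapped read counts and genome lengths (weight =
#' reads/length) or pre-computed per-entity coverages (weight = coverage),
#' returns fractions summing to 1.  This is the statistic used to compare
#' phages co-induced from a polylysogen.
#'
#' @param entities data.frame with column `id` plus either `coverage` or
#'   both `mapped_reads` and `length`.
#' @return the data.frame with `weight` and `fraction` columns added.
#' @export
relative_abundance <- function(entities) {
  stopifnot(is.data.frame(entities), "id" %in% names(entities))
  if ("coverage" %in% names(entities)) {
    w <- entities$coverage
  } else if (all(c("mapped_reads", "length") %in% names(entities))) {
    stopifnot(all(entities$length > 0))
    w <- entities$mapped_reads / entities$length
  } else {
    stop("entities need either a 'coverage' column or 'mapped_reads' + 'length'",
         call. = FALSE)
  }
  if (any(w < 0)) stop("negative abundance weight", call. = FALSE)
  if (sum(w) == 0) stop("all abundance weights are zero", call. = FALSE)
  entities$weight <- w
  entities$fraction <- w / sum(w)
  entities
}

#' RPKM: reads per kb of genome per Mbp of metagenomic sample
#'
#' `rpkm = mapped_reads / (entity_length / 1e3) / (sample_size / 1e6)`,
#' with `sample_size` the total base pairs of the (quality-filtered)
#' metagenomic sample.
#'
#' @param mapped_reads numeric vector of read counts.
#' @param entity_length_bp genome/contig length in bp (>= 1).
#' @param sample_size_bp metagenome size in bp (>= 1).
#' @return numeric RPKM values.
#' @export
rpkm <- function(mapped_reads, entity_length_bp, sample_size_bp) {
  if (any(entity_length_bp < 1) || any(sample_size_bp < 1))
    stop("entity_length_bp and sample_size_bp must be >= 1", call. = FALSE)
  if (any(mapped_reads < 0)) stop("mapped_reads must be >= 0", call. = FALSE)
  mapped_reads / (entity_length_bp / 1e3) / (sample_size_bp / 1e6)
}

#' Abundance filter: strict RPKM thresholds by entity type
#'
#' Hosts are retained iff RPKM > 0.1, prophages iff RPKM > 0.01 (strict
#' inequalities).  Idempotent.
#'
#' @param records data.frame with columns `entity_type` (`"host"` /
#'   `"prophage"`) and `rpkm`.
#' @param host_min,prophage_min thresholds, defaults 0.1 and 0.01.
#' @return the retained rows.
#' @export
filter_records <- function(records, host_min = 0.1, prophage_min = 0.01) {
  stopifnot(all(c("entity_type", "rpkm") %in% names(records)))
  keep <- (records$entity_type == "host" & records$rpkm > host_min) |
    (records$entity_type == "prophage" & records$rpkm > prophage_min)
  records[keep, , drop = FALSE]
}

#' Pair cellular and virion fractions by station
#'
#' For each station with a cellular-fraction host record and a
#' virion-fraction prophage record that both pass [filter_records()], emits
#' one row with the virus-to-host ratio `VHR = phage_rpkm / host_rpkm`.
#' Stations missing either fraction (or either entity) are dropped; an
#' empty result is allowed.
#'
#' @param records data.frame with columns station, fraction
#'   (`"cellular"`/`"virion"`), entity_id, entity_type, rpkm.
#' @param apply_filter apply the RPKM thresholds first (default `TRUE`).
#' @return data.frame: station, host_id, phage_id, host_rpkm, phage_rpkm,
#'   vhr.
#' @export
pair_stations <- function(records, apply_filter = TRUE) {
  need <- c("station", "fraction", "entity_id", "entity_type", "rpkm")
  stopifnot(all(need %in% names(records)))
  if (apply_filter) records <- filter_records(records)
  hosts <- records[records$entity_type == "host" &
                     records$fraction == "cellular", , drop = FALSE]
  phages <- records[records$entity_type == "prophage" &
                      records$fraction == "virion", , drop = FALSE]
  common <- intersect(unique(hosts$station), unique(phages$station))
  rows <- lapply(common, function(st) {
    h <- hosts[hosts$station == st, , drop = FALSE][1, ]
    p <- phages[phages$station == st, , drop = FALSE][1, ]
    data.frame(station = st, host_id = h$entity_id, phage_id = p$entity_id,
               host_rpkm = h$rpkm, phage_rpkm = p$rpkm,
               vhr = p$rpkm / h$rpkm, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(station = character(0), host_id = character(0),
                      phage_id = character(0), host_rpkm = numeric(0),
                      phage_rpkm = numeric(0), vhr = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Spearman that tolerates zero-variance input (rho := 0, p := 1).
safe_spearman <- function(x, y) {
  if (length(x) < 3L || stats::sd(x) < 1e-10 || stats::sd(y) < 1e-10)
    return(list(rho = 0, p = 1))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Log-log abundance slope and Piggyback-the-Winner classification
#'
#' Fits ordinary least squares to (log10 host RPKM, log10 phage RPKM),
#' i.e. the power law `phage ~ host^slope`.  Classification uses the 95%
#' confidence interval of the slope:
#' * `sublinear` -- CI within (0, 1): phage abundance grows less than
#'   proportionally with host abundance, the PtW signature;
#' * `linear` -- CI contains 1 and excludes 0;
#' * `superlinear` -- CI lower bound > 1;
#' * `indeterminate` otherwise.
#'
#' Spearman rank correlations (average ranks on ties) are reported for
#' phage~host and VHR~host; under sublinear scaling VHR falls with host
#' abundance, so the second correlation is negative.
#'
#' @param pairs data.frame from [pair_stations()] (needs host_rpkm,
#'   phage_rpkm, vhr; >= 3 rows).
#' @param conf confidence level for the slope CI, default 0.95.
#' @return object of class `ptw_result`: n_stations, slope, ci,
#'   slope_class, spearman_phage_host, spearman_vhr_host, fit.
#' @export
loglog_slope <- function(pairs, conf = 0.95) {
  stopifnot(is.data.frame(pairs),
            all(c("host_rpkm", "phage_rpkm", "vhr") %in% names(pairs)))
  if (nrow(pairs) < 3L)
    stop("need at least 3 paired stations to fit a slope", call. = FALSE)
  if (any(pairs$host_rpkm <= 0) || any(pairs$phage_rpkm <= 0))
    stop("log-log fit requires strictly positive abundances", call. = FALSE)
  x <- log10(pairs$host_rpkm)
  y <- log10(pairs$phage_rpkm)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  ci <- suppressWarnings(confint(fit, "x", level = conf))
  ci <- as.numeric(ci)
  if (anyNA(ci)) ci <- c(slope, slope)  # zero residual variance
  slope_class <- if (ci[1] > 0 && ci[2] < 1) "sublinear"
  else if (ci[1] > 1) "superlinear"
  else if (ci[1] > 0 && ci[1] <= 1 && ci[2] >= 1) "linear"
  else "indeterminate"
  structure(list(
    n_stations = nrow(pairs),
    slope = slope,
    ci = ci,
    slope_class = slope_class,
    spearman_phage_host = safe_spearman(x, y),
    spearman_vhr_host = safe_spearman(x, log10(pairs$vhr)),
    fit = fit), class = "ptw_result")
}

#' @export
print.ptw_result <- function(x, ...) {
  cat(sprintf(
    "<ptw_result> n = %d stations; slope = %.3f [%.3f, %.3f] (%s)\n",
    x$n_stations, x$slope, x$ci[1], x$ci[2], x$slope_class))
  cat(sprintf("  Spearman phage~host: rho = %.3f (p = %.3g)\n",
              x$spearman_phage_host$rho, x$spearman_phage_host$p))
  cat(sprintf("  Spearman VHR~host:   rho = %.3f (p = %.3g)\n",
              x$spearman_vhr_host$rho, x$spearman_vhr_host$p))
  invisible(x)
}

#' Read a per-sample abundance count table (TSV)
#'
#' Native schema: sample_id, station, fraction, entity_id, entity_type,
#' mapped_reads, entity_length, sample_size_bp.  RPKM is computed on read.
#'
#' @param path TSV file.
#' @return data.frame with an `rpkm` column added.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "station", "fraction", "entity_id", "entity_type",
            "mapped_reads", "entity_length", "sample_size_bp")
  if (!all(need %in% names(df)))
    stop(sprintf("count table must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  df$rpkm <- rpkm(df$mapped_reads, df$entity_length, df$sample_size_bp)
  df
}
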