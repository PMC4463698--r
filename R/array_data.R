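#' Read a tiling-array probe table
#'
#' Reads a tab-separated probe (reporter) table with columns `probe_id`,
#' `chrom`, `start`, `length` and optionally `n_genomic_hits` (defaults to 1
#' when absent). Coordinates are 1-based inclusive, genome-browser style.
#' Duplicated identical `(probe_id, chrom, start)` rows collapse to one.
#'
#' @param path Path to a TSV file with a header row.
#' @param coord_map Optional coordinate remapping, either a two-column
#'   data.frame (`old`, `new`) or a path to a headered two-column TSV.
#'   Applied to `start` at load; probes without a mapping are dropped and
#'   counted in the `"n_unmapped"` attribute of the result.
#' @return A data.frame of probes sorted by `(chrom, start)` with columns
#'   `probe_id`, `chrom`, `start`, `length`, `n_genomic_hits`.
#' @export
read_probe_table <- function(path, coord_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("probe_id", "chrom", "start", "length")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L)
    stop("probe table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"n_genomic_hits" %in% names(tab))
    tab$n_genomic_hits <- "1"

  parse_int <- function(col, what) {
    suppressWarnings(v <- as.integer(col))
    bad <- which(is.na(v) | is.na(col) | col == "")
    if (length(bad) > 0L)
      stop("malformed ", what, " in probe table line ", bad[1L] + 1L,
           " of ", path)  # +1 for the header line
    v
  }
  probes <- data.frame(
    probe_id = tab$probe_id,
    chrom = tab$chrom,
    start = parse_int(tab$start, "start"),
    length = parse_int(tab$length, "length"),
    n_genomic_hits = parse_int(tab$n_genomic_hits, "n_genomic_hits"),
    stringsAsFactors = FALSE)

  if (any(probes$probe_id == ""))
    stop("empty probe_id in probe table ", path)
  if (any(probes$start < 1L))
    stop("probe start < 1 (coordinates are 1-based) in probe table ", path,
         ": ", probes$probe_id[which(probes$start < 1L)[1L]])
  if (any(probes$length < 1L))
    stop("probe length < 1 in probe table ", path)

  probes <- unique(probes)
  key <- paste(probes$probe_id, probes$chrom, probes$start)
  if (anyDuplicated(key))
    stop("conflicting duplicate (probe_id, chrom, start) rows in ", path)

  n_unmapped <- 0L
  if (!is.null(coord_map)) {
    if (is.character(coord_map))
      coord_map <- utils::read.delim(coord_map, stringsAsFactors = FALSE)
    m <- match(probes$start, coord_map[[1L]])
    n_unmapped <- sum(is.na(m))
    probes <- probes[!is.na(m), , drop = FALSE]
    probes$start <- as.integer(coord_map[[2L]][m[!is.na(m)]])
  }

  probes <- probes[order(probes$chrom, probes$start, probes$probe_id), ,
                   drop = FALSE]
  rownames(probes) <- NULL
  attr(probes, "n_unmapped") <- n_unmapped
  probes
}

#' Read a one-channel intensity table
#'
#' @param path TSV with header columns `probe_id` and `signal`
#'   (fluorescence units).
#' @return A data.frame with columns `probe_id`, `signal`.
#' @export
read_intensity_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "signal") %in% names(tab)))
    stop("intensity table ", path, " needs columns probe_id, signal")
  data.frame(probe_id = as.character(tab$probe_id),
             signal = as.numeric(tab$signal),
             stringsAsFactors = FALSE)
}

#' Compute per-probe log2 IP/input ratios
#'
#' Joins the two channels on `probe_id` and computes
#' `log_ratio = log2(ip_signal / input_signal)`. Probes present in only one
#' channel are dropped; the number dropped is recorded in the
#' `"n_dropped"` attribute.
#'
#' @param ip,input Data.frames with columns `probe_id`, `signal` (or named
#'   numeric vectors keyed by probe id).
#' @return Data.frame with columns `probe_id`, `ip_signal`, `input_signal`,
#'   `log_ratio`.
#' @export
compute_log_ratios <- function(ip, input) {
  as_tab <- function(x) {
    if (is.numeric(x) && !is.null(names(x)))
      x <- data.frame(probe_id = names(x), signal = unname(x),
                      stringsAsFactors = FALSE)
    x
  }
  ip <- as_tab(ip); input <- as_tab(input)
  shared <- intersect(ip$probe_id, input$probe_id)
  n_dropped <- (nrow(ip) - length(shared)) + (nrow(input) - length(shared))
  ipv <- ip$signal[match(shared, ip$probe_id)]
  inv <- input$signal[match(shared, input$probe_id)]
  bad <- which(!(ipv > 0) | !(inv > 0))
  if (length(bad) > 0L)
    stop("nonpositive signal for probe ", shared[bad[1L]])
  res <- data.frame(probe_id = shared, ip_signal = ipv, input_signal = inv,
                    log_ratio = log2(ipv / inv), stringsAsFactors = FALSE)
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Remove non-uniquely mapping probes
#'
#' Keeps only reporters mapping to a single genomic location
#' (`n_genomic_hits == 1`), the standard guard against cross-hybridizing
#' probes seeding false enrichment.
#'
#' @param probes Probe data.frame (see [read_probe_table()]).
#' @return A list with `kept` (the unique probes), `removed_count` and
#'   `removed_fraction` (0 for empty input).
#' @export
filter_unique_probes <- function(probes) {
  keep <- probes$n_genomic_hits == 1L
  removed <- sum(!keep)
  list(kept = probes[keep, , drop = FALSE],
       removed_count = removed,
       removed_fraction = if (nrow(probes) == 0L) 0 else removed / nrow(probes))
}

#' Bundle probes, intensities and experiment labels
#'
#' @param probes Probe data.frame.
#' @param intensities Log-ratio data.frame from [compute_log_ratios()].
#' @param antibody,pool Free-text labels (e.g. antibody target and sample
#'   pool such as "AAA Pool" / "Control Pool").
#' @return An object of class `array_dataset`.
#' @export
array_dataset <- function(probes, intensities, antibody = NA_character_,
                          pool = NA_character_) {
  orphan <- setdiff(intensities$probe_id, probes$probe_id)
  if (length(orphan) > 0L)
    stop("intensities refer to unknown probe_id(s), e.g. ", orphan[1L])
  structure(list(probes = probes, intensities = intensities,
                 antibody = antibody, pool = pool),
            class = "array_dataset")
}

#' @export
print.array_dataset <- function(x, ...) {
  cat("ChIP-chip array dataset\n")
  cat("  probes:      ", nrow(x$probes), "\n")
  cat("  intensities: ", nrow(x$intensities), "\n")
  cat("  antibody:    ", x$antibody, "   pool: ", x$pool, "\n")
  invisible(x)
}

#' Write a probe table
#'
#' Inverse of [read_probe_table()]; round-trips the probe data model.
#'
#' @param probes Probe data.frame.
#' @param path Output TSV path.
#' @export
write_probe_table <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export probe positions as BED6
#'
#' BED is 0-based half-open; the BED score column holds
#' `round(log_ratio * 1000)` clamped to [0, 1000] (full precision belongs in
#' TSV exports, not BED).
#'
#' @param probes Probe data.frame.
#' @param ratios Log-ratio data.frame ([compute_log_ratios()]).
#' @param path Output BED path.
#' @export
export_probes_bed <- function(probes, ratios, path) {
  lr <- ratios$log_ratio[match(probes$probe_id, ratios$probe_id)]
  score <- pmin(1000, pmax(0, round(lr * 1000)))
  score[is.na(score)] <- 0
  gr <- GenomicRanges::GRanges(
    seqnames = probes$chrom,
    ranges = IRanges::IRanges(start = probes$start,
                              width = probes$length),
    name = probes$probe_id, score = score)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
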