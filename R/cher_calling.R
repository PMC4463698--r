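# Runs are maximal stretches of consecutive track rows (within one
# chromosome) whose smoothed value strictly exceeds a level; NA breaks a run.
runs_above <- function(track, level, min_probes) {
  out <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    above <- !is.na(t$smoothed) & t$smoothed > level
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_probes
    if (!any(keep)) next
    s <- starts[keep]; e <- ends[keep]
    out[[ch]] <- data.frame(
      chrom = ch,
      start = t$position[s], end = t$position[e],
      n_probes = e - s + 1L,
      max_value = vapply(seq_along(s),
                         function(i) max(t$smoothed[s[i]:e[i]]), 0),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      max_value = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enumerate candidate enriched runs
#'
#' Maximal stretches of at least `min_probes` consecutive probes whose
#' smoothed value strictly exceeds `floor_value`. Used both to build the
#' candidate-run distribution behind the quantile threshold and to audit
#' the null promotion rate on spike-free data.
#'
#' @param track A `smoothed_track` data.frame ([smooth_track()]).
#' @param floor_value Enrichment floor in log2 units.
#' @param min_probes Minimum run length (default 7).
#' @return Data.frame with columns `chrom`, `start`, `end`, `n_probes`,
#'   `max_value` (maximum smoothed value in the run).
#' @export
candidate_runs <- function(track, floor_value, min_probes = 7) {
  runs_above(track, floor_value, min_probes)
}

#' Compute the enrichment threshold y0
#'
#' The threshold is the top `quantile` (default 99th percentile, i.e. top
#' 1%) of the smoothed enrichment distribution, computed with linear
#' interpolation between order statistics. Two readings of "the
#' distribution" are supported:
#'
#' * `floor_quantile = NA` (default): the quantile of all non-missing
#'   smoothed values.
#' * `floor_quantile` set (e.g. 0.5): a two-pass scheme — candidate runs
#'   are enumerated above the `floor_quantile` percentile of the smoothed
#'   values, and y0 is the `quantile` percentile of the candidate runs'
#'   maximum levels. With fewer than 10 candidate runs this falls back to
#'   the all-values quantile (flagged in the `"method"` attribute).
#'
#' @param track A `smoothed_track` data.frame (several chromosomes allowed).
#' @param quantile Upper quantile defining y0 (default 0.99).
#' @param floor_quantile `NA` for the all-values quantile, else a
#'   proportion strictly between 0 and `quantile` enabling the
#'   candidate-run scheme.
#' @param min_probes Minimum run length for candidate enumeration.
#' @return y0 (numeric scalar) with attributes `method`
#'   (`"all_values"`, `"candidate_runs"` or `"fallback_all_values"`) and
#'   `n_candidates`.
#' @export
compute_threshold <- function(track, quantile = 0.99, floor_quantile = NA,
                              min_probes = 7) {
  if (!(quantile > 0 && quantile < 1))
    stop("quantile must be strictly between 0 and 1")
  vals <- track$smoothed[!is.na(track$smoothed)]
  if (length(vals) == 0L)
    stop("compute_threshold: all smoothed values are missing")
  if (is.na(floor_quantile)) {
    y0 <- unname(stats::quantile(vals, quantile, type = 7))
    attr(y0, "method") <- "all_values"
    attr(y0, "n_candidates") <- NA_integer_
    return(y0)
  }
  if (!(floor_quantile > 0 && floor_quantile < quantile))
    stop("floor_quantile must satisfy 0 < floor_quantile < quantile")
  floor_value <- unname(stats::quantile(vals, floor_quantile, type = 7))
  cand <- candidate_runs(track, floor_value, min_probes)
  if (nrow(cand) < 10L) {
    y0 <- unname(stats::quantile(vals, quantile, type = 7))
    attr(y0, "method") <- "fallback_all_values"
    attr(y0, "n_candidates") <- nrow(cand)
    message("compute_threshold: only ", nrow(cand),
            " candidate runs; falling back to the all-values quantile")
    return(y0)
  }
  y0 <- unname(stats::quantile(cand$max_value, quantile, type = 7))
  attr(y0, "method") <- "candidate_runs"
  attr(y0, "n_candidates") <- nrow(cand)
  y0
}

#' Call ChIP-enriched regions (chers)
#'
#' Three rules, applied in order: (i) find maximal runs of consecutive
#' probes with smoothed value strictly above `y0`; (ii) discard runs
#' shorter than `min_probes`; (iii) merge surviving runs on the same
#' chromosome whose separation (start of next minus end of previous) is
#' less than `merge_gap` bp — regions closer than the sonication-fragment
#' scale are not distinct binding events. Region start/end are the first
#' and last probe positions; `n_probes` counts above-threshold probes only
#' (a merged span may contain sub-threshold probes between runs).
#'
#' @param track A `smoothed_track` data.frame.
#' @param y0 Enrichment threshold in log2 units (see [compute_threshold()]).
#' @param min_probes Minimum probes per run (default 7).
#' @param merge_gap Minimum separation in bp between distinct regions
#'   (default 450).
#' @param antibody,pool Labels copied onto every emitted region.
#' @return A data.frame of chers: `cher_id`, `chrom`, `start`, `end`,
#'   `n_probes`, `max_peak`, `score`, `antibody`, `pool`. Zero rows when
#'   nothing exceeds the threshold.
#' @export
call_chers <- function(track, y0, min_probes = 7, merge_gap = 450,
                       antibody = NA_character_, pool = NA_character_) {
  y0 <- as.numeric(y0)
  if (!is.finite(y0)) stop("y0 must be finite")
  runs <- runs_above(track, y0, min_probes)
  empty <- data.frame(cher_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_probes = integer(0), max_peak = numeric(0),
                      score = numeric(0), antibody = character(0),
                      pool = character(0), stringsAsFactors = FALSE)
  if (nrow(runs) == 0L) return(empty)
  out <- list()
  for (ch in unique(runs$chrom)) {
    r <- runs[runs$chrom == ch, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(r$start[-1L] - r$end[-nrow(r)] >= merge_gap)))
    merged <- data.frame(
      chrom = ch,
      start = tapply(r$start, grp, min),
      end = tapply(r$end, grp, max),
      n_probes = as.integer(tapply(r$n_probes, grp, sum)),
      stringsAsFactors = FALSE)
    out[[ch]] <- merged
  }
  chers <- do.call(rbind, out)
  chers <- chers[order(chers$chrom, chers$start), , drop = FALSE]
  sc <- lapply(seq_len(nrow(chers)), function(i)
    score_cher(chers[i, ], track, y0))
  chers$max_peak <- vapply(sc, `[[`, 0, "max_peak")
  chers$score <- vapply(sc, `[[`, 0, "score")
  chers$cher_id <- sprintf("%s.cher%d", chers$chrom,
                           as.integer(stats::ave(seq_len(nrow(chers)),
                                                 chers$chrom,
                                                 FUN = seq_along)))
  chers$antibody <- antibody
  chers$pool <- pool
  rownames(chers) <- NULL
  chers[, c("cher_id", "chrom", "start", "end", "n_probes", "max_peak",
            "score", "antibody", "pool")]
}

#' Score a cher
#'
#' `score` is the sum of (smoothed - y0) over the region's above-threshold
#' probes — the enrichment mass above the threshold; `max_peak` is the
#' maximum smoothed value in the region span.
#'
#' @param cher A list or one-row data.frame with `chrom`, `start`, `end`.
#' @param track A `smoothed_track` data.frame.
#' @param y0 Enrichment threshold.
#' @return List with `score` and `max_peak`.
#' @export
score_cher <- function(cher, track, y0) {
  y0 <- as.numeric(y0)
  sel <- track$chrom == cher$chrom & track$position >= cher$start &
    track$position <= cher$end & !is.na(track$smoothed)
  v <- track$smoothed[sel]
  if (length(v) == 0L)
    stop("cher [", cher$chrom, ":", cher$start, "-", cher$end,
         "] contains no track probes")
  list(score = sum(pmax(v - y0, 0) * (v > y0)),
       max_peak = max(v))
}

#' Export chers
#'
#' Writes a full-precision TSV (Chr, CHER Start, CHER End, Max Peak, Score,
#' N Probes, Antibody, Pool) and optionally BED6 (score = cher score x 100,
#' clamped to [0, 1000] as BED requires).
#'
#' @param chers Cher data.frame from [call_chers()].
#' @param tsv_path,bed_path Output paths (`NULL` to skip either).
#' @export
export_chers <- function(chers, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    out <- data.frame(chr = chers$chrom, cher_start = chers$start,
                      cher_end = chers$end, max_peak = chers$max_peak,
                      score = chers$score, n_probes = chers$n_probes,
                      antibody = chers$antibody, pool = chers$pool)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path) && nrow(chers) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = chers$chrom,
      ranges = IRanges::IRanges(start = chers$start, end = chers$end),
      name = chers$cher_id,
      score = pmin(1000, pmax(0, round(chers$score * 100))))
    rtracklayer::export(gr, bed_path, format = "BED")
  } else if (!is.null(bed_path)) {
    writeLines(character(0), bed_path)
  }
  invisible(chers)
}

#' Plot a smoothed track with called regions
#'
#' @param track A `smoothed_track` data.frame (one chromosome is clearest).
#' @param chers Optional cher data.frame to shade.
#' @param y0 Optional threshold to draw.
#' @param chrom Chromosome to show (default: first in the track).
#' @param ... Passed to [graphics::plot()].
#' @export
plot_track <- function(track, chers = NULL, y0 = NULL, chrom = NULL, ...) {
  if (is.null(chrom)) chrom <- track$chrom[1L]
  t <- track[track$chrom == chrom, , drop = FALSE]
  graphics::plot(t$position, t$smoothed, type = "l", xlab = "position (bp)",
                 ylab = "smoothed log2 ratio", main = chrom, ...)
  graphics::points(t$position, t$value, pch = ".", col = "grey50")
  if (!is.null(y0))
    graphics::abline(h = as.numeric(y0), col = "red", lty = 2)
  if (!is.null(chers) && nrow(chers) > 0L) {
    ch <- chers[chers$chrom == chrom, , drop = FALSE]
    if (nrow(ch) > 0L)
      graphics::rect(ch$start, graphics::par("usr")[3L], ch$end,
                     graphics::par("usr")[4L],
                     col = grDevices::adjustcolor("orange", 0.2), border = NA)
  }
  invisible(track)
}
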