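#' One-step Tukey-biweight location estimate
#'
#' Robust centre of a set of log ratios: values are weighted by
#' `w = (1 - u^2)^2` for `|u| < 1` (0 otherwise), where
#' `u = (x - median) / (c * MAD + eps)` and MAD is the unscaled median
#' absolute deviation. With a degenerate MAD all weights can vanish, in
#' which case the median is returned.
#'
#' @param x Numeric vector (log2 ratios); non-finite values are ignored.
#' @param c Tuning constant (default 5, the conventional one-step array
#'   estimator).
#' @param eps Guard against zero MAD (default 1e-4).
#' @return The weighted location estimate, a scalar.
#' @export
tukey_biweight_location <- function(x, c = 5, eps = 1e-4) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    stop("tukey_biweight_location: no finite values")
  med <- stats::median(x)
  mad_raw <- stats::median(abs(x - med))
  u <- (x - med) / (c * mad_raw + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  if (sum(w) == 0) return(med)
  sum(w * x) / sum(w)
}

#' Tukey-biweight scale normalization of log ratios
#'
#' Centres the per-probe log2 ratios on their Tukey-biweight location, so
#' that the bulk of (unenriched) probes sits at zero. Idempotent: the
#' biweight centre of the normalized values is ~0.
#'
#' @param x Numeric vector of raw log2 ratios, optionally named by probe id.
#' @inheritParams tukey_biweight_location
#' @return A list with `location_estimate` and `normalized` (same names and
#'   order as `x`).
#' @export
normalize_log_ratios <- function(x, c = 5, eps = 1e-4) {
  loc <- tukey_biweight_location(x, c = c, eps = eps)
  list(location_estimate = loc, normalized = x - loc)
}

#' Position-window running median
#'
#' Smooths normalized log ratios along a chromosome: the smoothed value at
#' probe position p is the median over all probes within `half_window` bp of
#' p (a centred window of total span `2 * half_window`). Windows holding
#' fewer than `min_probes` probes yield `NA`, so sparse stretches cannot
#' seed enriched regions off single probes.
#'
#' @param positions Strictly increasing integer vector of probe positions
#'   (one chromosome).
#' @param values Numeric vector of normalized log ratios, same length.
#' @param half_window Half window span in bp (default 450, i.e. a 900-bp
#'   window).
#' @param min_probes Minimum probes per window (default 7).
#' @return Numeric vector of smoothed values (`NA` where the window was too
#'   sparse).
#' @export
running_median <- function(positions, values, half_window = 450,
                           min_probes = 7) {
  if (length(positions) != length(values))
    stop("positions and values differ in length")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing within a chromosome")
  n <- length(positions)
  if (n == 0L) return(numeric(0))
  # window [p - hw, p + hw], inclusive on both ends
  lo <- findInterval(positions - half_window - 0.5, positions) + 1L
  hi <- findInterval(positions + half_window + 0.5 - 1e-9, positions)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    k <- hi[i] - lo[i] + 1L
    if (k < min_probes) next
    w <- values[lo[i]:hi[i]]
    h <- (k + 1L) %/% 2L
    if (k %% 2L == 1L) {
      out[i] <- sort(w, partial = h)[h]
    } else {                      # even count: mean of the two central values
      sw <- sort(w, partial = c(h, h + 1L))
      out[i] <- (sw[h] + sw[h + 1L]) / 2
    }
  }
  out
}

#' Build a smoothed enrichment track
#'
#' Applies [running_median()] per chromosome to a probe-level table of
#' normalized log ratios.
#'
#' @param probe_values Data.frame with columns `probe_id`, `chrom`,
#'   `position` and `value` (normalized log ratio).
#' @inheritParams running_median
#' @return A `smoothed_track` data.frame: the input plus a `smoothed`
#'   column, sorted by `(chrom, position)`; window parameters are stored as
#'   attributes.
#' @export
smooth_track <- function(probe_values, half_window = 450, min_probes = 7) {
  need <- c("probe_id", "chrom", "position", "value")
  if (!all(need %in% names(probe_values)))
    stop("probe_values needs columns ", paste(need, collapse = ", "))
  pv <- probe_values[order(probe_values$chrom, probe_values$position), ,
                     drop = FALSE]
  pv$smoothed <- NA_real_
  for (ch in unique(pv$chrom)) {
    sel <- pv$chrom == ch
    pv$smoothed[sel] <- running_median(pv$position[sel], pv$value[sel],
                                       half_window = half_window,
                                       min_probes = min_probes)
  }
  rownames(pv) <- NULL
  attr(pv, "half_window") <- half_window
  attr(pv, "min_probes") <- min_probes
  class(pv) <- c("smoothed_track", "data.frame")
  pv
}

#' From raw channels to a smoothed track in one call
#'
#' Convenience wrapper chaining the standard preprocessing: drop
#' non-unique probes, compute log2 IP/input ratios, Tukey-biweight
#' normalize, and smooth with the position-window running median.
#'
#' @param probes Probe data.frame ([read_probe_table()]).
#' @param ip,input Intensity data.frames (`probe_id`, `signal`).
#' @inheritParams running_median
#' @return A `smoothed_track` data.frame; the normalization location
#'   estimate and the non-unique removal count are attached as attributes
#'   `"location_estimate"` and `"n_removed_nonunique"`.
#' @export
build_track <- function(probes, ip, input, half_window = 450,
                        min_probes = 7) {
  flt <- filter_unique_probes(probes)
  ratios <- compute_log_ratios(ip, input)
  ratios <- ratios[ratios$probe_id %in% flt$kept$probe_id, , drop = FALSE]
  nr <- normalize_log_ratios(stats::setNames(ratios$log_ratio,
                                             ratios$probe_id))
  m <- match(ratios$probe_id, flt$kept$probe_id)
  track <- smooth_track(
    data.frame(probe_id = ratios$probe_id, chrom = flt$kept$chrom[m],
               position = flt$kept$start[m],
               value = unname(nr$normalized), stringsAsFactors = FALSE),
    half_window = half_window, min_probes = min_probes)
  attr(track, "location_estimate") <- nr$location_estimate
  attr(track, "n_removed_nonunique") <- flt$removed_count
  track
}

#' Export a smoothed track
#'
#' Writes the full-precision TSV (probe_id, chrom, pos, raw, normalized,
#' smoothed) and optionally a bedGraph of the smoothed values (0-based
#' half-open intervals of width 1 at probe positions; NA values omitted).
#'
#' @param track `smoothed_track` data.frame.
#' @param raw Optional numeric vector of raw log ratios aligned with the
#'   track rows.
#' @param tsv_path,bedgraph_path Output paths (`NULL` to skip either).
#' @export
export_track <- function(track, raw = NULL, tsv_path = NULL,
                         bedgraph_path = NULL) {
  if (!is.null(tsv_path)) {
    out <- data.frame(probe_id = track$probe_id, chrom = track$chrom,
                      pos = track$position,
                      raw = if (is.null(raw)) NA_real_ else raw,
                      normalized = track$value, smoothed = track$smoothed)
    utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bedgraph_path)) {
    keep <- !is.na(track$smoothed)
    gr <- GenomicRanges::GRanges(
      seqnames = track$chrom[keep],
      ranges = IRanges::IRanges(start = track$position[keep], width = 1L),
      score = track$smoothed[keep])
    rtracklayer::export(gr, bedgraph_path, format = "bedGraph")
  }
  invisible(track)
}
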