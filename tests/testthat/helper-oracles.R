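# Independent brute-force oracles. These deliberately re-derive every
# quantity with literal loops over the definitions, so they share no code
# path with the package implementation.

oracle_tukey_biweight <- function(x, c = 5, eps = 1e-4) {
  x <- x[is.finite(x)]
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0) {
    s <- sort(x)
    med <- (s[length(x) / 2] + s[length(x) / 2 + 1]) / 2
  }
  devs <- sort(abs(x - med))
  mad_raw <- devs[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0)
    mad_raw <- (devs[length(x) / 2] + devs[length(x) / 2 + 1]) / 2
  num <- 0; den <- 0
  for (xi in x) {
    u <- (xi - med) / (c * mad_raw + eps)
    w <- if (abs(u) < 1) (1 - u^2)^2 else 0
    num <- num + w * xi
    den <- den + w
  }
  if (den == 0) med else num / den
}

oracle_median <- function(w) {
  s <- sort(w); k <- length(w)
  if (k %% 2 == 1) s[(k + 1) / 2] else (s[k / 2] + s[k / 2 + 1]) / 2
}

oracle_running_median <- function(positions, values, half_window = 450,
                                  min_probes = 7) {
  n <- length(positions)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- values[abs(positions - positions[i]) <= half_window]
    if (length(w) >= min_probes) out[i] <- oracle_median(w)
  }
  out
}

# linear-interpolation percentile between order statistics
oracle_percentile <- function(x, q) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * q + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# literal run enumeration + three-rule cher caller
oracle_call_chers <- function(track, y0, min_probes = 7, merge_gap = 450) {
  res <- list()
  for (ch in unique(track$chrom)) {
    t <- track[track$chrom == ch, , drop = FALSE]
    t <- t[order(t$position), , drop = FALSE]
    runs <- list()
    cur <- integer(0)
    for (i in seq_len(nrow(t))) {
      above <- !is.na(t$smoothed[i]) && t$smoothed[i] > y0
      if (above) cur <- c(cur, i)
      if ((!above || i == nrow(t)) && length(cur) > 0) {
        if (length(cur) >= min_probes) runs[[length(runs) + 1]] <- cur
        cur <- integer(0)
      }
    }
    if (length(runs) == 0) next
    # merge runs whose probe-position gap is < merge_gap
    groups <- list(runs[[1]])
    if (length(runs) > 1) for (r in runs[-1]) {
      last <- groups[[length(groups)]]
      gap <- t$position[r[1]] - t$position[last[length(last)]]
      if (gap < merge_gap) groups[[length(groups)]] <- c(last, r)
      else groups[[length(groups) + 1]] <- r
    }
    for (g in groups) {
      span <- t$position >= t$position[g[1]] &
        t$position <= t$position[g[length(g)]]
      v <- t$smoothed[span]
      v <- v[!is.na(v)]
      score <- 0
      for (vi in v) if (vi > y0) score <- score + (vi - y0)
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = t$position[g[1]],
        end = t$position[g[length(g)]], n_probes = length(g),
        max_peak = max(v), score = score, stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      max_peak = numeric(0), score = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# full-enumeration upper-tail hypergeometric probability
oracle_hypergeom <- function(k, K, n, N) {
  total <- choose(N, n)
  acc <- 0
  for (j in k:min(K, n))
    acc <- acc + choose(K, j) * choose(N - K, n - j)
  acc / total
}

# literal BH step-up: sort ascending, q_i = min_{j>=i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * p[o[j]] / j)
    q[o[i]] <- min(best, 1)
  }
  q
}

# literal Match-style scores
oracle_info <- function(freqs) {
  apply(freqs, 2, function(f) sum(ifelse(f > 0, f * log(4 * f), 0)))
}

oracle_similarity <- function(freqs, info, seq_chars, positions) {
  cur <- 0; mn <- 0; mx <- 0
  for (i in positions) {
    b <- match(seq_chars[i], c("A", "C", "G", "T"))
    cur <- cur + info[i] * freqs[b, i]
    mn <- mn + info[i] * min(freqs[, i])
    mx <- mx + info[i] * max(freqs[, i])
  }
  unname((cur - mn) / (mx - mn))
}

oracle_core_window <- function(info) {
  best <- -Inf; at <- 1
  for (i in 1:(length(info) - 4)) {
    s <- sum(info[i:(i + 4)])
    if (s > best + 1e-12) { best <- s; at <- i }
  }
  at
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# exhaustive both-strand window scan with css-then-mss filtering
oracle_scan <- function(p, seq, css_cut, mss_cut) {
  freqs <- p$freqs; info <- oracle_info(freqs)
  core <- oracle_core_window(info)
  L <- ncol(freqs)
  hits <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) toupper(seq) else oracle_revcomp(toupper(seq))
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    if (n < L) next
    for (j in 1:(n - L + 1)) {
      win <- chars[j:(j + L - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      css <- oracle_similarity(freqs, info, win, core:(core + 4))
      mss <- oracle_similarity(freqs, info, win, 1:L)
      if (css >= css_cut && mss >= mss_cut) {
        pos <- if (strand == 1L) j else n - j - L + 2L
        hits[[length(hits) + 1]] <- data.frame(
          position = pos, strand = strand, mss = mss, css = css)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(position = integer(0), strand = integer(0),
                      mss = numeric(0), css = numeric(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# BFS shortest-path levels from the roots (roots at level 1)
oracle_levels <- function(edges, ids) {
  parents <- split(edges$parent, edges$child)
  children <- split(edges$child, edges$parent)
  roots <- setdiff(ids, edges$child)
  lev <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  lev[roots] <- 1L
  frontier <- roots
  d <- 1L
  while (length(frontier) > 0) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[is.na(lev[nxt])]
    d <- d + 1L
    lev[nxt] <- d
    frontier <- nxt
  }
  lev
}

# transitive closure of child -> parent reachability (self included)
oracle_ancestors <- function(edges, ids) {
  parents <- split(edges$parent, edges$child)
  out <- list()
  for (t in ids) {
    seen <- t
    frontier <- t
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                     seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    out[[t]] <- seen
  }
  out
}

# literal interval-overlap recovery metrics
oracle_recovery <- function(called, spikes, min_overlap = 0.5) {
  rec <- 0
  for (i in seq_len(nrow(spikes))) {
    ok <- FALSE
    for (j in seq_len(nrow(called))) {
      if (called$chrom[j] != spikes$chrom[i]) next
      ov <- min(called$end[j], spikes$end[i]) -
        max(called$start[j], spikes$start[i]) + 1
      if (ov / (spikes$end[i] - spikes$start[i] + 1) >= min_overlap)
        ok <- TRUE
    }
    rec <- rec + ok
  }
  tp <- 0
  for (j in seq_len(nrow(called))) {
    hit <- FALSE
    for (i in seq_len(nrow(spikes))) {
      if (called$chrom[j] != spikes$chrom[i]) next
      if (called$start[j] <= spikes$end[i] &&
          called$end[j] >= spikes$start[i]) hit <- TRUE
    }
    tp <- tp + hit
  }
  list(sensitivity = rec / nrow(spikes),
       precision = if (nrow(called) == 0) NA_real_ else tp / nrow(called))
}
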