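BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' Builds the scanning representation of a motif: per-position base
#' frequencies, the per-position information vector
#' `I(i) = sum_B f(i,B) * ln(4 * f(i,B))` (natural log; `0 * ln 0 = 0`),
#' and the 5-position core — the contiguous window of maximal summed
#' information (leftmost on ties).
#'
#' @param freqs 4 x L numeric matrix (rows A, C, G, T) of frequencies or
#'   counts; count columns are normalized after adding `pseudocount`.
#' @param matrix_id Identifier string.
#' @param css_cutoff,mss_cutoff Default score cutoffs used when scanning
#'   (proportions in [0, 1]).
#' @param pseudocount Additive pseudocount applied to count matrices
#'   (default 0; 0.01 is recommended for raw counts so no base has
#'   frequency exactly 0).
#' @return An object of class `pwm`.
#' @export
pwm <- function(freqs, matrix_id = "pwm", css_cutoff = 0.75,
                mss_cutoff = 0.80, pseudocount = 0) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4L)
    stop("freqs must have 4 rows (A, C, G, T)")
  rownames(freqs) <- BASES
  if (ncol(freqs) < 5L)
    stop("matrix length must be at least 5 (got ", ncol(freqs), ")")
  if (any(freqs < 0)) stop("negative entries in frequency matrix")
  sums <- colSums(freqs)
  if (any(sums == 0))
    stop("matrix position ", which(sums == 0)[1L], " sums to 0")
  if (any(abs(sums - 1) > 1e-9)) {      # counts: normalize
    freqs <- sweep(freqs + pseudocount, 2L, colSums(freqs + pseudocount), "/")
  }
  info <- apply(freqs, 2L, function(f) {
    terms <- ifelse(f > 0, f * log(4 * f), 0)
    sum(terms)
  })
  win <- vapply(seq_len(ncol(freqs) - 4L),
                function(i) sum(info[i:(i + 4L)]), 0)
  core_start <- which.max(win)          # leftmost maximum
  structure(list(matrix_id = matrix_id, freqs = freqs, info = info,
                 core_start = core_start,
                 css_cutoff = css_cutoff, mss_cutoff = mss_cutoff),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$matrix_id, "| length", ncol(x$freqs),
      "| core", x$core_start, "-", x$core_start + 4L,
      "| cutoffs css", x$css_cutoff, "mss", x$mss_cutoff, "\n")
  cat("consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (argmax base per position)
#' @param x A `pwm` object.
#' @return Character string of length `ncol(x$freqs)`.
#' @export
consensus_string <- function(x) {
  paste(BASES[apply(x$freqs, 2L, which.max)], collapse = "")
}

#' Load PWMs from TRANSFAC or JASPAR text
#'
#' TRANSFAC flat files hold one or more matrices delimited by `//`, with an
#' identifier line (`ID`/`NA`/`DE`) and numbered rows of A C G T counts.
#' JASPAR files hold `>id name` headers followed by four
#' `A [ n1 n2 ... ]`-style rows.
#'
#' @param path Input file.
#' @param dialect `"transfac"` or `"jaspar"`.
#' @inheritParams pwm
#' @return A list of `pwm` objects (named by matrix id).
#' @export
load_pwms <- function(path, dialect = c("transfac", "jaspar"),
                      css_cutoff = 0.75, mss_cutoff = 0.80,
                      pseudocount = 0) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  mats <- if (dialect == "jaspar") parse_jaspar(lines)
          else parse_transfac(lines)
  if (length(mats) == 0L) stop("no matrices found in ", path)
  out <- lapply(names(mats), function(id)
    pwm(mats[[id]], matrix_id = id, css_cutoff = css_cutoff,
        mss_cutoff = mss_cutoff, pseudocount = pseudocount))
  names(out) <- names(mats)
  out
}

#' @rdname load_pwms
#' @details `load_pwm()` expects exactly one matrix in the file and returns
#'   it directly.
#' @export
load_pwm <- function(path, dialect = c("transfac", "jaspar"),
                     css_cutoff = 0.75, mss_cutoff = 0.80, pseudocount = 0) {
  all <- load_pwms(path, dialect, css_cutoff, mss_cutoff, pseudocount)
  if (length(all) > 1L)
    warning("multiple matrices in ", path, "; returning the first")
  all[[1L]]
}

parse_jaspar <- function(lines) {
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' header lines (JASPAR dialect)")
  bounds <- c(heads, length(lines) + 1L)
  mats <- list()
  for (i in seq_along(heads)) {
    id <- sub("^>\\s*(\\S+).*$", "\\1", lines[heads[i]])
    block <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(BASES, function(b) {
      ln <- grep(paste0("^\\s*", b, "\\b"), block, value = TRUE)
      if (length(ln) != 1L)
        stop("JASPAR matrix ", id, ": expected one '", b, "' row")
      as.numeric(strsplit(trimws(gsub("^\\s*[ACGT]\\s*\\[?|\\]", "", ln)),
                          "\\s+")[[1L]])
    })
    mats[[id]] <- do.call(rbind, rows)
  }
  mats
}

parse_transfac <- function(lines) {
  mats <- list()
  id <- NULL; rows <- list()
  flush <- function() {
    if (length(rows) > 0L) {
      m <- t(do.call(rbind, rows))
      mats[[if (is.null(id)) paste0("M", length(mats) + 1L) else id]] <<- m
    }
    id <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^(ID|NA)\\s+", ln) && is.null(id))
      id <- sub("^(ID|NA)\\s+(\\S+).*$", "\\2", ln)
    else if (grepl("^DE\\s+", ln) && is.null(id))
      id <- sub("^DE\\s+(\\S+).*$", "\\1", ln)
    else if (grepl("^[0-9]+\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      rows[[length(rows) + 1L]] <- as.numeric(f[2:5])
    }
  }
  flush()
  mats
}

#' Write a PWM in JASPAR text form
#' @param x A `pwm` object (frequencies are written).
#' @param path Output file.
#' @export
write_pwm_jaspar <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$matrix_id), con)
  for (b in BASES)
    writeLines(sprintf("%s [ %s ]", b,
                       paste(format(x$freqs[b, ], trim = TRUE),
                             collapse = " ")), con)
  invisible(path)
}

seq_to_codes <- function(seq) {
  match(strsplit(toupper(seq), "")[[1L]], BASES)
}

similarity_score <- function(pwm, codes, positions) {
  I <- pwm$info[positions]
  f <- pwm$freqs[, positions, drop = FALSE]
  cur <- sum(I * f[cbind(codes[positions], seq_len(length(positions)))])
  mn <- sum(I * apply(f, 2L, min))
  mx <- sum(I * apply(f, 2L, max))
  if (mx - mn <= 0)
    stop("degenerate matrix: maximal and minimal scores coincide")
  (cur - mn) / (mx - mn)
}

#' Matrix similarity score (MSS)
#'
#' Information-weighted similarity of a sequence to a PWM over all
#' positions: with `Current = sum_i I(i) * f(i, s_i)` and `Min`/`Max` the
#' analogous sums over the least/most frequent base per position,
#' `mss = (Current - Min) / (Max - Min)`, which is 1 exactly on the
#' consensus sequence and 0 on the anti-consensus.
#'
#' @param pwm A `pwm` object.
#' @param seq Character string over A/C/G/T of the matrix length.
#' @return mss in [0, 1].
#' @export
matrix_similarity <- function(pwm, seq) {
  codes <- seq_to_codes(seq)
  if (length(codes) != ncol(pwm$freqs))
    stop("sequence length ", length(codes), " != matrix length ",
         ncol(pwm$freqs))
  if (anyNA(codes))
    stop("ambiguous base in sequence: ", seq)
  similarity_score(pwm, codes, seq_len(ncol(pwm$freqs)))
}

#' Core similarity score (CSS)
#'
#' The same information-weighted similarity restricted to the matrix core:
#' the 5 consecutive positions of highest total information.
#'
#' @inheritParams matrix_similarity
#' @return css in [0, 1].
#' @export
core_similarity <- function(pwm, seq) {
  codes <- seq_to_codes(seq)
  if (length(codes) != ncol(pwm$freqs))
    stop("sequence length ", length(codes), " != matrix length ",
         ncol(pwm$freqs))
  if (anyNA(codes))
    stop("ambiguous base in sequence: ", seq)
  similarity_score(pwm, codes, pwm$core_start:(pwm$core_start + 4L))
}

scan_one_strand <- function(pwm, codes) {
  L <- ncol(pwm$freqs)
  n <- length(codes)
  if (n < L)
    return(data.frame(position = integer(0), mss = numeric(0),
                      css = numeric(0)))
  n_win <- n - L + 1L
  M <- sweep(pwm$freqs, 2L, pwm$info, "*")     # 4 x L weighted scores
  cur <- numeric(n_win)
  ok <- rep(TRUE, n_win)                        # windows free of N
  for (i in seq_len(L)) {
    ci <- codes[i:(i + n_win - 1L)]
    bad <- is.na(ci)
    ok <- ok & !bad
    ci[bad] <- 1L
    cur <- cur + M[cbind(ci, i)]
  }
  col_min <- apply(M, 2L, min); col_max <- apply(M, 2L, max)
  mn <- sum(col_min); mx <- sum(col_max)
  if (mx - mn <= 0) stop("degenerate matrix: Max = Min")
  mss <- (cur - mn) / (mx - mn)
  core <- pwm$core_start:(pwm$core_start + 4L)
  cur_c <- numeric(n_win)
  for (i in core) {
    ci <- codes[i:(i + n_win - 1L)]
    ci[is.na(ci)] <- 1L
    cur_c <- cur_c + M[cbind(ci, i)]
  }
  mn_c <- sum(col_min[core]); mx_c <- sum(col_max[core])
  css <- (cur_c - mn_c) / (mx_c - mn_c)
  data.frame(position = which(ok), mss = mss[ok], css = css[ok])
}

#' Scan cher sequences with PWMs on both strands
#'
#' Slides each PWM over each sequence and its reverse complement, applying
#' the two-stage filter: a window is a hit when its core similarity passes
#' `css_cutoff` and then its matrix similarity passes `mss_cutoff`.
#' Windows containing ambiguous bases are skipped. Minus-strand hits are
#' reported at the plus-strand start coordinate of the match footprint.
#'
#' @param pwms A `pwm` object or list of them.
#' @param seqs Named character vector or `Biostrings::DNAStringSet`, keyed
#'   by cher id.
#' @param cutoff_profile Optional data.frame (`matrix_id`, `css_cutoff`,
#'   `mss_cutoff`) overriding the per-PWM cutoffs.
#' @param chers Optional cher data.frame; when given, hits gain `chrom` and
#'   absolute `position` (cher start + offset - 1).
#' @return Data.frame of hits: `matrix_id`, `cher_id`, `position` (1-based
#'   within the sequence, or absolute when `chers` is given), `strand`
#'   (+1/-1), `mss`, `css`, `matched_sequence` (plus-strand footprint).
#' @export
scan_chers <- function(pwms, seqs, cutoff_profile = NULL, chers = NULL) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (methods::is(seqs, "DNAStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by cher_id")
  hits <- list()
  for (p in pwms) {
    cuts <- c(css = p$css_cutoff, mss = p$mss_cutoff)
    if (!is.null(cutoff_profile)) {
      row <- cutoff_profile[cutoff_profile$matrix_id == p$matrix_id, ]
      if (nrow(row) == 1L)
        cuts <- c(css = row$css_cutoff, mss = row$mss_cutoff)
    }
    L <- ncol(p$freqs)
    for (id in names(seqs)) {
      s <- toupper(seqs[[id]])
      n <- nchar(s)
      codes <- seq_to_codes(s)
      fwd <- scan_one_strand(p, codes)
      fwd$strand <- 1L
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      rev <- scan_one_strand(p, seq_to_codes(rc))
      # position j on the reverse complement footprints plus-strand
      # [n - j - L + 2, n - j + 1]
      rev$position <- n - rev$position - L + 2L
      rev$strand <- -1L
      both <- rbind(fwd, rev)
      keep <- both$css >= cuts[["css"]] & both$mss >= cuts[["mss"]]
      both <- both[keep, , drop = FALSE]
      if (nrow(both) == 0L) next
      both$matrix_id <- p$matrix_id
      both$cher_id <- id
      both$matched_sequence <- substring(s, both$position,
                                         both$position + L - 1L)
      hits[[length(hits) + 1L]] <- both
    }
  }
  if (length(hits) == 0L)
    return(data.frame(matrix_id = character(0), cher_id = character(0),
                      position = integer(0), strand = integer(0),
                      mss = numeric(0), css = numeric(0),
                      matched_sequence = character(0),
                      chrom = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, hits)
  res <- res[, c("matrix_id", "cher_id", "position", "strand", "mss",
                 "css", "matched_sequence")]
  if (!is.null(chers)) {
    m <- match(res$cher_id, chers$cher_id)
    if (anyNA(m)) stop("hit cher_id absent from chers table")
    res$chrom <- chers$chrom[m]
    res$position <- chers$start[m] + res$position - 1L
  }
  res <- res[order(res$matrix_id, res$cher_id, res$position, res$strand), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract cher sequences from a genome
#'
#' @param chers Cher data.frame.
#' @param genome `Biostrings::DNAStringSet` (named by chromosome) or a
#'   FASTA path.
#' @return `DNAStringSet` of cher sequences named by `cher_id`.
#' @export
fetch_cher_sequences <- function(chers, genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chrom <- setdiff(unique(chers$chrom), names(genome))
  if (length(missing_chrom) > 0L)
    stop("chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "))
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(chers)), function(i) {
    as.character(Biostrings::subseq(genome[[chers$chrom[i]]],
                                    chers$start[i], chers$end[i]))
  }, ""))
  names(out) <- chers$cher_id
  out
}

#' Export motif hits
#'
#' @param hits Hit data.frame from [scan_chers()] (with `chrom` column for
#'   BED export).
#' @param tsv_path,bed_path Output paths (`NULL` to skip either). BED
#'   scores are `round(mss * 1000)`.
#' @export
export_hits <- function(hits, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    if (nrow(hits) == 0L || is.null(hits$chrom)) {
      writeLines(character(0), bed_path)
    } else {
      w <- nchar(hits$matched_sequence)
      gr <- GenomicRanges::GRanges(
        seqnames = hits$chrom,
        ranges = IRanges::IRanges(start = hits$position, width = w),
        strand = ifelse(hits$strand == 1L, "+", "-"),
        name = paste(hits$matrix_id, hits$cher_id, sep = "|"),
        score = pmin(1000, pmax(0, round(hits$mss * 1000))))
      rtracklayer::export(gr, bed_path, format = "BED")
    }
  }
  invisible(hits)
}
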