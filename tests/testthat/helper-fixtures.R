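# Small in-code fixtures shared across test files.

# a random smoothed track: probes at ~100-bp spacing on 1-2 chromosomes,
# values N(0, 1) with optional NA holes
random_track <- function(n_probes, n_chroms = 1, na_frac = 0.05,
                         spacing = 100) {
  chrom <- sort(sample(sprintf("chr%d", seq_len(n_chroms)), n_probes,
                       replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_probes), chrom), function(i)
    cumsum(sample(c(spacing, spacing, 2 * spacing), length(i),
                  replace = TRUE))), use.names = FALSE)
  sm <- stats::rnorm(n_probes)
  sm[stats::runif(n_probes) < na_frac] <- NA
  df <- data.frame(probe_id = sprintf("p%04d", seq_len(n_probes)),
                   chrom = chrom, position = pos,
                   value = stats::rnorm(n_probes), smoothed = sm,
                   stringsAsFactors = FALSE)
  class(df) <- c("smoothed_track", "data.frame")
  df
}

# a mixed-information 6-position toy matrix (frequencies)
toy_pwm <- function(css_cutoff = 0, mss_cutoff = 0) {
  f <- cbind(c(0.7, 0.1, 0.1, 0.1),
             c(0.25, 0.25, 0.25, 0.25),
             c(0.05, 0.05, 0.85, 0.05),
             c(0.1, 0.6, 0.2, 0.1),
             c(0.4, 0.3, 0.2, 0.1),
             c(0.05, 0.05, 0.05, 0.85))
  cherscan::pwm(f, matrix_id = "TOY", css_cutoff = css_cutoff,
                mss_cutoff = mss_cutoff)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small DAG: root -> (A, B), A -> (C, D), B -> D, D -> E
tiny_graph <- function() {
  cherscan::term_graph(data.frame(
    child  = c("A", "B", "C", "D", "D", "E"),
    parent = c("root", "root", "A", "A", "B", "D"),
    stringsAsFactors = FALSE))
}

# random DAG edge list with given term count; level-k nodes take parents
# from any earlier level (so shortest-path level varies)
random_dag <- function(n_terms, p_extra = 0.3) {
  ids <- sprintf("N%02d", seq_len(n_terms))
  child <- character(0); parent <- character(0)
  for (i in 2:n_terms) {
    pa <- sample(ids[seq_len(i - 1)], 1)
    child <- c(child, ids[i]); parent <- c(parent, pa)
    if (stats::runif(1) < p_extra && i > 2) {
      pa2 <- sample(setdiff(ids[seq_len(i - 1)], pa), 1)
      child <- c(child, ids[i]); parent <- c(parent, pa2)
    }
  }
  data.frame(child = child, parent = parent, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
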