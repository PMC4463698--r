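test_that("PWM construction normalizes counts and computes information", {
  counts <- cbind(c(8, 0, 0, 0), c(2, 2, 2, 2), c(0, 8, 0, 0),
                  c(0, 0, 8, 0), c(0, 0, 0, 8), c(4, 4, 0, 0))
  p <- pwm(counts, pseudocount = 0)
  expect_equal(colSums(p$freqs), rep(1, 6))
  # uniform column carries zero information; single-base column ln 4
  expect_equal(p$info[2], 0)
  expect_equal(p$info[1], log(4))
  expect_equal(consensus_string(p), "AACGTA")

  expect_error(pwm(counts[, 1:4]), "at least 5")
  bad <- counts; bad[, 3] <- 0
  expect_error(pwm(bad, pseudocount = 0), "sums to 0")

  # uniform matrix: no information anywhere
  expect_equal(pwm(matrix(0.25, 4, 6))$info, rep(0, 6))
})

test_that("the core is the leftmost maximal 5-window of information", {
  p <- toy_pwm()
  expect_equal(p$core_start, oracle_core_window(oracle_info(p$freqs)))
  # strictly informative tail: core must shift right
  f <- cbind(matrix(0.25, 4, 3), diag(4)[, c(1, 2, 3, 4, 1)] * 0.97 + 0.0075)
  expect_equal(pwm(f)$core_start, 4L)
  # flat matrix + tiny tie: leftmost window wins
  expect_equal(pwm(matrix(0.25, 4, 8))$core_start, 1L)
})

test_that("similarity scores hit 1 on consensus and 0 on anti-consensus", {
  p <- toy_pwm()
  bases <- c("A", "C", "G", "T")
  cons <- paste(bases[apply(p$freqs, 2, which.max)], collapse = "")
  anti <- paste(bases[apply(p$freqs, 2, which.min)], collapse = "")
  expect_equal(matrix_similarity(p, cons), 1)
  expect_equal(matrix_similarity(p, anti), 0)
  expect_equal(core_similarity(p, cons), 1)

  # anti-consensus at the core positions only: css = 0 while mss > 0
  core <- p$core_start:(p$core_start + 4)
  mixed <- strsplit(cons, "")[[1]]
  mixed[core] <- bases[apply(p$freqs[, core], 2, which.min)]
  mixed <- paste(mixed, collapse = "")
  expect_equal(core_similarity(p, mixed), 0)
  expect_gt(matrix_similarity(p, mixed), 0)

  expect_error(matrix_similarity(p, "ANAAAA"), "ambiguous")
  expect_error(matrix_similarity(p, "AAAA"), "length")
  # degenerate matrix: every base equally likely everywhere
  expect_error(matrix_similarity(pwm(matrix(0.25, 4, 6)), "ACGTAC"),
               "degenerate")
})

test_that("toy-matrix scores equal the literal three-sum oracle", {
  set.seed(43)
  p <- toy_pwm()
  for (i in 1:40) {
    s <- random_dna(6)
    chars <- strsplit(s, "")[[1]]
    info <- oracle_info(p$freqs)
    expect_equal(matrix_similarity(p, s),
                 oracle_similarity(p$freqs, info, chars, 1:6))
    expect_equal(core_similarity(p, s),
                 oracle_similarity(p$freqs, info, chars,
                                   p$core_start:(p$core_start + 4)))
    expect_gte(matrix_similarity(p, s), 0)
    expect_lte(matrix_similarity(p, s), 1)
  }
})

test_that("scanning finds planted sites and respects strand symmetry", {
  p <- default_motif(css_cutoff = 0.99, mss_cutoff = 0.99)
  cons <- consensus_string(p)
  set.seed(47)
  flank <- random_dna(200)
  seq <- paste0(substr(flank, 1, 100), cons, substr(flank, 101, 200))
  hits <- scan_chers(p, c(cher1 = seq))
  fwd <- hits[hits$strand == 1, ]
  expect_equal(nrow(fwd), 1L)
  expect_equal(fwd$position, 101L)
  expect_equal(fwd$matched_sequence, cons)
  expect_equal(fwd$mss, 1)

  # reverse complement: same site on the minus strand, mirrored coordinate
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  hits_rc <- scan_chers(p, c(cher1 = rc))
  rev <- hits_rc[hits_rc$strand == -1, ]
  expect_equal(nrow(rev), 1L)
  expect_equal(rev$position, nchar(seq) - 101L - nchar(cons) + 2L)
  expect_equal(rev$matched_sequence,
               substr(rc, rev$position, rev$position + nchar(cons) - 1L))
})

test_that("raising either cutoff never enlarges the hit set", {
  set.seed(53)
  p <- toy_pwm()
  seq <- c(cherA = random_dna(800))
  loose <- scan_chers(p, seq,
                      cutoff_profile = data.frame(matrix_id = "TOY",
                                                  css_cutoff = 0.5,
                                                  mss_cutoff = 0.5))
  tight_css <- scan_chers(p, seq,
                          cutoff_profile = data.frame(matrix_id = "TOY",
                                                      css_cutoff = 0.8,
                                                      mss_cutoff = 0.5))
  tight_mss <- scan_chers(p, seq,
                          cutoff_profile = data.frame(matrix_id = "TOY",
                                                      css_cutoff = 0.5,
                                                      mss_cutoff = 0.8))
  key <- function(h) paste(h$position, h$strand)
  expect_true(all(key(tight_css) %in% key(loose)))
  expect_true(all(key(tight_mss) %in% key(loose)))
  expect_lte(nrow(tight_css), nrow(loose))
  expect_lte(nrow(tight_mss), nrow(loose))
})

test_that("windows containing N are skipped, not scored", {
  p <- toy_pwm()
  seq <- c(x = paste0("ACGTAN", random_dna(20)))
  hits <- scan_chers(p, seq,
                     cutoff_profile = data.frame(matrix_id = "TOY",
                                                 css_cutoff = 0,
                                                 mss_cutoff = 0))
  # every window whose footprint covers position 6 contains the N
  expect_false(any(hits$position <= 6))
  expect_true(all(!grepl("N", hits$matched_sequence)))
})

test_that("PWM files round-trip through the JASPAR and TRANSFAC dialects", {
  p <- default_motif()
  path <- tempfile(fileext = ".jaspar")
  write_pwm_jaspar(p, path)
  back <- load_pwm(path, dialect = "jaspar")
  expect_equal(back$freqs, p$freqs, tolerance = 1e-6)
  expect_equal(back$core_start, p$core_start)

  tf <- tempfile(fileext = ".transfac")
  writeLines(c("ID  MYTF",
               "P0      A      C      G      T",
               "01      8      0      0      0",
               "02      0      8      0      0",
               "03      2      2      2      2",
               "04      0      0      8      0",
               "05      0      0      0      8",
               "06      8      0      0      0",
               "//"), tf)
  q <- load_pwm(tf, dialect = "transfac", pseudocount = 0.01)
  expect_equal(q$matrix_id, "MYTF")
  expect_equal(ncol(q$freqs), 6L)
  expect_equal(consensus_string(q), "ACAGTA")
})

test_that("cher sequences come back from the genome keyed by cher id", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTACGTACGTACGT"))
  chers <- data.frame(cher_id = c("k1", "k2"), chrom = "chr1",
                      start = c(1L, 5L), end = c(4L, 12L))
  seqs <- fetch_cher_sequences(chers, genome)
  expect_equal(as.character(seqs), c(k1 = "ACGT", k2 = "ACGTACGT"))
  bad <- chers; bad$chrom <- "chr9"
  expect_error(fetch_cher_sequences(bad, genome), "chr9")
})
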