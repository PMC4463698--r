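test_that("configurations are validated up front", {
  expect_error(simulation_config(probe_spacing = 900, spike_width = 800),
               "probe_spacing")
  expect_error(simulation_config(spike_n_targets = 300, n_genes = 200),
               "exceed")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(spike_offset_range = c(200, 8000)),
               "upstream")
})

test_that("a fixed seed makes the generator byte-identical", {
  cfg <- simulation_config(seed = 99, n_genes = 30, n_chroms = 1,
                           spike_n_targets = 4,
                           ann_n_terms = 12, ann_term_size_range = c(3, 10),
                           ann_planted_size = 8)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_experiment(cfg, d1)
  a1 <- simulate_annotations(cfg, s1$genes$gene_id,
                             target_genes = s1$truth$target_genes, dir = d1)
  s2 <- simulate_experiment(cfg, d2)
  a2 <- simulate_annotations(cfg, s2$genes$gene_id,
                             target_genes = s2$truth$target_genes, dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("md5 of", f))
  }
})

test_that("noiseless spikes lift in-spike log ratios by exactly the height", {
  cfg <- simulation_config(seed = 3, n_genes = 30, n_chroms = 1,
                           spike_n_targets = 5, noise_sd = 0,
                           spike_height = 1)
  sim <- simulate_experiment(cfg)
  lr <- log2(sim$ip$signal / sim$input$signal)
  in_spike <- rep(FALSE, nrow(sim$probes))
  for (i in seq_len(nrow(sim$truth$spikes)))
    in_spike <- in_spike |
      (sim$probes$chrom == sim$truth$spikes$chrom[i] &
         sim$probes$start >= sim$truth$spikes$start[i] &
         sim$probes$start <= sim$truth$spikes$end[i])
  expect_equal(lr[in_spike], rep(1, sum(in_spike)))
  expect_equal(lr[!in_spike], rep(0, sum(!in_spike)))
})

test_that("in-spike enrichment means satisfy the CLT bound", {
  cfg <- simulation_config(seed = 4, n_genes = 120, n_chroms = 1,
                           spike_n_targets = 20)
  sim <- simulate_experiment(cfg)
  lr <- log2(sim$ip$signal / sim$input$signal)
  in_spike <- rep(FALSE, nrow(sim$probes))
  for (i in seq_len(nrow(sim$truth$spikes)))
    in_spike <- in_spike |
      (sim$probes$chrom == sim$truth$spikes$chrom[i] &
         sim$probes$start >= sim$truth$spikes$start[i] &
         sim$probes$start <= sim$truth$spikes$end[i])
  m <- sum(in_spike)
  expect_gt(m, 0)
  expect_lt(abs(mean(lr[in_spike]) - cfg$spike_height),
            3 * cfg$noise_sd / sqrt(m))
})

test_that("generated files round-trip through every reader without warnings", {
  cfg <- simulation_config(seed = 8, n_genes = 25, n_chroms = 2,
                           spike_n_targets = 3,
                           ann_n_terms = 12, ann_term_size_range = c(3, 10),
                           ann_planted_size = 8)
  dir <- tempfile()
  sim <- simulate_experiment(cfg, dir)
  ann <- simulate_annotations(cfg, sim$genes$gene_id,
                              target_genes = sim$truth$target_genes,
                              dir = dir)
  expect_no_warning({
    probes <- read_probe_table(sim$paths$probes)
    ip <- read_intensity_table(sim$paths$ip)
    input <- read_intensity_table(sim$paths$input)
    genes <- read_gene_models(sim$paths$genes)
    pw <- load_pwm(sim$paths$pwm, dialect = "jaspar")
    graph <- read_term_graph(ann$paths$edges, ann$paths$terms)
    read_annotations(ann$paths$annotations)
  })
  expect_equal(nrow(probes), nrow(sim$probes))
  expect_equal(sort(genes$gene_id), sort(sim$genes$gene_id))
  expect_equal(ncol(pw$freqs), ncol(sim$pwm$freqs))
  expect_equal(sort(names(graph$terms)),
               sort(unique(c(ann$graph$edges$child,
                             ann$graph$edges$parent))))

  # every spiked region lies inside a tiled window (probes cover it)
  for (i in seq_len(nrow(sim$truth$spikes))) {
    s <- sim$truth$spikes[i, ]
    covered <- probes$chrom == s$chrom & probes$start >= s$start &
      probes$start <= s$end
    expect_gte(sum(covered), 7)
  }
  # planted motif consensus is present in the genome where truth says
  for (i in seq_len(nrow(sim$truth$motifs))) {
    mt <- sim$truth$motifs[i, ]
    got <- as.character(Biostrings::subseq(
      sim$genome[[mt$chrom]], mt$position,
      mt$position + ncol(sim$pwm$freqs) - 1L))
    expect_equal(got, consensus_string(sim$pwm))
  }
})

test_that("simulated ontologies have the configured depth and planted term", {
  cfg <- simulation_config(seed = 21, n_genes = 200, ann_n_terms = 30,
                           ann_depth = 5, ann_term_size_range = c(5, 40),
                           ann_planted_size = 20)
  genes <- sprintf("g%03d", 1:500)
  ann <- simulate_annotations(cfg, genes, target_genes = genes[1:50])
  lev <- term_level(ann$graph)
  expect_equal(max(lev), 5L)
  expect_true(ann$truth$planted_term %in% names(ann$graph$terms))
  expect_equal(unname(lev[ann$truth$planted_term]), 5L)
  expect_equal(length(ann$truth$de_genes), round(0.3 * 500))
  expect_error(simulate_annotations(
    simulation_config(ann_planted_size = 300, ann_fold = 3), genes),
    "infeasible")
})

test_that("recovery metrics match the interval-overlap oracle", {
  spikes <- data.frame(chrom = "chr1", start = c(100L, 1000L),
                       end = c(400L, 1500L))
  perfect <- data.frame(cher_id = c("a", "b"), chrom = "chr1",
                        start = c(100L, 1000L), end = c(400L, 1500L))
  ev <- evaluate_recovery(perfect, spikes)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$precision, 1)

  none <- perfect[0, ]
  ev0 <- evaluate_recovery(none, spikes)
  expect_equal(ev0$sensitivity, 0)
  expect_true(is.na(ev0$precision))   # undefined, reported as missing

  set.seed(79)
  for (rep in 1:10) {
    called <- data.frame(cher_id = sprintf("c%d", 1:8), chrom = "chr1",
                         start = s <- sample.int(5000, 8))
    called$end <- called$start + sample.int(800, 8)
    ev <- evaluate_recovery(called, spikes)
    ora <- oracle_recovery(called, spikes)
    expect_equal(ev$sensitivity, ora$sensitivity)
    expect_equal(ev$precision, ora$precision)
  }
})
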