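# An ETS-family-like 9-bp motif (GGAA core) used as the default planted
# PWM; counts out of 100 per column.
default_pwm_counts <- function() {
  m <- matrix(c(
    # A   C   G   T
     70,  10, 10, 10,   # A
     10,  70, 10, 10,   # C
     70,  10, 10, 10,   # A
      2,   2, 94,  2,   # G
      2,   2, 94,  2,   # G
     94,   2,  2,  2,   # A
     94,   2,  2,  2,   # A
     10,  10, 70, 10,   # G
     10,  10, 10, 70),  # T
    nrow = 4L)
  rownames(m) <- c("A", "C", "G", "T")
  m
}

#' Default planted motif for simulations
#' @inheritParams pwm
#' @return A `pwm` (consensus `ACAGGAAGT`, an ETS-like site).
#' @export
default_motif <- function(css_cutoff = 0.85, mss_cutoff = 0.85) {
  pwm(default_pwm_counts(), matrix_id = "SIM_ETS",
      css_cutoff = css_cutoff, mss_cutoff = mss_cutoff, pseudocount = 0.01)
}

#' Simulation configuration
#'
#' Defines the synthetic promoter tiling-array experiment: ~100-bp-spaced
#' probes tiling -7 kb..+3 kb promoter windows, lognormal input-channel
#' baseline, Gaussian log2-ratio noise, boxcar enrichment spikes at a
#' subset of promoters (constant log2 enrichment across a
#' sonication-fragment-scale region), planted motif consensus instances
#' inside spikes, and a configurable fraction of non-uniquely mapping
#' probes.
#'
#' @param seed Integer RNG seed; a fixed seed makes all outputs
#'   byte-identical across runs.
#' @param n_chroms,n_genes Number of chromosomes / genes (genes are split
#'   evenly across chromosomes in non-overlapping promoter slots).
#' @param promoter_upstream,promoter_downstream Tiled window around each
#'   TSS in bp (defaults 7000 / 3000).
#' @param probe_spacing,probe_length Probe tiling step and length in bp
#'   (defaults 100 / 60).
#' @param spike_n_targets Number of promoters receiving an enrichment
#'   spike (default 20).
#' @param spike_height Boxcar height in log2 units (default 1.5).
#' @param spike_width Boxcar width in bp (default 800, the sonication
#'   fragment scale).
#' @param spike_offset_range Range (bp) of the spike's distance upstream
#'   of the TSS (uniform draw; default 200..4000, inside the tiled
#'   window).
#' @param noise_sd Per-probe Gaussian log2-ratio noise SD (default 0.3).
#' @param nonunique_fraction Fraction of probes flagged as multi-mapping
#'   (default 0.03).
#' @param baseline_meanlog,baseline_sdlog Lognormal input-channel
#'   parameters (defaults log(500), 0.5).
#' @param motif_per_spike Planted motif consensus copies per spike
#'   (default 1).
#' @param multi_tss_fraction Fraction of genes given a second,
#'   downstream-shifted TSS (default 0.2).
#' @param ann_n_terms,ann_depth Term count and DAG depth of the simulated
#'   ontology (defaults 50 / 6).
#' @param ann_term_size_range Uniform range of term sizes (default
#'   10..60 genes).
#' @param ann_planted_size Size of the planted enriched term (default 40).
#' @param ann_fold Fold over-representation of the planted term inside the
#'   target gene set (default 3; 1 = null).
#' @param de_fraction Fraction of genes declared differentially expressed
#'   (default 0.3).
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1, n_chroms = 2, n_genes = 200,
                              promoter_upstream = 7000,
                              promoter_downstream = 3000,
                              probe_spacing = 100, probe_length = 60,
                              spike_n_targets = 20, spike_height = 1.5,
                              spike_width = 800,
                              spike_offset_range = c(200, 4000),
                              noise_sd = 0.3, nonunique_fraction = 0.03,
                              baseline_meanlog = log(500),
                              baseline_sdlog = 0.5, motif_per_spike = 1,
                              multi_tss_fraction = 0.2,
                              ann_n_terms = 50, ann_depth = 6,
                              ann_term_size_range = c(10, 60),
                              ann_planted_size = 40, ann_fold = 3,
                              de_fraction = 0.3) {
  cfg <- as.list(environment())
  if (cfg$probe_spacing >= cfg$spike_width)
    stop("probe_spacing must be smaller than spike_width")
  counts <- c(cfg$n_chroms, cfg$n_genes, cfg$spike_n_targets,
              cfg$probe_spacing, cfg$probe_length, cfg$ann_n_terms,
              cfg$ann_depth)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (cfg$spike_n_targets > cfg$n_genes)
    stop("spike_n_targets cannot exceed n_genes")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$spike_offset_range[2] + cfg$spike_width >
      cfg$promoter_upstream)
    stop("spikes must fit inside the tiled upstream window")
  # non-overlapping promoter slots; window fits either strand
  cfg$slot_width <- cfg$promoter_upstream + cfg$promoter_downstream + 6000
  cfg$genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  cfg$chrom_length <- cfg$genes_per_chrom * cfg$slot_width + 10000
  structure(cfg, class = "sim_config")
}

#' Simulate a complete tiling-array experiment
#'
#' Generates, in a single seeded stream consumed in fixed order (genome,
#' genes, probes, intensities): a random genome; gene models in
#' non-overlapping promoter slots with random strands; probes tiling each
#' promoter window; two-channel intensities where the input channel is
#' lognormal and the IP channel multiplies it by
#' `2^(boxcar + N(0, noise_sd^2))` inside spikes and `2^N(0, noise_sd^2)`
#' elsewhere; planted motif consensus strings written into the genome at
#' the centre of each spike.
#'
#' @param config A `sim_config` ([simulation_config()]).
#' @param dir Optional output directory; when given, all pipeline input
#'   files are written (`genome.fa`, `genes.gff3`, `probes.tsv`, `ip.tsv`,
#'   `input.tsv`, `pwm.jaspar`, `truth.json`).
#' @return List with `probes`, `ip`, `input` (data.frames), `genes`
#'   (gene-model data.frame), `genome` (`DNAStringSet`), `pwm`, `truth`
#'   (list: `spikes`, `motifs`, `target_genes`) and, when `dir` is given,
#'   `paths`.
#' @export
simulate_experiment <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  chroms <- sprintf("chrS%d", seq_len(config$n_chroms))
  genome_chars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
  names(genome_chars) <- chroms

  # genes: one per slot, TSS near the slot centre
  n <- config$n_genes
  chrom_of <- rep(chroms, each = config$genes_per_chrom)[seq_len(n)]
  slot_of <- (seq_len(n) - 1L) %% config$genes_per_chrom
  slot_start <- slot_of * config$slot_width + 1L
  tss <- as.integer(slot_start + config$promoter_upstream + 1500 +
                      sample.int(1000, n, replace = TRUE))
  strand <- sample(c(1L, -1L), n, replace = TRUE)
  body_len <- sample(2000:8000, n, replace = TRUE)
  gene_start <- ifelse(strand == 1L, tss, tss - body_len)
  gene_end <- ifelse(strand == 1L, tss + body_len, tss)
  gene_id <- sprintf("SG%04d", seq_len(n))
  extra <- stats::runif(n) < config$multi_tss_fraction
  tss_list <- lapply(seq_len(n), function(i) {
    if (extra[i]) {
      alt <- tss[i] + strand[i] * (100L + sample.int(400L, 1L))
      sort(unique(c(tss[i], as.integer(alt))))
    } else tss[i]
  })
  genes <- gene_model_frame(gene_id, gene_id, chrom_of, strand,
                            gene_start, gene_end, tss_list)
  genes$primary_tss <- tss

  # probes tile the strand-aware promoter window around the primary TSS
  win_start <- ifelse(strand == 1L, tss - config$promoter_upstream,
                      tss - config$promoter_downstream)
  win_end <- ifelse(strand == 1L, tss + config$promoter_downstream,
                    tss + config$promoter_upstream)
  probe_rows <- lapply(seq_len(n), function(i) {
    starts <- seq.int(win_start[i],
                      win_end[i] - config$probe_length + 1L,
                      by = config$probe_spacing)
    data.frame(chrom = chrom_of[i], start = as.integer(starts),
               stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, probe_rows)
  probes <- probes[order(probes$chrom, probes$start), , drop = FALSE]
  probes <- data.frame(probe_id = sprintf("SP%06d", seq_len(nrow(probes))),
                       chrom = probes$chrom, start = probes$start,
                       length = config$probe_length,
                       n_genomic_hits = 1L, stringsAsFactors = FALSE)
  n_multi <- round(config$nonunique_fraction * nrow(probes))
  if (n_multi > 0L)
    probes$n_genomic_hits[sample.int(nrow(probes), n_multi)] <- 2L

  # spikes: boxcar upstream of randomly chosen target promoters
  targets <- sort(sample.int(n, config$spike_n_targets))
  off <- stats::runif(length(targets), config$spike_offset_range[1],
                      config$spike_offset_range[2])
  sp_start <- ifelse(strand[targets] == 1L,
                     tss[targets] - off - config$spike_width + 1,
                     tss[targets] + off)
  spikes <- data.frame(chrom = chrom_of[targets],
                       start = as.integer(round(sp_start)),
                       end = as.integer(round(sp_start)) +
                         as.integer(config$spike_width) - 1L,
                       gene_id = gene_id[targets], stringsAsFactors = FALSE)

  # intensities
  m <- nrow(probes)
  input_sig <- stats::rlnorm(m, config$baseline_meanlog,
                             config$baseline_sdlog)
  in_spike <- rep(FALSE, m)
  for (i in seq_len(nrow(spikes)))
    in_spike <- in_spike | (probes$chrom == spikes$chrom[i] &
                              probes$start >= spikes$start[i] &
                              probes$start <= spikes$end[i])
  log_fc <- ifelse(in_spike, config$spike_height, 0) +
    if (config$noise_sd > 0) stats::rnorm(m, 0, config$noise_sd) else 0
  ip_sig <- input_sig * 2^log_fc
  ip <- data.frame(probe_id = probes$probe_id, signal = ip_sig,
                   stringsAsFactors = FALSE)
  input <- data.frame(probe_id = probes$probe_id, signal = input_sig,
                      stringsAsFactors = FALSE)

  # plant motif consensus copies at the centre of each spike
  motif <- default_motif()
  cons <- strsplit(consensus_string(motif), "")[[1L]]
  L <- length(cons)
  motif_rows <- list()
  for (i in seq_len(nrow(spikes))) {
    centre <- floor((spikes$start[i] + spikes$end[i]) / 2)
    for (j in seq_len(config$motif_per_spike)) {
      pos <- centre - floor(L / 2) + (j - 1L) * (L + 10L)
      genome_chars[[spikes$chrom[i]]][pos:(pos + L - 1L)] <- cons
      motif_rows[[length(motif_rows) + 1L]] <-
        data.frame(chrom = spikes$chrom[i], position = as.integer(pos),
                   matrix_id = motif$matrix_id, gene_id = spikes$gene_id[i],
                   stringsAsFactors = FALSE)
    }
  }
  motifs <- do.call(rbind, motif_rows)

  genome <- Biostrings::DNAStringSet(
    vapply(genome_chars, paste, "", collapse = ""))
  names(genome) <- chroms

  truth <- list(spikes = spikes, motifs = motifs,
                target_genes = gene_id[targets])
  out <- list(probes = probes, ip = ip, input = input, genes = genes,
              genome = genome, pwm = motif, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      genome = file.path(dir, "genome.fa"),
      genes = file.path(dir, "genes.gff3"),
      probes = file.path(dir, "probes.tsv"),
      ip = file.path(dir, "ip.tsv"),
      input = file.path(dir, "input.tsv"),
      pwm = file.path(dir, "pwm.jaspar"),
      truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(genome, paths$genome)
    write_gene_models_gff3(genes, paths$genes)
    write_probe_table(probes, paths$probes)
    utils::write.table(ip, paths$ip, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(input, paths$input, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_pwm_jaspar(motif, paths$pwm)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Write gene models as GFF3 (gene + transcript features)
#'
#' @param genes Gene-model data.frame (list-column `tss_list`; one
#'   transcript feature per TSS).
#' @param path Output GFF3 file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    st <- if (genes$strand[i] == 1L) "+" else "-"
    rows[[length(rows) + 1L]] <- sprintf(
      "%s\tcherscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      genes$chrom[i], genes$gene_start[i], genes$gene_end[i], st,
      genes$gene_id[i], genes$symbol[i])
    for (j in seq_along(genes$tss_list[[i]])) {
      tss <- genes$tss_list[[i]][j]
      if (genes$strand[i] == 1L) {
        s <- tss; e <- genes$gene_end[i]
      } else {
        s <- genes$gene_start[i]; e <- tss
      }
      rows[[length(rows) + 1L]] <- sprintf(
        "%s\tcherscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t%d;Parent=%s",
        genes$chrom[i], s, e, st, genes$gene_id[i], j, genes$gene_id[i])
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Simulate an ontology, annotations and a differential-expression list
#'
#' Builds a random DAG of the configured depth (level-k terms take parents
#' only from level k-1, so construction depth equals shortest-path depth),
#' samples term memberships by size, inflates the planted term's
#' membership probability by `ann_fold` inside `target_genes`, and draws a
#' differential-expression list covering `de_fraction` of the genes with
#' random up/down directions. Seeded from `config$seed + 1` so the
#' annotation stream is reproducible independently of the array stream.
#'
#' @param config A `sim_config`.
#' @param genes Character vector: the gene universe.
#' @param target_genes Character vector: the set whose planted-term
#'   membership is inflated (e.g. DE cher-target genes). With
#'   `ann_fold = 1` the planted term behaves like any other (null).
#' @param intersect_de When `TRUE`, the inflated set is
#'   `target_genes` intersected with the drawn DE genes (the pipeline's
#'   reading: enrichment concentrates in differentially expressed spiked
#'   targets).
#' @param dir Optional output directory (`terms.tsv`, `term_edges.tsv`,
#'   `annotations.tsv`, `de.tsv`, `annotation_truth.json`).
#' @return List with `graph` (`term_graph`), `annotations` (data.frame
#'   `gene`, `term`), `de` (data.frame `gene`, `log2fc`, `direction`,
#'   `fdr`), `truth` (list: `planted_term`, `de_genes`) and optional
#'   `paths`.
#' @export
simulate_annotations <- function(config, genes, target_genes = character(0),
                                 intersect_de = FALSE, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_terms <- config$ann_n_terms
  depth <- config$ann_depth
  if (n_terms < depth) stop("need at least one term per DAG level")
  N <- length(genes)
  if (config$ann_fold * config$ann_planted_size > N)
    stop("planted fold infeasible: fold * planted size exceeds the universe")

  # differential expression drawn first so the planted structure can be
  # restricted to DE targets
  n_de <- round(config$de_fraction * N)
  de_genes <- sample(genes, n_de)
  direction <- sample(c("up", "down"), n_de, replace = TRUE)
  de <- data.frame(gene = de_genes,
                   log2fc = ifelse(direction == "up", 1, -1) *
                     stats::rlnorm(n_de, 0, 0.4),
                   direction = direction,
                   fdr = stats::runif(n_de, 0, 0.049),
                   stringsAsFactors = FALSE)
  if (intersect_de) target_genes <- intersect(target_genes, de_genes)

  # one root; remaining terms spread over levels 2..depth (each non-empty)
  level <- c(1L, rep(2:depth, length.out = n_terms - 1L))
  level <- sort(level)
  ids <- sprintf("T%03d", seq_len(n_terms))
  child <- character(0); parent <- character(0)
  for (lv in 2:depth) {
    here <- ids[level == lv]; above <- ids[level == lv - 1L]
    for (t in here) {
      np <- 1L + stats::rbinom(1L, 1L, 0.3)
      pa <- sample(above, min(np, length(above)))
      child <- c(child, rep(t, length(pa)))
      parent <- c(parent, pa)
    }
  }
  graph <- term_graph(data.frame(child = child, parent = parent,
                                 stringsAsFactors = FALSE),
                      stats::setNames(paste("term", ids), ids))

  # planted term sits at the deepest level
  planted <- ids[level == depth][1L]
  leaf_terms <- ids[-1L]                      # root gets members via closure
  sizes <- sample(config$ann_term_size_range[1]:config$ann_term_size_range[2],
                  length(leaf_terms), replace = TRUE)
  sizes[match(planted, leaf_terms)] <- config$ann_planted_size
  ann <- list()
  n_t <- length(target_genes)
  for (i in seq_along(leaf_terms)) {
    t <- leaf_terms[i]; K <- sizes[i]
    if (t == planted && n_t > 0L && config$ann_fold != 1) {
      p_t <- min(1, config$ann_fold * K / N)
      p_b <- max(0, (K - n_t * p_t) / (N - n_t))
      members <- c(target_genes[stats::runif(n_t) < p_t],
                   setdiff(genes, target_genes)[
                     stats::runif(N - n_t) < p_b])
    } else {
      members <- sample(genes, min(K, N))
    }
    if (length(members) > 0L)
      ann[[length(ann) + 1L]] <- data.frame(gene = members, term = t,
                                            stringsAsFactors = FALSE)
  }
  annotations <- unique(do.call(rbind, ann))

  truth <- list(planted_term = planted, de_genes = de_genes)
  out <- list(graph = graph, annotations = annotations, de = de,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(terms = file.path(dir, "terms.tsv"),
                  edges = file.path(dir, "term_edges.tsv"),
                  annotations = file.path(dir, "annotations.tsv"),
                  de = file.path(dir, "de.tsv"),
                  truth = file.path(dir, "annotation_truth.json"))
    utils::write.table(
      data.frame(term = names(graph$terms), name = unname(graph$terms)),
      paths$terms, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(child = child, parent = parent, relation = "is_a"),
      paths$edges, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(annotations, paths$annotations, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(de, paths$de, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Compare called regions with the planted truth
#'
#' A spike counts as recovered when a single cher covers at least
#' `min_overlap` of it; a cher is a true positive when it overlaps any
#' spike at all.
#'
#' @param called Cher data.frame ([call_chers()]).
#' @param truth_spikes Data.frame with `chrom`, `start`, `end` (the
#'   `spikes` element of the simulation truth).
#' @param min_overlap Minimum covered fraction of a spike (default 0.5).
#' @return List with `sensitivity` (recovered / spikes), `precision`
#'   (TP chers / chers; `NA` when nothing was called) and `per_region`
#'   (per-spike table with best covering fraction and recovery flag).
#' @export
evaluate_recovery <- function(called, truth_spikes, min_overlap = 0.5) {
  ns <- nrow(truth_spikes)
  best <- numeric(ns)
  for (i in seq_len(ns)) {
    s <- truth_spikes[i, ]
    ov <- pmin(called$end, s$end) - pmax(called$start, s$start) + 1
    ov[called$chrom != s$chrom] <- 0
    ov <- pmax(ov, 0)
    best[i] <- if (nrow(called) == 0L) 0 else
      max(ov) / (s$end - s$start + 1)
  }
  recovered <- best >= min_overlap
  tp <- vapply(seq_len(nrow(called)), function(j) {
    any(called$chrom[j] == truth_spikes$chrom &
          called$start[j] <= truth_spikes$end &
          called$end[j] >= truth_spikes$start)
  }, TRUE)
  list(sensitivity = if (ns == 0L) NA_real_ else mean(recovered),
       precision = if (nrow(called) == 0L) NA_real_ else mean(tp),
       per_region = data.frame(truth_spikes,
                               best_overlap = best,
                               recovered = recovered))
}
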