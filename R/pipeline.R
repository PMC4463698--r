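#' Default pipeline run configuration
#'
#' Stage parameters default to the analysis settings of the promoter
#' tiling-array design this package targets: a 900-bp smoothing window
#' with a minimum of 7 probes, region merging below 450 bp, the 99th
#' enrichment quantile, and a 10-kb upstream promoter definition.
#'
#' @param ... Overrides for any configuration field (see Details).
#' @details Fields: `simulate` (logical; generate synthetic inputs first),
#'   input paths (`probes`, `ip`, `input`, `genes`, `genome`, `pwm`,
#'   `term_edges`, `term_names`, `annotations`, `de`), `half_window`,
#'   `min_probes`, `merge_gap`, `quantile`, `floor_quantile`,
#'   `upstream_bp`, `css_cutoff`, `mss_cutoff`, `min_k`, `level_filter`,
#'   `fdr_cutoff`, `antibody`, `pool`, `seed`, plus the
#'   [simulation_config()] overrides `sim` (a named list) used when
#'   `simulate = TRUE`.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    probes = NULL, ip = NULL, input = NULL, genes = NULL, genome = NULL,
    pwm = NULL, term_edges = NULL, term_names = NULL, annotations = NULL,
    de = NULL,
    half_window = 450, min_probes = 7, merge_gap = 450,
    quantile = 0.99, floor_quantile = NA,
    upstream_bp = 10000, css_cutoff = 0.85, mss_cutoff = 0.85,
    min_k = 2, level_filter = NULL, fdr_cutoff = 0.05,
    antibody = "TF", pool = "AAA Pool", seed = 1,
    sim = list())
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown run_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (!(cfg$quantile > 0 && cfg$quantile < 1))
    stop("quantile must lie strictly between 0 and 1")
  if (!is.na(cfg$floor_quantile) &&
      !(cfg$floor_quantile > 0 && cfg$floor_quantile < cfg$quantile))
    stop("floor_quantile must satisfy 0 < floor_quantile < quantile")
  if (cfg$min_probes < 1 || cfg$merge_gap < 0 || cfg$half_window <= 0)
    stop("invalid window/merging parameters")
  if (!cfg$simulate) {
    need <- c("probes", "ip", "input")
    miss <- need[vapply(cfg[need], is.null, TRUE)]
    if (length(miss) > 0L)
      stop("non-simulated runs need input path(s): ",
           paste(miss, collapse = ", "))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; keys are [run_config()] fields.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full ChIP-chip analysis pipeline
#'
#' Executes (simulate) -> ingest -> normalize -> smooth -> call regions ->
#' annotate -> fetch sequences -> motif scan -> enrichment, writing every
#' stage product plus a machine-readable JSON manifest (parameters, input
#' checksums, per-stage record counts) to `out_dir`. Any stage error
#' aborts with a message naming the stage. Enrichment runs when ontology
#' and differential-expression inputs are available (always in simulated
#' runs).
#'
#' @param config A `run_config` (or a YAML path accepted by
#'   [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return An object of class `cher_run`: list with `chers`,
#'   `assignments`, `hits`, `enrichment`, `recovery` (simulated runs),
#'   `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("cherrun")) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  if (isTRUE(config$simulate)) {
    sim_cfg <- do.call(simulation_config,
                       c(list(seed = config$seed), config$sim))
    sim <- stage("simulate",
                 simulate_experiment(sim_cfg, file.path(out_dir, "inputs")))
    config$probes <- sim$paths$probes
    config$ip <- sim$paths$ip
    config$input <- sim$paths$input
    config$genes <- sim$paths$genes
    config$genome <- sim$paths$genome
    config$pwm <- sim$paths$pwm
    truth <- sim$truth
  }

  probes <- stage("ingest", read_probe_table(config$probes))
  counts$probes_read <- nrow(probes)
  flt <- filter_unique_probes(probes)
  counts$probes_removed_nonunique <- flt$removed_count
  probes <- flt$kept
  ratios <- stage("ingest", compute_log_ratios(
    read_intensity_table(config$ip), read_intensity_table(config$input)))
  ratios <- ratios[ratios$probe_id %in% probes$probe_id, , drop = FALSE]
  counts$probes_with_ratios <- nrow(ratios)

  norm <- stage("normalize", normalize_log_ratios(
    stats::setNames(ratios$log_ratio, ratios$probe_id)))
  counts$location_estimate <- norm$location_estimate

  m <- match(ratios$probe_id, probes$probe_id)
  pv <- data.frame(probe_id = ratios$probe_id,
                   chrom = probes$chrom[m], position = probes$start[m],
                   value = unname(norm$normalized),
                   stringsAsFactors = FALSE)
  track <- stage("smooth", smooth_track(pv, half_window = config$half_window,
                                        min_probes = config$min_probes))
  export_track(track,
               raw = ratios$log_ratio[match(track$probe_id,
                                            ratios$probe_id)],
               tsv_path = file.path(out_dir, "smoothed.tsv"),
               bedgraph_path = file.path(out_dir, "smoothed.bedGraph"))

  y0 <- stage("callchers", compute_threshold(
    track, quantile = config$quantile,
    floor_quantile = config$floor_quantile,
    min_probes = config$min_probes))
  chers <- stage("callchers", call_chers(
    track, y0, min_probes = config$min_probes,
    merge_gap = config$merge_gap, antibody = config$antibody,
    pool = config$pool))
  counts$y0 <- as.numeric(y0)
  counts$chers_called <- nrow(chers)
  export_chers(chers, tsv_path = file.path(out_dir, "chers.tsv"),
               bed_path = file.path(out_dir, "chers.bed"))

  assignments <- NULL
  genes <- NULL
  if (!is.null(config$genes)) {
    genes <- stage("annotate", read_gene_models(config$genes))
    assignments <- stage("annotate", assign_chers_to_genes(
      chers, genes, upstream_bp = config$upstream_bp))
    counts$genes_with_chers <- length(unique(assignments$gene_id))
    utils::write.table(assignments, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  hits <- NULL
  if (!is.null(config$genome) && !is.null(config$pwm) && nrow(chers) > 0L) {
    seqs <- stage("fetch-seqs", fetch_cher_sequences(chers, config$genome))
    pwms <- stage("scan", load_pwms(config$pwm, dialect = "jaspar",
                                    css_cutoff = config$css_cutoff,
                                    mss_cutoff = config$mss_cutoff))
    hits <- stage("scan", scan_chers(pwms, seqs, chers = chers))
    counts$chers_with_tfbs <- length(unique(hits$cher_id))
    export_hits(hits, tsv_path = file.path(out_dir, "tfbs_hits.tsv"),
                bed_path = file.path(out_dir, "tfbs_hits.bed"))
  }

  enrichment <- NULL
  recovery <- NULL
  if (isTRUE(config$simulate)) {
    ann_sim <- stage("enrich", simulate_annotations(
      sim_cfg, genes$gene_id, target_genes = truth$target_genes,
      intersect_de = TRUE, dir = file.path(out_dir, "inputs")))
    config$term_edges <- ann_sim$paths$edges
    config$term_names <- ann_sim$paths$terms
    config$annotations <- ann_sim$paths$annotations
    config$de <- ann_sim$paths$de
    recovery <- stage("evaluate", evaluate_recovery(chers, truth$spikes))
  }
  if (!is.null(config$term_edges) && !is.null(config$annotations) &&
      !is.null(config$de) && !is.null(assignments)) {
    enrichment <- stage("enrich", {
      graph <- read_term_graph(config$term_edges, config$term_names)
      ann <- propagate_annotations(graph,
                                   read_annotations(config$annotations))
      de <- utils::read.delim(config$de, stringsAsFactors = FALSE)
      target_sets <- intersect_with_expression(
        unique(assignments$gene_id), de, fdr_cutoff = config$fdr_cutoff)
      counts$de_targets <- length(target_sets$all)
      reference <- if (!is.null(genes)) genes$gene_id else names(ann$propagated)
      if (length(intersect(target_sets$all, names(ann$propagated))) == 0L) {
        message("no annotated differentially expressed target genes; ",
                "skipping over-representation analysis")
        counts$terms_tested <- 0L
        NULL
      } else {
        res <- enrich(target_sets$all, reference, ann, graph,
                      min_k = config$min_k,
                      level_filter = config$level_filter)
        counts$terms_tested <- nrow(res)
        utils::write.table(res, file.path(out_dir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        export_dag_dot(graph, res, file.path(out_dir, "enrichment_dag.dot"),
                       fdr_cutoff = config$fdr_cutoff)
        res
      }
    })
  }

  inputs <- Filter(Negate(is.null),
                   config[c("probes", "ip", "input", "genes", "genome",
                            "pwm", "term_edges", "annotations", "de")])
  manifest <- list(
    package = "cherscan",
    version = as.character(utils::packageVersion("cherscan")),
    parameters = config[c("half_window", "min_probes", "merge_gap",
                          "quantile", "floor_quantile", "upstream_bp",
                          "css_cutoff", "mss_cutoff", "min_k", "seed")],
    input_checksums = as.list(stats::setNames(
      unname(tools::md5sum(unlist(inputs))),
      basename(unlist(inputs)))),
    counts = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(chers = chers, assignments = assignments, hits = hits,
                 enrichment = enrichment, recovery = recovery,
                 manifest = manifest, out_dir = out_dir),
            class = "cher_run")
}

#' @export
print.cher_run <- function(x, ...) {
  c0 <- x$manifest$counts
  cat("cherscan pipeline run ->", x$out_dir, "\n")
  cat("  probes read:            ", c0$probes_read, "\n")
  cat("  removed (non-unique):   ", c0$probes_removed_nonunique, "\n")
  cat("  threshold y0:           ", format(c0$y0, digits = 4), "\n")
  cat("  chers called:           ", c0$chers_called, "\n")
  if (!is.null(c0$genes_with_chers))
    cat("  genes with chers:       ", c0$genes_with_chers, "\n")
  if (!is.null(c0$chers_with_tfbs))
    cat("  chers with TFBS:        ", c0$chers_with_tfbs, "\n")
  if (!is.null(c0$terms_tested))
    cat("  ontology terms tested:  ", c0$terms_tested, "\n")
  if (!is.null(x$recovery))
    cat("  spike recovery:          sensitivity",
        format(x$recovery$sensitivity, digits = 3), "/ precision",
        format(x$recovery$precision, digits = 3), "\n")
  invisible(x)
}
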