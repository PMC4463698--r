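#' Read gene models from GFF3 or BED
#'
#' For GFF3, `gene` features define the gene body and id/symbol, and
#' transcript-level children (`mRNA`, `transcript`, `*RNA`) supply one TSS
#' each (the strand-aware 5' end); genes without transcript children use
#' their own 5' end. For BED, every record is a gene with a single TSS at
#' its 5' end.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @return A data.frame with columns `gene_id`, `symbol`, `chrom`, `strand`
#'   (+1/-1), `gene_start`, `gene_end` and a list-column `tss_list`.
#' @export
read_gene_models <- function(path) {
  fmt <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED" else "GFF3"
  gr <- rtracklayer::import(path, format = fmt)
  if (fmt == "BED") {
    strand <- ifelse(as.character(GenomicRanges::strand(gr)) == "-", -1L, 1L)
    tss <- ifelse(strand == 1L, GenomicRanges::start(gr),
                  GenomicRanges::end(gr))
    ids <- if (!is.null(gr$name)) as.character(gr$name)
           else sprintf("gene%d", seq_along(gr))
    return(gene_model_frame(ids, ids, as.character(GenomicRanges::seqnames(gr)),
                            strand, GenomicRanges::start(gr),
                            GenomicRanges::end(gr), as.list(tss)))
  }
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gid <- if (!is.null(genes$ID)) as.character(genes$ID)
         else as.character(genes$gene_id)
  sym <- if (!is.null(genes$Name)) as.character(genes$Name) else gid
  strand <- ifelse(as.character(GenomicRanges::strand(genes)) == "-", -1L, 1L)

  tx <- gr[grepl("RNA$|transcript", type)]
  tss_list <- vector("list", length(genes))
  if (length(tx) > 0L) {
    parent <- vapply(as.list(tx$Parent), function(p)
      if (length(p) > 0L) as.character(p[[1L]]) else NA_character_, "")
    tx_strand <- ifelse(as.character(GenomicRanges::strand(tx)) == "-",
                        -1L, 1L)
    tx_tss <- ifelse(tx_strand == 1L, GenomicRanges::start(tx),
                     GenomicRanges::end(tx))
    for (i in seq_along(genes)) {
      hits <- which(parent == gid[i])
      if (length(hits) > 0L)
        tss_list[[i]] <- sort(unique(tx_tss[hits]))
    }
  }
  own_tss <- ifelse(strand == 1L, GenomicRanges::start(genes),
                    GenomicRanges::end(genes))
  for (i in seq_along(genes))
    if (is.null(tss_list[[i]])) tss_list[[i]] <- own_tss[i]

  gene_model_frame(gid, sym, as.character(GenomicRanges::seqnames(genes)),
                   strand, GenomicRanges::start(genes),
                   GenomicRanges::end(genes), tss_list)
}

gene_model_frame <- function(gene_id, symbol, chrom, strand, gene_start,
                             gene_end, tss_list) {
  stopifnot(all(strand %in% c(-1L, 1L)), all(gene_start <= gene_end),
            all(unlist(tss_list) >= 1L))
  df <- data.frame(gene_id = gene_id, symbol = symbol, chrom = chrom,
                   strand = as.integer(strand),
                   gene_start = as.integer(gene_start),
                   gene_end = as.integer(gene_end),
                   stringsAsFactors = FALSE)
  df$tss_list <- lapply(tss_list, as.integer)
  df
}

#' Assign chers to genes by the promoter rule
#'
#' A cher annotates a gene when its interval overlaps (a) the strand-aware
#' window `upstream_bp` 5' of any TSS of the gene — `[TSS - upstream_bp,
#' TSS - 1]` on plus-strand genes, `[TSS + 1, TSS + upstream_bp]` on minus
#' strand (the TSS base itself is excluded) — or (b) the gene body
#' `[gene_start, gene_end]`. One record per (cher, gene) pair; a cher may
#' annotate several genes. When both rules hold, `relation` is
#' `"within_gene"`; `tss_used` is the gene TSS most proximal to the cher
#' midpoint.
#'
#' @param chers Cher data.frame ([call_chers()]).
#' @param genes Gene-model data.frame ([read_gene_models()]).
#' @param upstream_bp Promoter extent upstream of the TSS (default 10000).
#' @return Data.frame with columns `cher_id`, `gene_id`, `relation`
#'   (`"upstream"` or `"within_gene"`), `tss_used`.
#' @export
assign_chers_to_genes <- function(chers, genes, upstream_bp = 10000) {
  empty <- data.frame(cher_id = character(0), gene_id = character(0),
                      relation = character(0), tss_used = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(chers) == 0L || nrow(genes) == 0L) return(empty)

  cher_gr <- GenomicRanges::GRanges(
    chers$chrom, IRanges::IRanges(chers$start, chers$end))

  # one window per (gene, tss) + one per gene body
  n_tss <- lengths(genes$tss_list)
  g_idx <- rep(seq_len(nrow(genes)), n_tss)
  tss <- unlist(genes$tss_list)
  strand <- genes$strand[g_idx]
  win_start <- ifelse(strand == 1L, pmax(1L, tss - upstream_bp), tss + 1L)
  win_end <- ifelse(strand == 1L, tss - 1L, tss + upstream_bp)
  ok <- win_start <= win_end
  up_gr <- GenomicRanges::GRanges(
    genes$chrom[g_idx][ok], IRanges::IRanges(win_start[ok], win_end[ok]))
  body_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$gene_start, genes$gene_end))

  hit_up <- GenomicRanges::findOverlaps(cher_gr, up_gr)
  hit_body <- GenomicRanges::findOverlaps(cher_gr, body_gr)

  ci_up <- S4Vectors::queryHits(hit_up)
  ci_body <- S4Vectors::queryHits(hit_body)
  pairs <- rbind(
    data.frame(ci = ci_up,
               gi = g_idx[ok][S4Vectors::subjectHits(hit_up)],
               relation = rep("upstream", length(ci_up)),
               stringsAsFactors = FALSE),
    data.frame(ci = ci_body,
               gi = S4Vectors::subjectHits(hit_body),
               relation = rep("within_gene", length(ci_body)),
               stringsAsFactors = FALSE))
  if (nrow(pairs) == 0L) return(empty)
  # within_gene wins when both rules hold for a (cher, gene) pair
  pairs$rank <- ifelse(pairs$relation == "within_gene", 1L, 2L)
  pairs <- pairs[order(pairs$ci, pairs$gi, pairs$rank), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs[, c("ci", "gi")]), , drop = FALSE]

  mid <- floor((chers$start + chers$end) / 2)
  tss_used <- vapply(seq_len(nrow(pairs)), function(i) {
    most_proximal_tss(genes$tss_list[[pairs$gi[i]]], mid[pairs$ci[i]])
  }, 0L)
  res <- data.frame(cher_id = chers$cher_id[pairs$ci],
                    gene_id = genes$gene_id[pairs$gi],
                    relation = pairs$relation,
                    tss_used = tss_used, stringsAsFactors = FALSE)
  res <- res[order(res$cher_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Most proximal TSS to a reference point
#'
#' @param tss_list Integer vector of TSS positions (bp).
#' @param reference_point Position (bp) to measure from.
#' @return The TSS minimizing the absolute distance; ties break toward the
#'   smaller coordinate.
#' @export
most_proximal_tss <- function(tss_list, reference_point) {
  tss_list <- as.integer(tss_list)
  if (length(tss_list) == 0L) stop("empty tss_list")
  d <- abs(tss_list - reference_point)
  cand <- tss_list[d == min(d)]
  as.integer(min(cand))
}

#' Signed distance from a predicted binding site to the TSS
#'
#' The motif's absolute position is `cher_start + tfbs_offset`; the
#' returned distance is `(TSS - absolute position) * strand`, so a positive
#' value means the site lies upstream of the TSS on the gene's coding
#' strand. `literal = TRUE` instead evaluates the alternative reading
#' `(TSS - cher_start + tfbs_offset) * strand` for comparison.
#'
#' @param tss TSS position (bp).
#' @param cher_start Cher start position (bp).
#' @param tfbs_offset Offset of the motif start within the cher (bp >= 0).
#' @param strand +1 or -1.
#' @param literal Use the additive alternative reading (default FALSE).
#' @return Signed distance in bp (vectorized).
#' @export
tss_distance <- function(tss, cher_start, tfbs_offset, strand,
                         literal = FALSE) {
  if (any(tfbs_offset < 0)) stop("tfbs_offset must be >= 0")
  if (!all(strand %in% c(-1, 1))) stop("strand must be +1 or -1")
  if (literal) (tss - cher_start + tfbs_offset) * strand
  else (tss - (cher_start + tfbs_offset)) * strand
}

#' Offset between a predicted binding site and a qPCR assay
#'
#' Signed difference in bp between a validation amplicon midpoint and the
#' predicted site: `assay_position - tfbs_position`.
#'
#' @param tfbs_position Predicted site position (bp).
#' @param assay_position Amplicon midpoint position (bp), same chromosome.
#' @return Signed offset in bp (vectorized).
#' @export
tfbs_assay_offset <- function(tfbs_position, assay_position) {
  as.integer(assay_position) - as.integer(tfbs_position)
}

#' qPCR validation assays for predicted binding sites
#'
#' The bundled table of ChIP-qPCR validation assays in human aortic tissue:
#' per predicted transcription-factor binding site, the cher it lies in,
#' the assay amplicon midpoint and the published signed offset (`delta`).
#'
#' @return Data.frame with columns `tf`, `gene`, `chrom`, `cher_start`,
#'   `cher_end`, `max_peak`, `score`, `tfbs`, `assay_id`, `assay_position`,
#'   `delta`.
#' @export
qpcr_assays <- function() {
  path <- system.file("extdata", "qpcr_assays.tsv", package = "cherscan",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
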