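#' Build a term graph (ontology DAG)
#'
#' Edges point child -> parent (is_a/part_of collapsed). The graph must be
#' acyclic; roots are the terms with no parent.
#'
#' @param edges Data.frame with columns `child`, `parent` (extra columns
#'   such as `relation` are ignored). May have zero rows (flat collections
#'   of pathway gene sets).
#' @param terms Optional named character vector mapping term id -> name;
#'   ids seen only in `edges` get their id as name.
#' @return An object of class `term_graph` with elements `terms`, `edges`,
#'   `graph` (igraph, edges child -> parent), `roots`.
#' @export
term_graph <- function(edges = NULL, terms = NULL) {
  if (is.null(edges))
    edges <- data.frame(child = character(0), parent = character(0))
  ids <- unique(c(edges$child, edges$parent, names(terms)))
  if (length(ids) == 0L) stop("term_graph: no terms")
  nm <- stats::setNames(ids, ids)
  if (!is.null(terms)) nm[names(terms)] <- terms
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")],
    vertices = data.frame(name = ids), directed = TRUE)
  if (!igraph::is_dag(g))
    stop("term graph contains a cycle")
  roots <- ids[igraph::degree(g, mode = "out") == 0L]
  structure(list(terms = nm, edges = edges, graph = g, roots = roots),
            class = "term_graph")
}

#' @export
print.term_graph <- function(x, ...) {
  cat("term graph:", length(x$terms), "terms,", nrow(x$edges),
      "edges,", length(x$roots), "root(s)\n")
  invisible(x)
}

#' Read a term graph from TSV edge and name lists
#'
#' @param edges_path TSV with header columns `child`, `parent` (and
#'   optionally `relation`).
#' @param names_path Optional TSV with columns `term`, `name`.
#' @return A `term_graph`.
#' @export
read_term_graph <- function(edges_path, names_path = NULL) {
  edges <- utils::read.delim(edges_path, stringsAsFactors = FALSE,
                             colClasses = "character")
  terms <- NULL
  if (!is.null(names_path)) {
    nm <- utils::read.delim(names_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    terms <- stats::setNames(nm$name, nm$term)
  }
  term_graph(edges, terms)
}

#' Read gene -> term annotations
#'
#' @param path TSV with header columns `gene`, `term`.
#' @return Data.frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("gene", "term") %in% names(tab)))
    stop("annotation table needs columns gene, term")
  unique(tab[, c("gene", "term")])
}

# ancestor sets per term (the term itself included)
term_ancestors <- function(graph) {
  ids <- names(igraph::V(graph$graph))
  anc <- lapply(ids, function(t)
    names(igraph::subcomponent(graph$graph, t, mode = "out")))
  stats::setNames(anc, ids)
}

#' Propagate annotations up the DAG
#'
#' Each gene's propagated term set is the union of its direct terms and
#' all their ancestors (the true-path rule). Annotations to terms absent
#' from the graph are skipped with a warning and counted in the
#' `"n_unknown"` attribute.
#'
#' @param graph A `term_graph`.
#' @param direct Data.frame (`gene`, `term`) or named list gene -> terms.
#' @return An object of class `annotation_set` with `direct` and
#'   `propagated` (named lists gene -> term ids).
#' @export
propagate_annotations <- function(graph, direct) {
  if (is.data.frame(direct))
    direct <- split(direct$term, direct$gene)
  direct <- lapply(direct, unique)
  known <- names(graph$terms)
  n_unknown <- 0L
  anc <- term_ancestors(graph)
  propagated <- lapply(direct, function(ts) {
    bad <- setdiff(ts, known)
    n_unknown <<- n_unknown + length(bad)
    ts <- intersect(ts, known)
    unique(unlist(anc[ts], use.names = FALSE))
  })
  direct <- lapply(direct, function(ts) intersect(ts, known))
  if (n_unknown > 0L)
    warning(n_unknown, " annotation(s) to unknown terms skipped")
  keep <- lengths(propagated) > 0L
  structure(list(direct = direct[keep], propagated = propagated[keep]),
            class = "annotation_set")
}

#' Depth of a term below the root
#'
#' Level 1 is a root; a term's level is 1 + the shortest path length from
#' any root (so reporting "level 6" selects terms five edges below a
#' root).
#'
#' @param graph A `term_graph`.
#' @param term_id Term id(s); default all terms.
#' @return Named integer vector of levels.
#' @export
term_level <- function(graph, term_id = NULL) {
  ids <- names(graph$terms)
  if (is.null(term_id)) term_id <- ids
  unknown <- setdiff(term_id, ids)
  if (length(unknown) > 0L)
    stop("unknown term(s): ", paste(unknown, collapse = ", "))
  if (length(graph$roots) == 0L)
    stop("term graph has no roots")
  d <- igraph::distances(graph$graph, v = term_id, to = graph$roots,
                         mode = "out")
  lev <- apply(d, 1L, min) + 1L
  stats::setNames(as.integer(lev), term_id)
}

#' Upper-tail hypergeometric test
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes in a sample of `n` from a universe of `N`
#' genes of which `K` carry the annotation.
#'
#' @param k Observed annotated genes in the sample.
#' @param K Annotated genes in the universe.
#' @param n Sample size.
#' @param N Universe size.
#' @return p in [0, 1] (vectorized).
#' @export
hypergeometric_test <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(K > N) || any(n > N) ||
      any(k > pmin(K, n)))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), ",
         "K <= N, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Adjusted values (FDR) in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Over-representation analysis of a gene set
#'
#' Hypergeometric test per term over propagated annotations. The universe
#' `N` counts only reference genes carrying at least one propagated
#' annotation, and `n` the annotated input genes; input genes absent from
#' the reference are dropped (count in attribute `"n_dropped"`). Terms
#' with `K >= 1` reference genes and `k >= min_k` input genes are tested;
#' BH adjustment runs across all tested terms jointly, before any level
#' filtering.
#'
#' @param target_genes Character vector, the gene set of interest (e.g.
#'   differentially expressed cher targets).
#' @param reference_genes Character vector, the reference universe.
#' @param annotations An `annotation_set` ([propagate_annotations()]), or a
#'   (`gene`, `term`) data.frame for flat collections (used as-is, no
#'   propagation).
#' @param graph Optional `term_graph` for level reporting (`NULL` for flat
#'   pathway collections: level is `NA`).
#' @param min_k Minimum input-gene overlap for a term to be tested
#'   (default 2).
#' @param level_filter Optional integer: keep only terms at this DAG level
#'   (applied after BH).
#' @return Data.frame sorted by p: `term_id`, `term_name`, `level`, `K`,
#'   `k`, `n`, `N`, `expected` (= n*K/N), `p`, `fdr`.
#' @export
enrich <- function(target_genes, reference_genes, annotations, graph = NULL,
                   min_k = 2, level_filter = NULL) {
  if (is.data.frame(annotations)) {
    prop <- lapply(split(annotations$term, annotations$gene), unique)
  } else prop <- annotations$propagated
  target_genes <- unique(target_genes)
  reference_genes <- unique(reference_genes)
  n_dropped <- sum(!target_genes %in% reference_genes)
  target_genes <- intersect(target_genes, reference_genes)

  ref_ann <- intersect(reference_genes, names(prop))
  tgt_ann <- intersect(target_genes, names(prop))
  if (length(tgt_ann) == 0L)
    stop("no annotated genes in the target set")
  N <- length(ref_ann); n <- length(tgt_ann)

  K_tab <- table(unlist(prop[ref_ann], use.names = FALSE))
  k_tab <- table(unlist(prop[tgt_ann], use.names = FALSE))
  terms <- names(K_tab)
  K <- as.integer(K_tab)
  k <- as.integer(k_tab[terms]); k[is.na(k)] <- 0L
  test <- K >= 1L & k >= min_k
  if (!any(test)) {
    res <- data.frame(term_id = character(0), term_name = character(0),
                      level = integer(0), K = integer(0), k = integer(0),
                      n = integer(0), N = integer(0), expected = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE)
    attr(res, "n_dropped") <- n_dropped
    return(res)
  }
  terms <- terms[test]; K <- K[test]; k <- k[test]
  p <- hypergeometric_test(k, K, n, N)
  fdr <- bh_adjust(p)
  lev <- rep(NA_integer_, length(terms))
  nm <- terms
  if (!is.null(graph)) {
    lev <- unname(term_level(graph, terms))
    nm <- unname(graph$terms[terms])
  }
  res <- data.frame(term_id = terms, term_name = nm, level = lev,
                    K = K, k = k, n = n, N = N, expected = n * K / N,
                    p = p, fdr = fdr, stringsAsFactors = FALSE)
  if (!is.null(level_filter))
    res <- res[!is.na(res$level) & res$level == level_filter, , drop = FALSE]
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_dropped") <- n_dropped
  res
}

#' Intersect cher target genes with a differential-expression list
#'
#' @param cher_target_genes Character vector of genes with chers.
#' @param de_list Data.frame with columns `gene` and either `direction`
#'   (`"up"`/`"down"`) or `log2fc` (sign gives the direction); an optional
#'   `fdr` column is filtered at `fdr_cutoff`.
#' @param fdr_cutoff Keep DE genes with `fdr < fdr_cutoff` (default 0.05;
#'   ignored when the table has no `fdr` column).
#' @return List of three character vectors: `all`, `up`, `down` (DE cher
#'   targets); intersection sizes in the `"counts"` attribute.
#' @export
intersect_with_expression <- function(cher_target_genes, de_list,
                                      fdr_cutoff = 0.05) {
  de <- de_list
  if (!is.null(de$fdr)) de <- de[de$fdr < fdr_cutoff, , drop = FALSE]
  dir <- if (!is.null(de$direction)) de$direction
         else ifelse(de$log2fc >= 0, "up", "down")
  targets <- unique(cher_target_genes)
  all_de <- intersect(targets, de$gene)
  up <- intersect(targets, de$gene[dir == "up"])
  down <- intersect(targets, de$gene[dir == "down"])
  out <- list(all = all_de, up = up, down = down)
  attr(out, "counts") <- c(all = length(all_de), up = length(up),
                           down = length(down))
  out
}

#' Export the significant-term sub-DAG as DOT
#'
#' Writes a Graphviz DOT file of the terms passing `fdr_cutoff` together
#' with all their ancestors, significant terms shaded.
#'
#' @param graph A `term_graph`.
#' @param results Enrichment data.frame ([enrich()]).
#' @param path Output DOT file.
#' @param fdr_cutoff Significance cutoff (default 0.05).
#' @export
export_dag_dot <- function(graph, results, path, fdr_cutoff = 0.05) {
  sig <- results$term_id[results$fdr < fdr_cutoff]
  anc <- term_ancestors(graph)
  keep <- unique(unlist(anc[sig], use.names = FALSE))
  lines <- c("digraph enrichment {", "  rankdir=BT;")
  for (t in keep) {
    lab <- sprintf("%s\\n%s", t, graph$terms[[t]])
    if (t %in% sig) {
      fdr <- results$fdr[match(t, results$term_id)]
      lines <- c(lines, sprintf(
        "  \"%s\" [label=\"%s\\nFDR=%.2g\", style=filled, fillcolor=lightblue];",
        t, lab, fdr))
    } else {
      lines <- c(lines, sprintf("  \"%s\" [label=\"%s\"];", t, lab))
    }
  }
  e <- graph$edges[graph$edges$child %in% keep &
                     graph$edges$parent %in% keep, , drop = FALSE]
  lines <- c(lines,
             sprintf("  \"%s\" -> \"%s\";", e$child, e$parent),
             "}")
  writeLines(lines, path)
  invisible(path)
}
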