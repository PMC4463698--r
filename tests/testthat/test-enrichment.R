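test_that("annotation propagation closes over ancestors", {
  g <- term_graph(data.frame(child = c("B", "A"), parent = c("A", "root")))
  ann <- propagate_annotations(g, data.frame(gene = "g1", term = "B"))
  expect_setequal(ann$propagated$g1, c("B", "A", "root"))

  # root annotation is a fixed point
  ann <- propagate_annotations(g, data.frame(gene = "g1", term = "root"))
  expect_equal(ann$propagated$g1, "root")

  # unknown terms are skipped with a warning and counted
  expect_warning(
    ann <- propagate_annotations(
      g, data.frame(gene = c("g1", "g1"), term = c("B", "XX"))),
    "unknown")
  expect_setequal(ann$propagated$g1, c("B", "A", "root"))

  # cycles are rejected at graph construction
  expect_error(term_graph(data.frame(child = c("A", "B"),
                                     parent = c("B", "A"))), "cycle")
})

test_that("propagation equals the transitive-closure oracle on random DAGs", {
  set.seed(59)
  for (rep in 1:10) {
    edges <- random_dag(sample(20:50, 1))
    ids <- unique(c(edges$child, edges$parent))
    g <- term_graph(edges)
    anc <- oracle_ancestors(edges, ids)
    genes <- sprintf("g%d", 1:30)
    direct <- data.frame(
      gene = sample(genes, 60, replace = TRUE),
      term = sample(ids, 60, replace = TRUE))
    ann <- propagate_annotations(g, direct)
    for (gn in names(ann$propagated)) {
      want <- unique(unlist(anc[unique(direct$term[direct$gene == gn])]))
      expect_setequal(ann$propagated[[gn]], want)
      expect_true(all(ann$direct[[gn]] %in% ann$propagated[[gn]]))
    }
  }
})

test_that("term levels are shortest-path depths with roots at level 1", {
  g <- tiny_graph()
  expect_equal(unname(term_level(g, "root")), 1L)
  expect_equal(unname(term_level(g, "A")), 2L)
  expect_equal(unname(term_level(g, "D")), 3L)  # root->A->D shorter path
  expect_equal(unname(term_level(g, "E")), 4L)
  expect_error(term_level(g, "nope"), "unknown")

  set.seed(61)
  for (rep in 1:10) {
    edges <- random_dag(sample(15:40, 1))
    ids <- unique(c(edges$child, edges$parent))
    g <- term_graph(edges)
    expect_equal(term_level(g)[ids], oracle_levels(edges, ids))
  }
})

test_that("hypergeometric upper tails match enumeration and behave monotonically", {
  expect_equal(hypergeometric_test(0, 3, 3, 10), 1)
  expect_equal(hypergeometric_test(3, 3, 3, 3), 1)
  expect_equal(hypergeometric_test(2, 3, 3, 10), oracle_hypergeom(2, 3, 3, 10))
  expect_error(hypergeometric_test(4, 3, 3, 10), "bounds")
  expect_error(hypergeometric_test(2, 11, 3, 10), "bounds")

  # p non-increasing in k
  p_seq <- hypergeometric_test(0:5, 8, 5, 20)
  expect_true(all(diff(p_seq) <= 0))

  # tail mass sums to one
  for (cfg in list(c(20, 7, 5), c(60, 30, 25), c(15, 15, 3))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]
    k <- max(0, n + K - N):min(K, n)
    expect_equal(sum(stats::dhyper(k, K, N - K, n)), 1, tolerance = 1e-12)
  }
})

test_that("BH adjustment equals the literal step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 6)), rep(0.02, 6))
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_equal(oracle_bh(p), c(0.04, 0.04, 0.04, 0.5))  # hand-checkable
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(67)
  for (i in 1:50) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # monotone along the sorted p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("over-representation composes the hypergeometric and BH machinery", {
  # planted structure: term T in 30/100 target vs 248/7400 reference
  set.seed(71)
  genes <- sprintf("g%05d", 1:7400)
  target <- sample(genes, 100)
  inT <- c(sample(target, 30), sample(setdiff(genes, target), 218))
  ann <- rbind(data.frame(gene = genes, term = "root"),
               data.frame(gene = inT, term = "T"))
  g <- term_graph(data.frame(child = "T", parent = "root"))
  aset <- propagate_annotations(g, ann)
  res <- enrich(target, genes, aset, g)
  row <- res[res$term_id == "T", ]
  expect_equal(row$k, 30L); expect_equal(row$K, 248L)
  expect_equal(row$n, 100L); expect_equal(row$N, 7400L)
  expect_equal(row$expected, 100 * 248 / 7400)
  expect_equal(row$p, oracle_hypergeom(30, 248, 100, 7400))
  expect_equal(res$fdr, bh_adjust(res$p))
  expect_equal(row$level, 2L)

  # target = reference: nothing can be over-represented
  res0 <- enrich(genes, genes, aset, g)
  expect_true(all(res0$p == 1))

  # flat mode: same machinery, level undefined
  flat <- enrich(target, genes, ann, graph = NULL)
  expect_true(all(is.na(flat$level)))
  expect_equal(flat$p[flat$term_id == "T"],
               oracle_hypergeom(30, 248, 100, 7400))

  expect_error(enrich("absent", genes, aset, g), "no annotated genes")
})

test_that("universe counts only annotated genes and dropped targets are tallied", {
  genes <- sprintf("g%d", 1:50)
  ann <- data.frame(gene = genes[1:40], term = "root")  # 10 unannotated
  g <- term_graph(data.frame(child = character(0), parent = character(0)),
                  terms = c(root = "root"))
  aset <- propagate_annotations(g, ann)
  res <- enrich(genes[1:20], genes, aset, g, min_k = 1)
  expect_equal(unique(res$N), 40L)
  res2 <- enrich(c(genes[1:5], "not_in_ref"), genes, aset, g, min_k = 1)
  expect_equal(attr(res2, "n_dropped"), 1L)
})

test_that("expression intersection splits targets by direction", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   direction = c("up", "down", "up", "down"),
                   fdr = c(0.01, 0.01, 0.2, 0.04))
  x <- intersect_with_expression(c("a", "b", "c", "z"), de)
  expect_setequal(x$all, c("a", "b"))       # c fails the FDR filter
  expect_equal(x$up, "a")
  expect_equal(x$down, "b")
  expect_equal(attr(x, "counts")[["all"]], 2L)

  # disjoint sets
  y <- intersect_with_expression("q", de)
  expect_equal(lengths(y), c(all = 0L, up = 0L, down = 0L))

  # random sets vs a literal set oracle
  set.seed(73)
  univ <- sprintf("g%04d", 1:1000)
  targ <- sample(univ, 200)
  de2 <- data.frame(gene = sample(univ, 300),
                    log2fc = stats::rnorm(300))
  z <- intersect_with_expression(targ, de2)
  brute_all <- 0
  for (g0 in targ) if (g0 %in% de2$gene) brute_all <- brute_all + 1
  expect_equal(length(z$all), brute_all)
  expect_setequal(c(z$up, z$down), z$all)
})

test_that("enrichment tables and DAG exports survive a file round-trip", {
  dir <- tempfile(); dir.create(dir)
  edges <- data.frame(child = c("A", "B"), parent = c("root", "A"),
                      relation = "is_a")
  write_tsv(edges, file.path(dir, "edges.tsv"))
  write_tsv(data.frame(term = c("root", "A", "B"),
                       name = c("r", "a", "b")),
            file.path(dir, "names.tsv"))
  g <- read_term_graph(file.path(dir, "edges.tsv"),
                       file.path(dir, "names.tsv"))
  expect_equal(unname(g$terms["A"]), "a")
  write_tsv(data.frame(gene = c("g1", "g2"), term = c("B", "A")),
            file.path(dir, "ann.tsv"))
  ann <- read_annotations(file.path(dir, "ann.tsv"))
  aset <- propagate_annotations(g, ann)
  res <- enrich("g1", c("g1", "g2"), aset, g, min_k = 1)
  dot <- file.path(dir, "dag.dot")
  export_dag_dot(g, res, dot, fdr_cutoff = 1.1)
  expect_true(any(grepl("->", readLines(dot))))
})
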