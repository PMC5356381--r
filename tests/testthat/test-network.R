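toy_dag <- function() {
  # namespace BP: root -> A -> {B, C}; separate component D -> E;
  # namespace MF: single component
  go_dag(
    terms = data.frame(
      id = c("R", "A", "B", "C", "D", "E", "M1", "M2"),
      namespace = c(rep("BP", 6), "MF", "MF")),
    edges = data.frame(
      child = c("A", "B", "C", "E", "M2"),
      parent = c("R", "A", "A", "D", "M1"),
      relation = c("is_a", "is_a", "part_of", "is_a", "is_a")))
}

test_that("Wang similarity matches hand-computed values", {
  dag <- toy_dag()
  expect_equal(wang_term_similarity("A", "A", dag), 1.0)
  # single is_a edge: S_B = {B:1, A:0.8}, S_A = {A:1}
  # sim = (0.8 + 1) / (1 + 1.8) = 0.642857...
  dag2 <- go_dag(terms = data.frame(id = c("P", "Q"),
                                    namespace = c("BP", "BP")),
                 edges = data.frame(child = "Q", parent = "P",
                                    relation = "is_a"))
  expect_equal(round(wang_term_similarity("Q", "P", dag2), 4), 0.6429)
  # part_of weight 0.6: sim = (0.6 + 1) / (1 + 1.6) = 0.615385
  dag3 <- go_dag(terms = data.frame(id = c("P", "Q"),
                                    namespace = c("BP", "BP")),
                 edges = data.frame(child = "Q", parent = "P",
                                    relation = "part_of"))
  expect_equal(wang_term_similarity("Q", "P", dag3), 1.6 / 2.6)
  # disjoint components share no ancestor
  expect_equal(wang_term_similarity("B", "E", dag), 0)
  expect_error(wang_term_similarity("A", "M1", dag), "namespaces")
  expect_error(wang_term_similarity("A", "ZZ", dag), "unknown")
})

test_that("Wang similarity is symmetric and bounded on random DAGs", {
  set.seed(801)
  for (k in 1:5) {
    n <- 12
    ids <- sprintf("T%02d", 1:n)
    # random DAG: each node may attach to a lower-numbered node
    edges <- do.call(rbind, lapply(2:n, function(i) {
      if (runif(1) < 0.8)
        data.frame(child = ids[i],
                   parent = ids[sample.int(i - 1, 1)],
                   relation = sample(c("is_a", "part_of"), 1))
    }))
    dag <- go_dag(data.frame(id = ids, namespace = "BP"), edges)
    for (j in 1:10) {
      ab <- sample(ids, 2)
      s1 <- wang_term_similarity(ab[1], ab[2], dag)
      s2 <- wang_term_similarity(ab[2], ab[1], dag)
      expect_equal(s1, s2)
      expect_gte(s1, 0)
      expect_lte(s1, 1)
    }
    expect_equal(wang_term_similarity(ids[3], ids[3], dag), 1.0)
  }
})

test_that("gene similarity is the per-branch best-match average", {
  dag <- toy_dag()
  # identical single-term annotation in one branch; empty branches score 0
  res <- gene_functional_similarity(c("B", "M1"), c("B", "M1"), dag)
  expect_equal(res$sim_bp, 1.0)
  expect_equal(res$sim_mf, 1.0)
  expect_equal(res$sim_cc, 0)      # no CC annotation on either side
  expect_equal(res$avg, 2 / 3)
  # disjoint-component annotations score 0
  res2 <- gene_functional_similarity("B", "E", dag)
  expect_equal(res2$avg, 0)
  # brute-force BMA oracle over the full matrix
  ta <- c("B", "C"); tb <- c("A", "E")
  m <- outer(ta, tb, Vectorize(function(x, y)
    wang_term_similarity(x, y, dag)))
  bma <- (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) /
    (nrow(m) + ncol(m))
  res3 <- gene_functional_similarity(ta, tb, dag)
  expect_equal(res3$sim_bp, bma)
  expect_error(gene_functional_similarity(character(), "B", dag),
               "annotation")
})

test_that("minimal OBO round trip preserves terms, edges and namespaces", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "namespace: biological_process", "",
               "[Term]", "id: GO:2", "namespace: biological_process",
               "is_a: GO:1 ! parent", "",
               "[Term]", "id: GO:3", "namespace: molecular_function",
               "relationship: part_of GO:4", "",
               "[Term]", "id: GO:4", "namespace: molecular_function"),
             path)
  dag <- read_go_obo(path)
  expect_equal(nrow(dag$terms), 4L)
  expect_setequal(dag$terms$namespace[dag$terms$id %in% c("GO:1", "GO:2")],
                  "BP")
  expect_equal(dag$edges$relation[dag$edges$child == "GO:3"], "part_of")
  expect_equal(round(wang_term_similarity("GO:2", "GO:1", dag), 4),
               0.6429)
})

test_that("permutation p-values are bounded and detect identity", {
  x <- c(1, 3, 2, 5, 4, 6)
  res <- pearson_permutation_test(x, x, n_perm = 1000, seed = 5)
  expect_equal(res$r, 1.0)
  expect_lt(res$p_perm, 0.05)
  expect_gte(res$p_perm, 1 / 1001)
  expect_lte(res$p_perm, 1)
  expect_error(pearson_permutation_test(rep(1, 6), x), "constant")
  # deterministic under a fixed seed
  res2 <- pearson_permutation_test(x, rev(x), n_perm = 200, seed = 9)
  res3 <- pearson_permutation_test(x, rev(x), n_perm = 200, seed = 9)
  expect_equal(res2$p_perm, res3$p_perm)
})

test_that("identity permutation p matches exhaustive enumeration", {
  # with n = 6 and x = y on distinct values, |r_perm| >= 1 holds exactly
  # for the identity and the full reversal among all 720 orderings;
  # the sampled estimate must sit near 2/720 (within Monte Carlo error)
  x <- c(2, 9, 4, 7, 1, 6)
  perms <- NULL
  idx <- seq_len(6)
  hits <- 0L; total <- 0L
  rec <- function(rest, acc) {
    if (!length(rest)) {
      total <<- total + 1L
      if (abs(cor(x, x[acc])) >= 1 - 1e-12) hits <<- hits + 1L
      return()
    }
    for (r in rest) rec(setdiff(rest, r), c(acc, r))
  }
  rec(idx, integer())
  expect_equal(total, 720L)
  exact_rate <- hits / total
  res <- pearson_permutation_test(x, x, n_perm = 2000, seed = 13)
  expect_lt(abs((res$p_perm * 2001 - 1) / 2000 - exact_rate), 0.005)
})

test_that("co-function edges require all three criteria jointly", {
  set.seed(802)
  samples <- 12
  # A and B co-vary; C is independent noise
  z <- rnorm(samples)
  expr <- rbind(A = z + rnorm(samples, 0, 0.2),
                B = z + rnorm(samples, 0, 0.2),
                C = rnorm(samples))
  w <- rnorm(samples)
  meth <- rbind(A = w + rnorm(samples, 0, 0.2),
                B = w + rnorm(samples, 0, 0.2),
                C = rnorm(samples))
  colnames(expr) <- colnames(meth) <- paste0("s", 1:samples)
  dag <- go_dag(data.frame(id = c("X", "Y"), namespace = c("BP", "BP")))
  ann <- list(A = "X", B = "X", C = "Y")
  net <- build_cofunction_network(expr, meth, ann, dag, n_perm = 500,
                                  seed = 3)
  expect_equal(nrow(net$edges), 1L)
  expect_setequal(c(net$edges$gene_a, net$edges$gene_b), c("A", "B"))
  expect_equal(net$edges$weight, net$edges$meth_r)
  expect_equal(net$edges$weight, cor(meth["A", ], meth["B", ]))
  # removing a criterion can only grow the edge set
  relaxed <- net$pairs[net$pairs$expr_perm_p < 0.05 &
                         net$pairs$meth_p < 0.05, ]
  expect_gte(nrow(relaxed), nrow(net$edges))
  expect_error(build_cofunction_network(expr[1, , drop = FALSE],
                                        meth, ann, dag), "two genes")
})

test_that("degrees and seed modules match the induced subgraph", {
  edges <- data.frame(gene_a = c("s", "s", "s", "n1"),
                      gene_b = c("n1", "n2", "n3", "n2"))
  deg <- degree_stats(edges)
  expect_equal(deg$degree[deg$gene == "s"], 3L)
  expect_equal(deg$gene[1], "s")
  # isolated nodes report zero
  deg2 <- degree_stats(edges[0, ], nodes = c("a", "b"))
  expect_equal(deg2$degree, c(0L, 0L))

  ppi <- rbind(edges, data.frame(gene_a = c("n3", "x"),
                                 gene_b = c("x", "y")))
  mod <- extract_seed_module(ppi, "s")
  expect_setequal(mod$nodes, c("s", "n1", "n2", "n3"))
  # star edges plus the n1-n2 link; x-y and n3-x excluded
  expect_equal(nrow(mod$edges), 4L)
  iso <- extract_seed_module(data.frame(gene_a = "a", gene_b = "b"), "a")
  expect_setequal(iso$nodes, c("a", "b"))
  expect_error(extract_seed_module(ppi, "zz"), "absent")
})

test_that("seed module equals the igraph induced subgraph on random PPIs", {
  skip_if_not_installed("igraph")
  set.seed(803)
  for (k in 1:5) {
    nodes <- sprintf("g%02d", 1:15)
    ppi <- unique(data.frame(
      gene_a = sample(nodes, 25, replace = TRUE),
      gene_b = sample(nodes, 25, replace = TRUE)))
    ppi <- ppi[ppi$gene_a != ppi$gene_b, ]
    g <- igraph::graph_from_data_frame(ppi, directed = FALSE)
    seed_gene <- sample(names(igraph::V(g)), 1)
    nb <- names(igraph::neighbors(g, seed_gene))
    sub <- igraph::induced_subgraph(g, c(seed_gene, nb))
    mod <- extract_seed_module(ppi, seed_gene)
    expect_setequal(mod$nodes, names(igraph::V(sub)))
    expect_equal(nrow(mod$edges), igraph::ecount(sub))
  }
})

test_that("Fisher exact and hypergeometric tests behave analytically", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1.0)
  expect_error(fisher_exact(matrix(c(-1, 5, 5, 5), 2)), "nonnegative")
  # one-sided p never exceeds the two-sided p for the same table
  tb <- matrix(c(12, 3, 4, 11), 2)
  expect_lte(fisher_exact(tb, alternative = "greater")$p,
             fisher_exact(tb)$p)
  expect_equal(hypergeometric_enrichment(5, 5, 5, 5), 1.0)
  expect_equal(hypergeometric_enrichment(5, 5, 5, 100),
               1 / choose(100, 5))
  expect_error(hypergeometric_enrichment(6, 5, 5, 100), "inconsistent")
  # brute-force tail sum
  set.seed(804)
  for (k in 1:10) {
    u <- sample(20:60, 1); cat_n <- sample(1:u, 1)
    set_n <- sample(1:u, 1)
    hit <- sample(0:min(cat_n, set_n), 1)
    brute <- sum(vapply(hit:min(cat_n, set_n), function(x)
      choose(cat_n, x) * choose(u - cat_n, set_n - x) / choose(u, set_n),
      0))
    expect_equal(hypergeometric_enrichment(hit, set_n, cat_n, u), brute)
  }
})
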