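# Core co-function network: permutation-tested co-expression, Wang-measure
# GO semantic similarity with best-match-average combination,
# co-methylation weighting; plus PPI seed modules and enrichment tests.

#' Read a minimal OBO-like ontology
#'
#' Parses `[Term]` stanzas with `id:`, `namespace:`, `is_a:` and
#' `relationship: part_of` lines into a GO DAG object.
#'
#' @param path ontology file.
#' @return object of class `go_dag`: list with `terms` (data.frame `id`,
#'   `namespace`) and `edges` (data.frame `child`, `parent`, `relation`).
#' @export
read_go_obo <- function(path) {
  lines <- readLines(path)
  terms <- list()
  edges <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      terms[[length(terms) + 1L]] <<- data.frame(
        id = cur$id, namespace = cur$namespace %||% NA_character_,
        stringsAsFactors = FALSE)
      for (p in cur$parents)
        edges[[length(edges) + 1L]] <<- data.frame(
          child = cur$id, parent = p$id, relation = p$rel,
          stringsAsFactors = FALSE)
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- list(parents = list())
    } else if (!is.null(cur)) {
      if (startsWith(ln, "id:")) {
        cur$id <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "namespace:")) {
        cur$namespace <- trimws(sub("^namespace:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        id <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur$parents <- c(cur$parents, list(list(id = id, rel = "is_a")))
      } else if (startsWith(ln, "relationship: part_of")) {
        id <- trimws(sub("!.*$", "", sub("^relationship: part_of", "", ln)))
        cur$parents <- c(cur$parents, list(list(id = id, rel = "part_of")))
      }
    }
  }
  flush()
  go_dag(do.call(rbind, terms), do.call(rbind, edges))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a GO DAG from term and edge tables
#'
#' @param terms data.frame with columns `id`, `namespace` (one of `BP`,
#'   `CC`, `MF` or the long OBO names).
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (`is_a` or `part_of`); NULL for an edgeless ontology.
#' @return object of class `go_dag`.
#' @export
go_dag <- function(terms, edges = NULL) {
  ns_map <- c(biological_process = "BP", cellular_component = "CC",
              molecular_function = "MF", BP = "BP", CC = "CC", MF = "MF")
  terms$namespace <- unname(ns_map[terms$namespace])
  if (any(is.na(terms$namespace)))
    stop("unknown namespace in ontology", call. = FALSE)
  if (is.null(edges))
    edges <- data.frame(child = character(), parent = character(),
                        relation = character())
  if (nrow(edges) && !all(edges$relation %in% c("is_a", "part_of")))
    stop("edge relations must be is_a or part_of", call. = FALSE)
  structure(list(terms = terms, edges = edges), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag:", nrow(x$terms), "terms,", nrow(x$edges), "edges (",
      paste(names(table(x$terms$namespace)), collapse = "/"), ")\n")
  invisible(x)
}

# Wang S-values: for term t, the semantic contribution of each ancestor a
# is the maximum over upward paths of the product of edge weights;
# S(t) = 1. Returned as a named vector over t and its ancestors.
.wang_svalues <- function(term, dag, weights) {
  s <- c(1)
  names(s) <- term
  frontier <- term
  while (length(frontier)) {
    nxt <- character()
    for (ch in frontier) {
      up <- dag$edges[dag$edges$child == ch, , drop = FALSE]
      if (!nrow(up)) next
      for (k in seq_len(nrow(up))) {
        val <- s[[ch]] * weights[[up$relation[k]]]
        p <- up$parent[k]
        if (is.null(s[p]) || is.na(s[p]) || val > s[p]) {
          s[p] <- val
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  s
}

#' Wang semantic similarity between two GO terms
#'
#' Graph-based measure: each term's ancestors receive S-values (maximum
#' path product of edge weights, is_a = 0.8 and part_of = 0.6 by default,
#' with S = 1 for the term itself); similarity is the summed S-values over
#' shared ancestors divided by the total S mass of both terms. Identical
#' terms score 1; terms with no common ancestor score 0.
#'
#' @param term_a,term_b term ids (must share a namespace).
#' @param dag a `go_dag`.
#' @param weights named vector of edge weights.
#' @return similarity in `[0, 1]`.
#' @export
wang_term_similarity <- function(term_a, term_b, dag,
                                 weights = c(is_a = 0.8, part_of = 0.6)) {
  i <- match(c(term_a, term_b), dag$terms$id)
  if (any(is.na(i)))
    stop("unknown term: ", paste(c(term_a, term_b)[is.na(i)],
                                 collapse = ", "), call. = FALSE)
  ns <- dag$terms$namespace[i]
  if (ns[1L] != ns[2L])
    stop("terms belong to different namespaces", call. = FALSE)
  sa <- .wang_svalues(term_a, dag, weights)
  sb <- .wang_svalues(term_b, dag, weights)
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

# Best-match average of a similarity matrix: mean of all row maxima and
# column maxima together.
.bma <- function(simmat) {
  (sum(apply(simmat, 1L, max)) + sum(apply(simmat, 2L, max))) /
    (nrow(simmat) + ncol(simmat))
}

#' Gene-level GO functional similarity (per branch, best-match average)
#'
#' For each GO branch (BP, CC, MF), computes the Wang similarity matrix
#' between the two genes' term sets in that branch and combines it by the
#' best-match average (mean of row and column maxima). A branch in which
#' either gene has no annotation scores 0 and still enters the 3-branch
#' average.
#'
#' @param terms_a,terms_b character vectors of term ids annotated to each
#'   gene (branch membership is looked up in the DAG).
#' @param dag a `go_dag`.
#' @param weights Wang edge weights.
#' @return list with `sim_bp`, `sim_cc`, `sim_mf`, `avg`.
#' @export
gene_functional_similarity <- function(terms_a, terms_b, dag,
                                       weights = c(is_a = 0.8,
                                                   part_of = 0.6)) {
  if (!length(terms_a) || !length(terms_b))
    stop("each gene needs at least one GO annotation", call. = FALSE)
  ns_of <- function(tt) dag$terms$namespace[match(tt, dag$terms$id)]
  if (any(is.na(ns_of(terms_a))) || any(is.na(ns_of(terms_b))))
    stop("annotation uses a term absent from the ontology", call. = FALSE)
  branch_sim <- vapply(c(BP = "BP", CC = "CC", MF = "MF"), function(b) {
    ta <- terms_a[ns_of(terms_a) == b]
    tb <- terms_b[ns_of(terms_b) == b]
    if (!length(ta) || !length(tb)) return(0)
    m <- outer(ta, tb, Vectorize(function(x, y)
      wang_term_similarity(x, y, dag, weights)))
    .bma(matrix(m, nrow = length(ta)))
  }, numeric(1L))
  list(sim_bp = unname(branch_sim["BP"]),
       sim_cc = unname(branch_sim["CC"]),
       sim_mf = unname(branch_sim["MF"]),
       avg = mean(branch_sim))
}

#' Permutation test for a Pearson co-expression correlation
#'
#' Shuffles `y` `n_perm` times with a seeded RNG and reports the add-one
#' permutation p-value for the two-sided alternative:
#' p = (1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1). The global RNG state
#' is left untouched.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation RNG.
#' @return list with `r` and `p_perm`.
#' @export
pearson_permutation_test <- function(x, y, n_perm = 1000L, seed = 1L) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  r_obs <- stats::cor(x, y)
  n <- length(y)
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  hits <- .with_seed(seed, {
    h <- 0L
    for (i in seq_len(n_perm)) {
      r <- sum(xs * ys[sample.int(n)]) / (n - 1)
      if (abs(r) >= abs(r_obs) - 1e-12) h <- h + 1L
    }
    h
  })
  list(r = r_obs, p_perm = (1 + hits) / (n_perm + 1))
}

# Evaluate `expr` under a temporary seed, restoring the caller's RNG
# state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Build the core co-function network
#'
#' For every unordered gene pair, an edge is included when all three
#' criteria hold: (1) permutation-tested co-expression with
#' `p_perm < alpha`; (2) average Wang GO similarity over the BP, CC and MF
#' branches `> go_min`; (3) co-methylation Pearson correlation with
#' analytic `p < alpha`. The edge weight is the signed co-methylation
#' Pearson coefficient.
#'
#' @param expr genes x samples expression matrix.
#' @param meth genes x samples promoter methylation matrix (same genes).
#' @param annotations named list mapping gene to its GO term ids.
#' @param dag a `go_dag`.
#' @param n_perm,seed permutation test settings.
#' @param alpha significance level for both correlation criteria.
#' @param go_min minimum 3-branch average GO similarity (default 0.2,
#'   strict).
#' @return list with `edges` (data.frame of retained edges with all
#'   criterion columns) and `pairs` (the full pair table before the
#'   criteria are applied).
#' @export
build_cofunction_network <- function(expr, meth, annotations, dag,
                                     n_perm = 1000L, seed = 1L,
                                     alpha = 0.05, go_min = 0.2) {
  genes <- rownames(expr)
  if (length(genes) < 2L)
    stop("need at least two genes", call. = FALSE)
  stopifnot(all(genes %in% rownames(meth)),
            all(genes %in% names(annotations)))
  pairs <- utils::combn(genes, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    ex <- pearson_permutation_test(expr[a, ], expr[b, ], n_perm,
                                   seed = seed + k)
    go <- gene_functional_similarity(annotations[[a]], annotations[[b]],
                                     dag)
    ct <- stats::cor.test(meth[a, ], meth[b, ])
    data.frame(gene_a = a, gene_b = b,
               expr_r = ex$r, expr_perm_p = ex$p_perm,
               go_sim_bp = go$sim_bp, go_sim_cc = go$sim_cc,
               go_sim_mf = go$sim_mf, go_sim_avg = go$avg,
               meth_r = unname(ct$estimate), meth_p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  keep <- tab$expr_perm_p < alpha & tab$go_sim_avg > go_min &
    tab$meth_p < alpha
  edges <- tab[keep, , drop = FALSE]
  edges$weight <- edges$meth_r
  rownames(edges) <- NULL
  list(edges = edges, pairs = tab)
}

#' Node degrees of an edge list
#'
#' @param edges data.frame with `gene_a`, `gene_b` columns.
#' @param nodes optional full node set (so isolated nodes report degree
#'   0).
#' @return data.frame `gene`, `degree`, sorted by decreasing degree then
#'   gene id.
#' @export
degree_stats <- function(edges, nodes = NULL) {
  all_nodes <- unique(c(nodes, edges$gene_a, edges$gene_b))
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = all_nodes))
  out <- data.frame(gene = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$gene), , drop = FALSE]
}

#' Extract the PPI module around a seed gene
#'
#' Nodes are the seed plus its direct interaction partners; edges are all
#' PPI edges with both endpoints in that node set (seed-neighbor and
#' neighbor-neighbor links).
#'
#' @param ppi data.frame with columns `gene_a`, `gene_b`.
#' @param seed_gene seed gene id.
#' @return list with `nodes` and `edges`.
#' @export
extract_seed_module <- function(ppi, seed_gene) {
  nodes_all <- unique(c(ppi$gene_a, ppi$gene_b))
  if (!seed_gene %in% nodes_all)
    stop("seed gene absent from the PPI network", call. = FALSE)
  nb <- unique(c(ppi$gene_b[ppi$gene_a == seed_gene],
                 ppi$gene_a[ppi$gene_b == seed_gene]))
  nodes <- union(seed_gene, nb)
  edges <- ppi[ppi$gene_a %in% nodes & ppi$gene_b %in% nodes, ,
               drop = FALSE]
  rownames(edges) <- NULL
  list(nodes = sort(nodes), edges = edges)
}

#' Fisher exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test; the two-sided p-value sums the
#' probabilities of all tables (at fixed margins) no more probable than
#' the observed one.
#'
#' @param table 2x2 matrix of nonnegative counts.
#' @param alternative passed to [stats::fisher.test()].
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_exact <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  if (any(table < 0) || any(dim(table) != 2L))
    stop("a 2x2 table of nonnegative counts is required", call. = FALSE)
  ft <- stats::fisher.test(table, alternative = alternative)
  list(odds_ratio = unname(ft$estimate), p = ft$p.value)
}

#' Upper-tail hypergeometric enrichment probability
#'
#' P(X >= hit_count) when drawing `set_size` genes from a universe of
#' `universe_size` containing `category_size` category members.
#'
#' @param hit_count observed category hits in the set.
#' @param set_size size of the gene set.
#' @param category_size category size in the universe.
#' @param universe_size universe size.
#' @return p-value.
#' @export
hypergeometric_enrichment <- function(hit_count, set_size, category_size,
                                      universe_size) {
  if (hit_count > min(set_size, category_size) ||
      set_size > universe_size || category_size > universe_size ||
      any(c(hit_count, set_size, category_size, universe_size) < 0))
    stop("inconsistent counts", call. = FALSE)
  stats::phyper(hit_count - 1, category_size,
                universe_size - category_size, set_size,
                lower.tail = FALSE)
}

#' Read a PPI edge list
#'
#' @param path two-column TSV (`gene_a`, `gene_b`), with or without
#'   header.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
read_ppi <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  names(d)[1:2] <- c("gene_a", "gene_b")
  d[, 1:2]
}

#' Read gene-to-GO-term annotations
#'
#' @param path TSV with columns gene, term (and optionally branch), with
#'   or without header.
#' @return named list mapping gene to character vector of term ids.
#' @export
read_go_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene", first, ignore.case = TRUE)
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  split(as.character(d[[2L]]), as.character(d[[1L]]))
}
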