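# End-to-end driver: from on-disk study inputs to biomarker candidates
# and the core co-function network.

#' Run the integrated methylome/transcriptome pipeline
#'
#' Reads a study directory (genome FASTA, transcript GTF, CpG-island BED,
#' per-sample Bismark-coverage methylation calls, FPKM table,
#' coding-potential scores, GO ontology + annotations, PPI edge list --
#' the layout written by [simulate_ptc_study()]) and runs all stages:
#' promoter extraction and CpG-density classification, shared-CpG-site
#' filtering, promoter methylation and top-quantile DMP calling,
#' low-expression filtering and per-pair DE calling, the novel-lincRNA
#' cascade, the sign-consistent DMP/DE intersection gated on CpG islands
#' and negative methylation-expression correlation, and the co-function
#' network over the candidate genes.
#'
#' @param dir study directory.
#' @param dmp_quantile top fraction of |delta| called as DMP (default
#'   0.05).
#' @param alpha significance level used by the DE test, the correlation
#'   screen and the network criteria (default 0.05).
#' @param n_perm permutations for the co-expression test (default 1000).
#' @param seed seed for the permutation RNG (default 1).
#' @return object of class `ptc_pipeline`: list with `promoters`, `dmp`,
#'   `de`, `candidates`, `novel_lincrnas`, `network`, `degrees`,
#'   `ppi_module`, `cpg`, `meth_levels`, `expression`, `summaries`.
#' @export
run_ptc_pipeline <- function(dir, dmp_quantile = 0.05, alpha = 0.05,
                             n_perm = 1000L, seed = 1L) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  models <- read_transcript_models(file.path(dir, "transcripts.gtf"))
  islands <- read_cpg_islands(file.path(dir, "cpg_islands.bed"))

  known <- models[is.na(models$class_code) | models$class_code != "x", ,
                  drop = FALSE]
  candidates <- models[!is.na(models$class_code) &
                         models$class_code == "x", , drop = FALSE]

  promoters <- promoter_records(known, genome, islands)

  cov_files <- sort(list.files(dir, pattern = "^meth_.*\\.cov$",
                               full.names = TRUE))
  samples <- sub("^meth_(.*)\\.cov$", "\\1", basename(cov_files))
  calls <- lapply(cov_files, read_cpg_calls)
  names(calls) <- samples
  cpg <- filter_shared_sites(calls)

  meth_levels <- promoter_methylation(cpg, promoters)
  groups <- ifelse(grepl("^ca_", colnames(meth_levels)), "tumor",
                   "normal")
  deltas <- methylation_difference(meth_levels, groups)
  fclass <- stats::setNames(promoters$feature_class,
                            promoters$transcript_id)
  dmp <- call_dmps(deltas, fclass, quantile = dmp_quantile)

  expr <- read_expression(file.path(dir, "expression.tsv"))
  expr <- filter_low_expression(expr)
  de <- call_de(expr, alpha = alpha)

  scores <- utils::read.table(file.path(dir, "coding_potential.tsv"),
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  novel <- if (nrow(candidates))
    lincrna_filter(candidates, known, scores)
  else list(retained = character(), filters = NULL)

  cand <- biomarker_candidates(de, dmp, promoters, meth_levels, expr,
                               alpha = alpha)

  spans <- transcript_spans(known)
  spans$category <- promoters$feature_class[
    match(spans$transcript_id, promoters$transcript_id)]
  med_fpkm <- apply(expr, 1L, stats::median)
  summaries <- transcript_summaries(spans[!is.na(spans$category), ],
                                    med_fpkm)

  network <- NULL
  degrees <- NULL
  module <- NULL
  if (nrow(cand) >= 2L &&
      file.exists(file.path(dir, "ontology.obo"))) {
    dag <- read_go_obo(file.path(dir, "ontology.obo"))
    annotations <- read_go_annotations(file.path(dir,
                                                 "go_annotations.tsv"))
    genes <- cand$gene_id
    tx <- cand$transcript_id
    expr_g <- expr[tx, , drop = FALSE]
    meth_g <- meth_levels[tx, colnames(expr_g), drop = FALSE]
    rownames(expr_g) <- rownames(meth_g) <- genes
    have_go <- genes %in% names(annotations)
    if (sum(have_go) >= 2L) {
      network <- build_cofunction_network(
        expr_g[have_go, , drop = FALSE], meth_g[have_go, , drop = FALSE],
        annotations, dag, n_perm = n_perm, seed = seed, alpha = alpha)
      degrees <- degree_stats(network$edges, nodes = genes[have_go])
      if (file.exists(file.path(dir, "ppi.tsv")) &&
          nrow(network$edges)) {
        ppi <- read_ppi(file.path(dir, "ppi.tsv"))
        hub <- degrees$gene[1L]
        if (hub %in% c(ppi$gene_a, ppi$gene_b))
          module <- extract_seed_module(ppi, hub)
      }
    }
  }

  structure(list(promoters = promoters, cpg = cpg,
                 meth_levels = meth_levels, dmp = dmp,
                 expression = expr, de = de,
                 novel_lincrnas = novel$retained,
                 lincrna_filters = novel$filters,
                 candidates = cand, summaries = summaries,
                 network = network, degrees = degrees,
                 ppi_module = module),
            class = "ptc_pipeline")
}

#' @export
print.ptc_pipeline <- function(x, ...) {
  cd <- class_distribution(x$promoters$cpg_class)
  cat("ptc_pipeline results\n")
  cat("  promoters: ", nrow(x$promoters), " (",
      paste(sprintf("%s %d [%.1f%%]", cd$class, cd$n, cd$pct),
            collapse = ", "), ")\n", sep = "")
  cat("  shared CpG sites:", nrow(x$cpg$level), "\n")
  cat("  DMPs:", nrow(x$dmp), "(",
      sum(x$dmp$direction == "hyper"), "hyper /",
      sum(x$dmp$direction == "hypo"), "hypo )\n")
  cat("  DE transcripts:", nrow(x$de), "(",
      sum(x$de$direction == "up"), "up /",
      sum(x$de$direction == "down"), "down )\n")
  cat("  novel lincRNAs:", length(x$novel_lincrnas), "\n")
  cat("  biomarker candidates:", nrow(x$candidates), "\n")
  if (!is.null(x$network))
    cat("  co-function network:", nrow(x$network$edges), "edges; top gene:",
        x$degrees$gene[1L], "\n")
  invisible(x)
}

#' @export
summary.ptc_pipeline <- function(object, ...) {
  print(object)
  if (nrow(object$candidates)) {
    cat("\ncandidates:\n")
    print(object$candidates[, c("transcript_id", "gene_id",
                                "dmp_direction", "de_direction", "delta",
                                "meth_expr_r", "meth_expr_p")],
          row.names = FALSE)
  }
  invisible(object)
}
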