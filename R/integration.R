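# Methylation-expression integration: sign-consistent overlap of DMP and
# DE calls, CpG-island gating, and Pearson methylation-expression
# correlation.

#' Sign-consistent intersection of DE and DMP calls
#'
#' Keeps transcripts that are both differentially expressed and
#' differentially methylated with concordant regulatory sign: promoter
#' hypermethylation with down-regulation, or hypomethylation with
#' up-regulation. All other combinations are excluded.
#'
#' @param de data.frame of DE records (see [call_de()]).
#' @param dmp data.frame of DMP records (see [call_dmps()]).
#' @return merged data.frame, one row per sign-consistent transcript, with
#'   `dmp_direction` and `de_direction` columns.
#' @export
intersect_de_dm <- function(de, dmp) {
  m <- merge(dmp[, c("transcript_id", "feature_class", "mean_tumor",
                     "mean_normal", "delta", "direction")],
             de[, c("transcript_id", "p_value", "direction")],
             by = "transcript_id",
             suffixes = c("_dmp", "_de"))
  names(m)[names(m) == "direction_dmp"] <- "dmp_direction"
  names(m)[names(m) == "direction_de"] <- "de_direction"
  keep <- (m$dmp_direction == "hyper" & m$de_direction == "down") |
    (m$dmp_direction == "hypo" & m$de_direction == "up")
  m[keep, , drop = FALSE]
}

#' Keep candidates whose promoter overlaps a CpG island
#'
#' @param candidates data.frame with a `transcript_id` column.
#' @param promoters promoter records with `transcript_id`, `chrom`,
#'   `start`, `end` (and optionally a precomputed `has_cpg_island`).
#' @param islands CpG-island intervals (0-based half-open); ignored when
#'   `promoters` already carries `has_cpg_island`.
#' @return filtered candidate data.frame.
#' @export
require_cpg_island <- function(candidates, promoters, islands = NULL) {
  i <- match(candidates$transcript_id, promoters$transcript_id)
  if (any(is.na(i)))
    stop("candidate(s) without promoter record", call. = FALSE)
  has <- if ("has_cpg_island" %in% names(promoters) && is.null(islands)) {
    promoters$has_cpg_island[i]
  } else {
    vapply(i, function(k) overlaps_cpg_island(
      promoters$chrom[k], promoters$start[k], promoters$end[k], islands),
      logical(1L))
  }
  candidates[has, , drop = FALSE]
}

#' Pearson correlation between promoter methylation and expression
#'
#' Two-sided p-value from the t transform with n - 2 degrees of freedom
#' (as in [stats::cor.test()]). Callers screening for methylation-repressed
#' genes additionally require r < 0.
#'
#' @param meth,expr per-sample methylation levels and expression values,
#'   aligned.
#' @return list with `r` and `p`.
#' @export
meth_expr_correlation <- function(meth, expr) {
  if (length(meth) != length(expr) || length(meth) < 3L)
    stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(meth) == 0 || stats::sd(expr) == 0)
    stop("zero variance in methylation or expression", call. = FALSE)
  ct <- stats::cor.test(meth, expr, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Biomarker candidates from the three integration gates
#'
#' Runs the sign-consistency intersection, the CpG-island gate, and the
#' negative methylation-expression correlation screen (Pearson r < 0 with
#' p < alpha across all samples, tumor and normal pooled). When several
#' transcripts of one gene survive, the transcript with the largest
#' |delta| is reported for that gene.
#'
#' @param de,dmp differential calls (see [call_de()], [call_dmps()]).
#' @param promoters promoter records (see [promoter_records()]).
#' @param meth_levels promoter x sample methylation matrix.
#' @param expr FPKM matrix (same sample columns).
#' @param alpha correlation significance level (default 0.05).
#' @param collapse_genes report one transcript (largest |delta|) per gene
#'   (default TRUE).
#' @return data.frame of biomarker candidates with correlation columns
#'   `meth_expr_r`, `meth_expr_p`.
#' @export
biomarker_candidates <- function(de, dmp, promoters, meth_levels, expr,
                                 alpha = 0.05, collapse_genes = TRUE) {
  cand <- intersect_de_dm(de, dmp)
  cand <- require_cpg_island(cand, promoters)
  if (nrow(cand) == 0L) {
    cand$meth_expr_r <- numeric(0)
    cand$meth_expr_p <- numeric(0)
    cand$gene_id <- character(0)
    return(cand)
  }
  samples <- intersect(colnames(meth_levels), colnames(expr))
  rp <- t(vapply(cand$transcript_id, function(id) {
    res <- tryCatch(
      meth_expr_correlation(meth_levels[id, samples], expr[id, samples]),
      error = function(e) list(r = NA_real_, p = NA_real_))
    c(res$r, res$p)
  }, numeric(2L)))
  cand$meth_expr_r <- rp[, 1L]
  cand$meth_expr_p <- rp[, 2L]
  cand <- cand[!is.na(cand$meth_expr_r) &
                 cand$meth_expr_r < 0 & cand$meth_expr_p < alpha, ,
               drop = FALSE]
  cand$gene_id <- promoters$gene_id[match(cand$transcript_id,
                                          promoters$transcript_id)]
  if (collapse_genes && nrow(cand) > 1L) {
    keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$gene_id),
                          function(idx) idx[which.max(abs(cand$delta[idx]))]))
    cand <- cand[sort(keep), , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}
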