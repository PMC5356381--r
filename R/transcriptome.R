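# Expression matrices with tumor/normal pair structure, the per-pair
# fold-change differential-expression rule, the novel-lincRNA filter
# cascade, transcript summaries and ROC/AUC evaluation.

#' Read an FPKM expression table
#'
#' Rows are transcripts, columns samples named `ca_1..ca_n` (tumor) and
#' `adj_1..adj_n` (matched normal).
#'
#' @param path tab-separated table with a transcript id column first and a
#'   header of sample names.
#' @return numeric matrix with transcript rownames.
#' @export
read_expression <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         row.names = 1L, check.names = FALSE)
  as.matrix(d)
}

#' Pair structure of an expression matrix
#'
#' @param m matrix with `ca_i`/`adj_i` column names.
#' @return data.frame with columns `pair`, `tumor`, `normal`.
#' @export
pair_map <- function(m) {
  cn <- colnames(m)
  idx <- sort(as.integer(sub("^ca_", "", cn[grepl("^ca_", cn)])))
  if (length(idx) == 0L)
    stop("no tumor (ca_*) samples found", call. = FALSE)
  tum <- paste0("ca_", idx)
  nor <- paste0("adj_", idx)
  if (!all(nor %in% cn))
    stop("missing normal sample for pair(s): ",
         paste(idx[!nor %in% cn], collapse = ", "), call. = FALSE)
  data.frame(pair = idx, tumor = tum, normal = nor,
             stringsAsFactors = FALSE)
}

#' Remove low-expressed transcripts
#'
#' Drops transcripts with FPKM below `fpkm_floor` in strictly more than
#' `sample_fraction` of the samples.
#'
#' @param m FPKM matrix.
#' @param fpkm_floor expression floor (default 0.01).
#' @param sample_fraction fraction of samples (default 0.5); strictly more
#'   than this fraction must be below the floor for removal.
#' @return the filtered matrix.
#' @export
filter_low_expression <- function(m, fpkm_floor = 0.01,
                                  sample_fraction = 0.5) {
  stopifnot(nrow(m) > 0L)
  low <- rowSums(m < fpkm_floor)
  m[low <= sample_fraction * ncol(m), , drop = FALSE]
}

#' Per-pair tumor/normal fold changes
#'
#' FC = (tumor + pseudocount) / (normal + pseudocount) for each matched
#' pair.
#'
#' @param m FPKM matrix.
#' @param pairs data.frame from [pair_map()]; derived from `m` by default.
#' @param pseudocount added to numerator and denominator (default 0.01,
#'   the scale of the expression floor).
#' @return matrix transcripts x pairs of fold changes.
#' @export
per_pair_fold_change <- function(m, pairs = pair_map(m),
                                 pseudocount = 0.01) {
  fc <- sapply(seq_len(nrow(pairs)), function(i)
    (m[, pairs$tumor[i]] + pseudocount) /
      (m[, pairs$normal[i]] + pseudocount))
  fc <- matrix(fc, nrow = nrow(m),
               dimnames = list(rownames(m), paste0("pair_", pairs$pair)))
  fc
}

# Default p-value: one-sample location test (t-type) of per-pair log2 fold
# changes against 0. Degenerate (constant) input gets p = 1.
.default_de_test <- function(log2fc) {
  if (length(unique(round(log2fc, 12))) < 2L) return(1)
  tryCatch(stats::t.test(log2fc, mu = 0)$p.value, error = function(e) 1)
}

#' Call differentially expressed transcripts by the per-pair rule
#'
#' A transcript is up-regulated when its fold change exceeds `fc_up` in
#' every tumor/normal pair, down-regulated when below `fc_down` in every
#' pair, and in either case the p-value from `test` must fall below
#' `alpha`. The test is pluggable; the default is a one-sample t-type test
#' of the per-pair log2 fold changes against 0.
#'
#' @param m FPKM matrix.
#' @param pairs pair structure (see [pair_map()]).
#' @param alpha significance level (default 0.05).
#' @param fc_up,fc_down fold-change bounds (defaults 1.5 and 2/3).
#' @param pseudocount see [per_pair_fold_change()].
#' @param test function(log2fc) -> p-value.
#' @return data.frame of DE records: `transcript_id`, per-pair fold
#'   changes, `p_value`, `direction` (`up`/`down`).
#' @export
call_de <- function(m, pairs = pair_map(m), alpha = 0.05,
                    fc_up = 1.5, fc_down = 2 / 3, pseudocount = 0.01,
                    test = .default_de_test) {
  if (nrow(pairs) < 2L)
    stop("at least two tumor/normal pairs are required", call. = FALSE)
  fc <- per_pair_fold_change(m, pairs, pseudocount)
  p <- apply(log2(fc), 1L, test)
  up <- apply(fc, 1L, function(x) all(x > fc_up))
  dn <- apply(fc, 1L, function(x) all(x < fc_down))
  called <- (up | dn) & p < alpha
  out <- data.frame(transcript_id = rownames(m)[called],
                    p_value = p[called],
                    direction = ifelse(up[called], "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fc[called, , drop = FALSE], row.names = NULL))
}

# Distance between two 0-based half-open intervals on one chromosome:
# 0 when they overlap, otherwise the gap length.
.interval_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmax(a_start, b_start) - pmin(a_end, b_end))
}

#' Transcript-level span table from exon models
#'
#' @param models data.frame with one row per exon (`transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, plus optional
#'   `class_code`/`biotype`/`feature_class`).
#' @return data.frame with one row per transcript: span, exon count and
#'   summed exonic length.
#' @export
transcript_spans <- function(models) {
  sp <- split(models, models$transcript_id)
  out <- do.call(rbind, lapply(sp, function(e) {
    data.frame(transcript_id = e$transcript_id[1L],
               gene_id = e$gene_id[1L],
               chrom = e$chrom[1L], start = min(e$start), end = max(e$end),
               strand = e$strand[1L],
               class_code = if ("class_code" %in% names(e))
                 e$class_code[1L] else NA_character_,
               n_exons = nrow(e),
               length = sum(e$end - e$start),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Novel-lincRNA filter cascade
#'
#' Retains candidate transcripts that pass all of: summed exonic length
#' over 200 nt; more than one exon; assembler class code `"x"`; no exonic
#' overlap (>= 1 bp, either strand) with any known transcript; distance of
#' at least 1000 bp from the nearest protein-coding gene; CPC score < 0;
#' CPAT score < 0.364. All cutoffs are strict.
#'
#' @param candidates exon-level data.frame of candidate transcript models.
#' @param known exon-level data.frame of known transcript models; rows
#'   with `biotype == "protein_coding"` define the coding genes used for
#'   the distance rule.
#' @param coding_scores data.frame with columns `transcript_id`, `cpc`,
#'   `cpat`; every candidate must be present.
#' @param min_length,min_distance,cpc_max,cpat_max rule cutoffs.
#' @return list with `retained` (character vector of transcript ids) and
#'   `filters` (logical matrix, one row per candidate, one column per
#'   rule).
#' @export
lincrna_filter <- function(candidates, known, coding_scores,
                           min_length = 200L, min_distance = 1000L,
                           cpc_max = 0, cpat_max = 0.364) {
  cand <- transcript_spans(candidates)
  miss <- setdiff(cand$transcript_id, coding_scores$transcript_id)
  if (length(miss))
    stop("candidate(s) missing from the coding-potential table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sc <- coding_scores[match(cand$transcript_id,
                            coding_scores$transcript_id), ]
  cand_ex <- split(candidates, candidates$transcript_id)
  # coding gene spans for the distance rule
  coding <- known[!is.na(known$biotype) & known$biotype == "protein_coding", ]
  gene_sp <- if (nrow(coding)) {
    sp <- split(coding, coding$gene_id)
    do.call(rbind, lapply(sp, function(e)
      data.frame(chrom = e$chrom[1L], start = min(e$start),
                 end = max(e$end), stringsAsFactors = FALSE)))
  } else data.frame(chrom = character(), start = integer(), end = integer())
  ok <- sapply(seq_len(nrow(cand)), function(i) {
    ex <- cand_ex[[cand$transcript_id[i]]]
    same <- known[known$chrom == cand$chrom[i], , drop = FALSE]
    overlap <- FALSE
    if (nrow(same)) for (j in seq_len(nrow(ex))) {
      if (any(same$start < ex$end[j] & same$end > ex$start[j])) {
        overlap <- TRUE
        break
      }
    }
    gs <- gene_sp[gene_sp$chrom == cand$chrom[i], , drop = FALSE]
    dist <- if (nrow(gs))
      min(.interval_gap(cand$start[i], cand$end[i], gs$start, gs$end))
    else Inf
    c(length = cand$length[i] > min_length,
      exons = cand$n_exons[i] > 1L,
      class_code = !is.na(cand$class_code[i]) & cand$class_code[i] == "x",
      no_overlap = !overlap,
      distance = dist >= min_distance,
      cpc = sc$cpc[i] < cpc_max,
      cpat = sc$cpat[i] < cpat_max)
  })
  filters <- t(matrix(ok, nrow = 7L,
                      dimnames = list(c("length", "exons", "class_code",
                                        "no_overlap", "distance",
                                        "cpc", "cpat"), NULL)))
  rownames(filters) <- cand$transcript_id
  list(retained = cand$transcript_id[rowSums(!filters) == 0L],
       filters = filters)
}

#' Per-category transcript structure and expression summaries
#'
#' @param spans transcript-level table (see [transcript_spans()]) with a
#'   `category` column.
#' @param fpkm optional named vector of per-transcript median (or mean)
#'   FPKM.
#' @return data.frame per category: mean exon count, mean length, median
#'   expression. Empty categories are absent.
#' @export
transcript_summaries <- function(spans, fpkm = NULL) {
  sp <- split(spans, spans$category)
  out <- do.call(rbind, lapply(names(sp), function(k) {
    d <- sp[[k]]
    med <- if (is.null(fpkm)) NA_real_ else
      stats::median(fpkm[d$transcript_id], na.rm = TRUE)
    data.frame(category = k,
               n = nrow(d),
               mean_exons = mean(d$n_exons),
               mean_length = mean(d$length),
               median_fpkm = med,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' ROC AUC and Youden-optimal cutoff for a tumor/normal biomarker
#'
#' The AUC is computed by the rank (Mann-Whitney) formulation with ties
#' handled by midranks; the orientation is chosen so that AUC >= 0.5 and
#' is reported in `direction` (`"tumor_high"` or `"tumor_low"`). The
#' cutoff maximizes Youden's J = sensitivity + specificity - 1 over
#' midpoints between adjacent distinct values.
#'
#' @param values numeric biomarker values per sample.
#' @param labels character vector, `"tumor"` or `"normal"`.
#' @return list with `auc`, `cutoff`, `direction`, `sensitivity`,
#'   `specificity` (at the cutoff).
#' @export
auc_roc <- function(values, labels) {
  stopifnot(length(values) == length(labels),
            all(labels %in% c("tumor", "normal")))
  n1 <- sum(labels == "tumor")
  n0 <- sum(labels == "normal")
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(values)
  auc <- (sum(r[labels == "tumor"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  direction <- "tumor_high"
  if (auc < 0.5) {
    auc <- 1 - auc
    direction <- "tumor_low"
  }
  v <- if (direction == "tumor_high") values else -values
  sv <- sort(unique(v))
  cuts <- if (length(sv) > 1L) (sv[-1L] + sv[-length(sv)]) / 2
          else sv
  best <- NULL
  for (cut in cuts) {
    sens <- mean(v[labels == "tumor"] > cut)
    spec <- mean(v[labels == "normal"] <= cut)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j)
      best <- list(cut = cut, sens = sens, spec = spec, j = j)
  }
  cutoff <- if (direction == "tumor_high") best$cut else -best$cut
  list(auc = auc, cutoff = cutoff, direction = direction,
       sensitivity = best$sens, specificity = best$spec)
}
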