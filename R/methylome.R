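# RRBS methylome: Bismark-coverage ingestion, site filters, promoter
# methylation, top-quantile differential-methylation calls, TSS profiles.

#' Read per-sample CpG methylation calls (Bismark coverage dialect)
#'
#' Expects tab-separated columns: chrom, start, end (both 1-based),
#' methylation percentage (0-100), count methylated, count unmethylated.
#' The methylation level is recomputed from the counts; the percent column
#' is only cross-checked (within 0.5 percentage points) to catch corrupted
#' files. Sites with zero total coverage are skipped with a warning.
#'
#' @param path coverage file.
#' @return data.frame with columns `chrom`, `pos` (1-based CpG position),
#'   `level` (fraction methylated), `coverage`.
#' @export
read_cpg_calls <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end",
                                       "pct", "m", "u"),
                         colClasses = c("character", "integer", "integer",
                                       "numeric", "integer", "integer"))
  bad <- which(is.na(d$start) | is.na(d$pct) | is.na(d$m) | is.na(d$u) |
               d$m < 0 | d$u < 0)
  if (length(bad))
    stop("malformed coverage line ", bad[1L], " in ", path, call. = FALSE)
  cov <- d$m + d$u
  zero <- cov == 0L
  if (any(zero)) {
    warning(sum(zero), " site(s) with zero coverage skipped in ",
            basename(path), call. = FALSE)
    d <- d[!zero, , drop = FALSE]
    cov <- cov[!zero]
  }
  level <- d$m / cov
  off <- abs(d$pct - 100 * level)
  if (any(off > 0.5)) {
    i <- which(off > 0.5)[1L]
    stop("percent column inconsistent with counts at line ", i,
         " (", d$pct[i], "% vs counts ", d$m[i], "/", cov[i], ")",
         call. = FALSE)
  }
  data.frame(chrom = d$chrom, pos = d$start, level = level,
             coverage = cov, stringsAsFactors = FALSE)
}

#' Write CpG calls in the Bismark coverage dialect
#'
#' @param calls data.frame as returned by [read_cpg_calls()].
#' @param path output file.
#' @export
write_cpg_calls <- function(calls, path) {
  out <- data.frame(calls$chrom, calls$pos, calls$pos,
                    round(100 * calls$level, 6),
                    as.integer(round(calls$level * calls$coverage)),
                    as.integer(round((1 - calls$level) * calls$coverage)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.is_sex_chrom <- function(chrom) {
  toupper(sub("^chr", "", chrom)) %in% c("X", "Y")
}

#' Build the shared CpG site matrix across samples
#'
#' Drops sites on the X and Y chromosomes (names `X`/`Y`/`chrX`/`chrY`),
#' retains sites covered at least `min_coverage`-fold in at least one
#' sample, and intersects to the sites present in every sample, yielding
#' one shared site set.
#'
#' @param samples named list of per-sample call data.frames
#'   (see [read_cpg_calls()]).
#' @param min_coverage minimum read depth (default 5).
#' @return An object of class `cpg_matrix`: a list with `sites`
#'   (data.frame `chrom`, `pos`), `level` and `coverage`
#'   (site x sample matrices).
#' @export
filter_shared_sites <- function(samples, min_coverage = 5L) {
  stopifnot(is.list(samples), length(samples) >= 2L)
  if (is.null(names(samples)))
    names(samples) <- paste0("sample_", seq_along(samples))
  keyed <- lapply(samples, function(d) {
    d <- d[!.is_sex_chrom(d$chrom), , drop = FALSE]
    key <- paste(d$chrom, d$pos, sep = ":")
    d[!duplicated(key), , drop = FALSE]
  })
  keys <- lapply(keyed, function(d) paste(d$chrom, d$pos, sep = ":"))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L)
    stop("no CpG sites shared across all samples", call. = FALSE)
  lev <- sapply(seq_along(keyed), function(i) {
    d <- keyed[[i]]
    d$level[match(shared, keys[[i]])]
  })
  cov <- sapply(seq_along(keyed), function(i) {
    d <- keyed[[i]]
    d$coverage[match(shared, keys[[i]])]
  })
  lev <- matrix(lev, ncol = length(keyed),
                dimnames = list(NULL, names(samples)))
  cov <- matrix(cov, ncol = length(keyed),
                dimnames = list(NULL, names(samples)))
  keep <- apply(cov, 1L, max) >= min_coverage
  if (!any(keep))
    stop("no CpG sites pass the coverage filter", call. = FALSE)
  parts <- strsplit(shared[keep], ":", fixed = TRUE)
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = as.integer(vapply(parts, `[`, "", 2L)),
                      stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos)
  structure(list(sites = sites[o, , drop = FALSE],
                 level = lev[keep, , drop = FALSE][o, , drop = FALSE],
                 coverage = cov[keep, , drop = FALSE][o, , drop = FALSE]),
            class = "cpg_matrix")
}

#' @export
print.cpg_matrix <- function(x, ...) {
  cat("cpg_matrix:", nrow(x$level), "shared CpG sites x",
      ncol(x$level), "samples\n")
  cat("chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' Promoter methylation: per-sample mean CpG level in each promoter
#'
#' Unweighted mean of site-level methylation over the CpG sites falling in
#' each promoter interval. Promoters containing no covered site get NA
#' (absent), never 0.
#'
#' @param mat a `cpg_matrix` (see [filter_shared_sites()]).
#' @param promoters data.frame with `transcript_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return matrix promoters x samples of mean methylation levels, rownames
#'   the transcript ids.
#' @export
promoter_methylation <- function(mat, promoters) {
  stopifnot(inherits(mat, "cpg_matrix"))
  pos0 <- mat$sites$pos - 1L
  ns <- ncol(mat$level)
  res <- vapply(seq_len(nrow(promoters)), function(i) {
    in_prom <- mat$sites$chrom == promoters$chrom[i] &
      pos0 >= promoters$start[i] & pos0 < promoters$end[i]
    if (!any(in_prom)) return(rep(NA_real_, ns))
    colMeans(mat$level[in_prom, , drop = FALSE])
  }, numeric(ns))
  out <- matrix(res, ncol = ns, byrow = TRUE)
  rownames(out) <- promoters$transcript_id
  colnames(out) <- colnames(mat$level)
  out
}

#' Tumor-normal promoter methylation differences
#'
#' delta = mean over tumor samples - mean over normal samples. Promoters
#' with an absent methylation value in any sample are excluded.
#'
#' @param levels promoter x sample matrix (see [promoter_methylation()]).
#' @param groups character vector (`"tumor"`/`"normal"`) aligned with the
#'   columns of `levels`.
#' @return data.frame `transcript_id`, `mean_tumor`, `mean_normal`,
#'   `delta`.
#' @export
methylation_difference <- function(levels, groups) {
  stopifnot(ncol(levels) == length(groups),
            all(groups %in% c("tumor", "normal")))
  if (!any(groups == "tumor") || !any(groups == "normal"))
    stop("both tumor and normal samples are required", call. = FALSE)
  keep <- stats::complete.cases(levels)
  lv <- levels[keep, , drop = FALSE]
  mt <- rowMeans(lv[, groups == "tumor", drop = FALSE])
  mn <- rowMeans(lv[, groups == "normal", drop = FALSE])
  data.frame(transcript_id = rownames(lv), mean_tumor = mt,
             mean_normal = mn, delta = mt - mn,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially methylated promoters by the top-quantile rule
#'
#' Within each feature class (mRNA, lncRNA) separately, promoters whose
#' absolute tumor-normal difference reaches the top `quantile` fraction of
#' that class are called differentially methylated. The threshold is the
#' ceiling(quantile * N)-th largest |delta|; ties at the threshold are all
#' included. Direction is `hyper` when delta > 0, else `hypo`; a delta of
#' exactly 0 is never called.
#'
#' @param deltas data.frame from [methylation_difference()].
#' @param feature_class named character vector (or data.frame column)
#'   mapping transcript_id to `"mRNA"`/`"lncRNA"`.
#' @param quantile top fraction called (default 0.05).
#' @return data.frame of DMP records: `transcript_id`, `feature_class`,
#'   `mean_tumor`, `mean_normal`, `delta`, `direction`, `threshold`.
#' @export
call_dmps <- function(deltas, feature_class, quantile = 0.05) {
  fc <- feature_class[deltas$transcript_id]
  if (any(is.na(fc)))
    stop("feature class missing for some promoters", call. = FALSE)
  out <- lapply(split(seq_len(nrow(deltas)), fc), function(idx) {
    d <- deltas[idx, , drop = FALSE]
    n <- nrow(d)
    if (n < 20L)
      stop("fewer than 20 promoters in a feature class; ",
           "quantile threshold unstable", call. = FALSE)
    a <- abs(d$delta)
    thr <- sort(a, decreasing = TRUE)[ceiling(quantile * n)]
    called <- d[a >= thr & d$delta != 0, , drop = FALSE]
    if (nrow(called) == 0L) return(NULL)
    called$direction <- ifelse(called$delta > 0, "hyper", "hypo")
    called$threshold <- thr
    called
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(transcript_id = character(), feature_class = character(),
                      mean_tumor = numeric(), mean_normal = numeric(),
                      delta = numeric(), direction = character(),
                      threshold = numeric()))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$feature_class <- unname(feature_class[res$transcript_id])
  res[, c("transcript_id", "feature_class", "mean_tumor", "mean_normal",
          "delta", "direction", "threshold")]
}

#' Label a methylation level as hypo-, intermediate or hypermethylated
#'
#' Levels below 0.2 are hypomethylated and levels above 0.6
#' hypermethylated; both cuts are strict, so 0.2 and 0.6 are intermediate.
#'
#' @param level numeric vector of methylation fractions in `[0, 1]`.
#' @return character vector of state labels.
#' @export
label_methylation_state <- function(level) {
  if (any(is.na(level)) || any(level < 0 | level > 1))
    stop("methylation level must lie in [0, 1]", call. = FALSE)
  ifelse(level < 0.2, "hypomethylated",
         ifelse(level > 0.6, "hypermethylated", "intermediate"))
}

#' CpG density and methylation profile by distance to the TSS
#'
#' Aggregates, in bins of signed distance to the TSS (upstream negative,
#' strand-aware), the window CpG ratio, GC content and mean methylation
#' across promoters. Empty bins are absent from the output.
#'
#' @param mat a `cpg_matrix`.
#' @param promoters promoter records with `chrom`, `start`, `end`,
#'   `strand`, `tss` and `sequence` columns (see [promoter_records()]).
#' @param bin_width bin width in bp.
#' @return data.frame `bin_start`, `bin_mid`, `cpg_ratio`, `gc_content`,
#'   `methylation` (bin boundaries in signed distance, 0-based).
#' @export
tss_profile <- function(mat, promoters, bin_width = 100L) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  bw <- as.integer(bin_width)
  acc <- new.env(parent = emptyenv())
  add <- function(store, bin, vals) {
    key <- as.character(bin)
    cur <- if (!is.null(acc[[store]][[key]])) acc[[store]][[key]] else numeric()
    if (is.null(acc[[store]])) acc[[store]] <- list()
    tmp <- acc[[store]]; tmp[[key]] <- c(cur, vals); acc[[store]] <- tmp
  }
  acc$ratio <- list(); acc$gc <- list(); acc$meth <- list()
  pos0 <- mat$sites$pos - 1L
  for (i in seq_len(nrow(promoters))) {
    p <- promoters[i, ]
    t0 <- p$tss - 1L
    # sequence bins: signed distance of each promoter base
    ch <- .seq_chars(p$sequence)
    gpos <- seq(p$start, p$end - 1L)
    dist <- if (p$strand == "+") gpos - t0 else t0 - gpos
    for (b in unique(dist %/% bw)) {
      sel <- dist %/% bw == b
      sub <- ch[sel][order(dist[sel])]
      s <- paste(sub, collapse = "")
      add("ratio", b, cpg_ratio(s))
      add("gc", b, gc_content(s))
    }
    in_prom <- mat$sites$chrom == p$chrom &
      pos0 >= p$start & pos0 < p$end
    if (any(in_prom)) {
      d <- if (p$strand == "+") pos0[in_prom] - t0 else t0 - pos0[in_prom]
      lv <- rowMeans(mat$level[in_prom, , drop = FALSE])
      for (b in unique(d %/% bw)) add("meth", b, lv[d %/% bw == b])
    }
  }
  bins <- sort(unique(as.integer(c(names(acc$ratio), names(acc$meth)))))
  mfun <- function(store, b) {
    v <- acc[[store]][[as.character(b)]]
    if (is.null(v)) NA_real_ else mean(v)
  }
  data.frame(
    bin_start = bins * bw,
    bin_mid = bins * bw + bw / 2,
    cpg_ratio = vapply(bins, function(b) mfun("ratio", b), 0),
    gc_content = vapply(bins, function(b) mfun("gc", b), 0),
    methylation = vapply(bins, function(b) mfun("meth", b), 0))
}
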