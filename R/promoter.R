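# Promoter definition, CpG-density metrics and HCP/ICP/LCP classification.
#
# Coordinate convention: all intervals handled here are 0-based half-open
# [start, end). GTF input (1-based closed) and BED input (native 0-based
# half-open) are converted on read; see read_transcript_models().

.seq_chars <- function(seq) {
  strsplit(toupper(seq), "", fixed = TRUE)[[1]]
}

.check_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("'seq' must be a single DNA string", call. = FALSE)
  if (nchar(seq) == 0L)
    stop("empty sequence", call. = FALSE)
  invisible(seq)
}

#' Promoter interval around a transcription start site
#'
#' Defines the promoter of a transcript as the window from 1500 bp upstream
#' of the TSS to 500 bp downstream of the TSS, where upstream/downstream are
#' strand-relative. The result is clipped to the contig.
#'
#' @param tss 1-based TSS position on the contig.
#' @param strand `"+"` or `"-"`.
#' @param contig_length length of the contig in bp.
#' @param upstream,downstream extent of the promoter on either side of the
#'   TSS (bp). Defaults 1500/500.
#' @return Integer vector `c(start, end)`: a 0-based half-open interval.
#' @examples
#' extract_promoter(10001, "+", 1e6)  # [8500, 10500)
#' @export
extract_promoter <- function(tss, strand, contig_length,
                             upstream = 1500L, downstream = 500L) {
  stopifnot(length(tss) == 1L, length(strand) == 1L)
  if (!strand %in% c("+", "-"))
    stop("unknown strand symbol: ", strand, call. = FALSE)
  if (tss < 1L || tss > contig_length)
    stop("TSS outside contig", call. = FALSE)
  t0 <- as.integer(tss) - 1L  # 0-based TSS
  if (strand == "+") {
    start <- t0 - upstream
    end   <- t0 + downstream
  } else {
    start <- t0 - downstream + 1L
    end   <- t0 + upstream + 1L
  }
  c(start = max(0L, as.integer(start)),
    end   = min(as.integer(contig_length), as.integer(end)))
}

#' CpG observed/expected ratio of a sequence
#'
#' Computed as (number of CpG dinucleotides x sequence length) /
#' (number of C x number of G). Length counts all characters including N;
#' N never contributes to the C, G or CpG counts. When the sequence contains
#' no C or no G the ratio is defined as 0.
#'
#' @param seq DNA string (A/C/G/T/N).
#' @return Non-negative numeric scalar.
#' @examples
#' cpg_ratio("CGCGCG")  # 2
#' @export
cpg_ratio <- function(seq) {
  .check_seq(seq)
  ch <- .seq_chars(seq)
  L  <- length(ch)
  nC <- sum(ch == "C")
  nG <- sum(ch == "G")
  if (nC == 0L || nG == 0L) return(0)
  nCG <- if (L < 2L) 0L else sum(ch[-L] == "C" & ch[-1L] == "G")
  nCG * L / (nC * nG)
}

#' GC content of a sequence
#'
#' (C count + G count) / length; N bases count in the denominator only.
#'
#' @inheritParams cpg_ratio
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  .check_seq(seq)
  ch <- .seq_chars(seq)
  sum(ch == "C" | ch == "G") / length(ch)
}

# Per-window counts at every 1-bp offset, via cumulative sums.
# Returns a list of vectors of length L - window + 1.
.window_counts <- function(ch, window) {
  L  <- length(ch)
  n  <- L - window + 1L
  cs <- function(x) cumsum(as.integer(x))
  cC  <- cs(ch == "C")
  cG  <- cs(ch == "G")
  # CpG pair starting at i (i in 1..L-1)
  pair <- ch[-L] == "C" & ch[-1L] == "G"
  cP <- cs(c(pair, FALSE))
  idx <- seq_len(n)
  wsum <- function(cum, from, to) cum[to] - c(0, cum)[from]
  list(
    nC  = wsum(cC, idx, idx + window - 1L),
    nG  = wsum(cG, idx, idx + window - 1L),
    # a pair counts when its first base lies within [i, i+window-2]
    nCG = wsum(cP, idx, idx + window - 2L)
  )
}

#' Classify a promoter sequence by CpG density
#'
#' Slides a 500-bp window across the sequence at 1-bp steps. HCP (high-CpG
#' promoter) if any window has CpG ratio > 0.75 and GC content > 0.55;
#' LCP (low-CpG) if no window has CpG ratio > 0.48; ICP otherwise. All
#' thresholds are strict inequalities, so boundary values do not qualify.
#'
#' @inheritParams cpg_ratio
#' @param window window size in bp (default 500).
#' @param hcp_ratio,hcp_gc,lcp_ratio class thresholds.
#' @return One of `"HCP"`, `"ICP"`, `"LCP"`.
#' @export
classify_promoter <- function(seq, window = 500L,
                              hcp_ratio = 0.75, hcp_gc = 0.55,
                              lcp_ratio = 0.48) {
  .check_seq(seq)
  ch <- .seq_chars(seq)
  if (length(ch) < window)
    stop("sequence shorter than the ", window, "-bp window", call. = FALSE)
  w <- .window_counts(ch, as.integer(window))
  denom <- w$nC * w$nG
  ratio <- ifelse(denom == 0, 0, w$nCG * window / denom)
  gc    <- (w$nC + w$nG) / window
  if (any(ratio > hcp_ratio & gc > hcp_gc)) return("HCP")
  if (!any(ratio > lcp_ratio)) return("LCP")
  "ICP"
}

#' Does a promoter interval overlap any CpG island?
#'
#' Both the promoter and the islands are 0-based half-open intervals; an
#' overlap means at least one shared base on the same chromosome.
#'
#' @param chrom,start,end the promoter interval.
#' @param islands data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Logical scalar.
#' @export
overlaps_cpg_island <- function(chrom, start, end, islands) {
  stopifnot(is.data.frame(islands),
            all(c("chrom", "start", "end") %in% names(islands)))
  any(islands$chrom == chrom & islands$start < end & islands$end > start)
}

#' Class counts and percentages for a set of promoters
#'
#' @param classes character vector of `"HCP"`/`"ICP"`/`"LCP"` labels.
#' @return data.frame with columns `class`, `n`, `pct` (percent of total),
#'   ordered HCP, ICP, LCP.
#' @export
class_distribution <- function(classes) {
  lv <- c("HCP", "ICP", "LCP")
  stopifnot(all(classes %in% lv))
  n <- as.integer(table(factor(classes, levels = lv)))
  data.frame(class = lv, n = n, pct = 100 * n / sum(n))
}

#' Build promoter records from genome, transcript models and islands
#'
#' For each transcript, extracts the promoter interval around its TSS,
#' pulls the genomic sequence, computes CpG ratio and GC content over the
#' full promoter, classifies the promoter, and flags CpG-island overlap.
#'
#' @param transcripts data.frame as returned by [read_transcript_models()]
#'   (one row per exon); the TSS is the strand-aware 5' end of the
#'   transcript span.
#' @param genome a named [Biostrings::DNAStringSet] of contigs.
#' @param islands data.frame of CpG islands (0-based half-open), or NULL.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end` (promoter, 0-based half-open),
#'   `strand`, `tss` (1-based), `feature_class`, `cpg_ratio`, `gc_content`,
#'   `cpg_class`, `has_cpg_island`, `sequence`.
#' @export
promoter_records <- function(transcripts, genome, islands = NULL) {
  tx <- split(transcripts, transcripts$transcript_id)
  rows <- lapply(tx, function(e) {
    chrom  <- e$chrom[1L]
    strand <- e$strand[1L]
    # transcript span in 0-based half-open coordinates
    span <- c(min(e$start), max(e$end))
    tss1 <- if (strand == "+") span[1L] + 1L else span[2L]  # 1-based
    clen <- length(genome[[chrom]])
    pr <- extract_promoter(tss1, strand, clen)
    s  <- as.character(Biostrings::subseq(genome[[chrom]],
                                          pr["start"] + 1L, pr["end"]))
    isl <- if (is.null(islands)) FALSE else
      overlaps_cpg_island(chrom, pr["start"], pr["end"], islands)
    data.frame(
      transcript_id = e$transcript_id[1L],
      gene_id = e$gene_id[1L],
      chrom = chrom, start = unname(pr["start"]), end = unname(pr["end"]),
      strand = strand, tss = tss1,
      feature_class = e$feature_class[1L],
      cpg_ratio = cpg_ratio(s), gc_content = gc_content(s),
      cpg_class = classify_promoter(s),
      has_cpg_island = isl,
      sequence = s,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read transcript models from a GTF file
#'
#' Imports exon records and converts coordinates to the package-internal
#' 0-based half-open convention. The transcript biotype is mapped to a
#' feature class: `protein_coding` becomes `mRNA`, everything else
#' `lncRNA`.
#'
#' @param path GTF file.
#' @return data.frame with one row per exon: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `class_code`, `biotype`,
#'   `feature_class`.
#' @export
read_transcript_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  cc <- if ("class_code" %in% names(md)) as.character(md$class_code)
        else rep(NA_character_, length(gr))
  bt <- if ("transcript_biotype" %in% names(md))
          as.character(md$transcript_biotype)
        else rep(NA_character_, length(gr))
  data.frame(
    transcript_id = as.character(md$transcript_id),
    gene_id = as.character(md$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class_code = cc,
    biotype = bt,
    feature_class = ifelse(!is.na(bt) & bt == "protein_coding",
                           "mRNA", "lncRNA"),
    stringsAsFactors = FALSE)
}

#' Read CpG-island intervals from a BED file
#'
#' @param path BED file (0-based half-open, as native BED).
#' @return data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_cpg_islands <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}
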