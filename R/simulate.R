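# Synthetic study generator: emits genome (FASTA), transcript models
# (GTF), CpG islands (BED), per-sample Bismark-coverage methylation
# calls, FPKM tables, coding-potential scores, a toy GO ontology with
# annotations, and a PPI edge list -- all with planted, recoverable
# ground truth (which promoters are HCP/ICP/LCP, which are differentially
# methylated and in which direction, which transcripts are differentially
# expressed, which genes are methylation-repressed candidates, and which
# gene pairs must pass all three co-function network criteria).

#' Configuration for the synthetic tumor/normal study
#'
#' Defaults emulate a three-pair matched tumor/normal design with an
#' HCP-dominant promoter landscape, a methylation shift of 0.3 planted in
#' 5\% of promoters, and a 4-fold expression change planted in a matched
#' subset, part of which is anti-correlated with promoter methylation.
#'
#' @param n_pairs tumor/normal pairs (default 3).
#' @param n_promoters_per_class named counts for HCP/ICP/LCP promoters.
#' @param promoter_length promoter block length in bp (default 2000,
#'   i.e. -1500/+500 around the TSS); must be >= 500.
#' @param n_planted_dmp promoters given a group methylation shift.
#' @param delta_mu planted methylation shift (fraction in (0, 1)).
#' @param n_planted_de transcripts given an expression fold change.
#' @param planted_fc planted fold change (> 0).
#' @param n_anticorrelated planted methylation-repressed genes (both DMP
#'   and DE, opposite signs, expression coupled to realized methylation);
#'   at most `min(n_planted_dmp, n_planted_de)`.
#' @param coverage_mean mean CpG read depth (Poisson; constant when
#'   `noise_sd` is 0).
#' @param noise_sd per-sample methylation noise (also reused as the
#'   log-scale expression noise); 0 gives the deterministic noiseless
#'   limit.
#' @param mrna_fraction fraction of promoters labeled mRNA (rest lncRNA).
#' @param island_fraction fraction of non-candidate promoters given a CpG
#'   island (all candidate promoters get one).
#' @param low_coverage_fraction fraction of CpG sites emitted below 5x in
#'   every sample, to exercise the coverage filter.
#' @param seed integer RNG seed; identical configurations give
#'   byte-identical output files.
#' @return validated list of class `sim_config`.
#' @export
simulation_config <- function(n_pairs = 3L,
                              n_promoters_per_class = c(HCP = 240L,
                                                        ICP = 40L,
                                                        LCP = 20L),
                              promoter_length = 2000L,
                              n_planted_dmp = 15L,
                              delta_mu = 0.3,
                              n_planted_de = 15L,
                              planted_fc = 4,
                              n_anticorrelated = 10L,
                              coverage_mean = 30,
                              noise_sd = 0.05,
                              mrna_fraction = 0.8,
                              island_fraction = 0.3,
                              low_coverage_fraction = 0.02,
                              seed = 1L) {
  np <- n_promoters_per_class
  if (is.null(names(np)) || !all(c("HCP", "ICP", "LCP") %in% names(np)))
    stop("n_promoters_per_class must be named HCP/ICP/LCP", call. = FALSE)
  np <- np[c("HCP", "ICP", "LCP")]
  if (any(np < 0) || sum(np) == 0L)
    stop("at least one promoter must be requested", call. = FALSE)
  if (promoter_length < 500L)
    stop("promoter_length must be >= 500 (window undefined below)",
         call. = FALSE)
  if (n_pairs < 1L) stop("need at least one pair", call. = FALSE)
  if (delta_mu <= 0 || delta_mu >= 1)
    stop("delta_mu must lie in (0, 1)", call. = FALSE)
  if (planted_fc <= 0) stop("planted_fc must be > 0", call. = FALSE)
  if (n_planted_de > sum(np))
    stop("n_planted_de exceeds the number of transcripts", call. = FALSE)
  if (n_planted_dmp > sum(np))
    stop("n_planted_dmp exceeds the number of promoters", call. = FALSE)
  if (n_anticorrelated > min(n_planted_dmp, n_planted_de))
    stop("n_anticorrelated exceeds the planted DMP/DE counts",
         call. = FALSE)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_promoters_per_class = as.integer(np),
                 promoter_length = as.integer(promoter_length),
                 n_planted_dmp = as.integer(n_planted_dmp),
                 delta_mu = delta_mu,
                 n_planted_de = as.integer(n_planted_de),
                 planted_fc = planted_fc,
                 n_anticorrelated = as.integer(n_anticorrelated),
                 coverage_mean = coverage_mean,
                 noise_sd = noise_sd,
                 mrna_fraction = mrna_fraction,
                 island_fraction = island_fraction,
                 low_coverage_fraction = low_coverage_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_pairs, "tumor/normal pairs;",
      paste(c("HCP", "ICP", "LCP"), x$n_promoters_per_class,
            collapse = ", "),
      "promoters\n")
  cat("planted: ", x$n_planted_dmp, " DMP (delta ", x$delta_mu, "), ",
      x$n_planted_de, " DE (FC ", x$planted_fc, "), ",
      x$n_anticorrelated, " anti-correlated; seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# ---- sequence building blocks -------------------------------------------

.DNA <- c("A", "C", "G", "T")

# sample() without the 1:x surprise on length-1 vectors
.sample_from <- function(x, n) x[sample.int(length(x), n)]

.rand_seq <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(.DNA, n, replace = TRUE, prob = p)
}

# Replace the G of a CpG dinucleotide with A with probability 1 - keep.
.deplete_cpg <- function(ch, keep) {
  repeat {
    idx <- which(ch[-length(ch)] == "C" & ch[-1L] == "G")
    if (!length(idx)) break
    drop <- idx[stats::runif(length(idx)) > keep]
    if (!length(drop)) break
    ch[drop + 1L] <- "A"
    # replacing G with A can only destroy CpGs, never create them
    break
  }
  ch
}

# One promoter sequence of the requested CpG-density class.
.class_seq <- function(class, len) {
  if (class == "HCP") {
    # CpG-dense core so that at least one 500-bp window exceeds both the
    # CpG-ratio (0.75) and GC (0.55) thresholds
    core_len <- 600L
    n_units <- core_len %/% 2L
    units <- ifelse(stats::runif(n_units) < 0.35, "CG", NA)
    fill <- which(is.na(units))
    units[fill] <- vapply(fill, function(i)
      paste(.rand_seq(2L, 0.55), collapse = ""), "")
    core <- .seq_chars(paste(units, collapse = ""))
    flank <- len - length(core)
    left <- flank %/% 2L
    ch <- c(.deplete_cpg(.rand_seq(left, 0.45), 0.5),
            core,
            .deplete_cpg(.rand_seq(flank - left, 0.45), 0.5))
  } else if (class == "ICP") {
    ch <- .deplete_cpg(.rand_seq(len, 0.50), 0.55)
  } else {
    ch <- .deplete_cpg(.rand_seq(len, 0.40), 0.10)
  }
  ch
}

# CpG (C position) offsets within a block, 1-based.
.cpg_offsets <- function(ch) {
  which(ch[-length(ch)] == "C" & ch[-1L] == "G")
}

.write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# ---- genome + transcript models + islands -------------------------------

#' Generate the synthetic genome, transcript models and CpG islands
#'
#' Lays promoters out along `chr1` (one block per transcript, alternating
#' strands), with per-class sequence composition tuned so that
#' [classify_promoter()] recovers the intended class, plus small `chrX`
#' and `chrY` decoy contigs to exercise the sex-chromosome filter. Emits
#' `genome.fa`, `transcripts.gtf` (known models and a set of novel-lincRNA
#' candidate models with assembler class codes) and `cpg_islands.bed`,
#' and returns the ground-truth manifest used by the later stages.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return the ground-truth manifest (list); see [simulate_ptc_study()].
#' @export
simulate_genome <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(config$seed + 101L, .simulate_genome_impl(config, out_dir))
}

.simulate_genome_impl <- function(config, out_dir) {
  np <- config$n_promoters_per_class
  classes <- rep(c("HCP", "ICP", "LCP"), np)
  N <- length(classes)
  plen <- config$promoter_length
  tail_len <- 2400L
  unit <- plen + tail_len
  pad <- 200L
  # interleave classes so genomic position carries no class information
  classes <- sample(classes)
  ids <- sprintf("TX%04d", seq_len(N))
  genes <- sprintf("G%04d", seq_len(N))
  strands <- rep_len(c("+", "-"), N)

  # feature classes: exactly round(mrna_fraction * N) mRNA promoters
  n_mrna <- round(config$mrna_fraction * N)
  feature <- rep("lncRNA", N)
  feature[.sample_from(seq_len(N), n_mrna)] <- "mRNA"

  # planted DMPs, split across feature classes proportionally
  n_dmp_m <- round(config$n_planted_dmp * n_mrna / N)
  n_dmp_l <- config$n_planted_dmp - n_dmp_m
  dmp_idx <- c(.sample_from(which(feature == "mRNA"), n_dmp_m),
               .sample_from(which(feature == "lncRNA"), n_dmp_l))
  # direction feasible wrt the class baseline and the shift size
  base_by_class <- c(HCP = 0.1, ICP = 0.4, LCP = 0.7)
  base <- unname(base_by_class[classes])
  dmp_dir <- vapply(dmp_idx, function(i) {
    ok <- c(hyper = base[i] + config$delta_mu <= 0.95,
            hypo = base[i] - config$delta_mu >= 0.05)
    if (!any(ok)) stop("delta_mu infeasible for every baseline")
    sample(names(ok)[ok], 1L)
  }, "")

  # anti-correlated candidates: a subset of the planted DMPs, with the
  # opposite expression direction; remaining DE slots go to non-DMP
  # transcripts
  anti_idx <- .sample_from(dmp_idx, config$n_anticorrelated)
  anti_dir <- dmp_dir[match(anti_idx, dmp_idx)]
  n_de_only <- config$n_planted_de - config$n_anticorrelated
  de_only_idx <- .sample_from(setdiff(seq_len(N), dmp_idx), n_de_only)
  de_idx <- c(anti_idx, de_only_idx)
  de_dir <- c(ifelse(anti_dir == "hyper", "down", "up"),
              sample(c("up", "down"), n_de_only, replace = TRUE))

  # promoter sequences; planted promoters are regenerated until they
  # carry enough CpG sites to measure methylation reliably
  seqs <- vector("list", N)
  for (i in seq_len(N)) {
    ch <- .class_seq(classes[i], plen)
    if (i %in% dmp_idx) {
      tries <- 0L
      while (length(.cpg_offsets(ch)) < 5L && tries < 20L) {
        ch <- .class_seq(classes[i], plen)
        tries <- tries + 1L
      }
    }
    seqs[[i]] <- ch
  }

  # assemble chr1: pad | block_1 | block_2 | ...
  block_start <- pad + (seq_len(N) - 1L) * unit  # 0-based
  tails <- lapply(seq_len(N), function(i)
    .deplete_cpg(.rand_seq(tail_len, 0.45), 0.5))
  chr1 <- c(.rand_seq(pad, 0.45),
            unlist(lapply(seq_len(N), function(i)
              c(seqs[[i]], tails[[i]]))))
  # TSS (1-based): promoter block is [-1500, +500) around the TSS
  tss1 <- ifelse(strands == "+",
                 block_start + (plen - 500L) + 1L,
                 block_start + 500L)

  # exon models: two exons of 150 bp inside the downstream promoter half
  mk_exons <- function(i) {
    t0 <- tss1[i] - 1L
    if (strands[i] == "+")
      list(c(t0, t0 + 150L), c(t0 + 300L, t0 + 450L))   # 0-based half-open
    else
      list(c(t0 - 449L, t0 - 299L), c(t0 - 149L, t0 + 1L))
  }

  # novel-lincRNA candidate models in the tails of plus-strand mRNA units:
  # one clean pass plus one failure per cascade rule
  plus_mrna <- which(strands == "+" & feature == "mRNA")
  kinds <- c("pass", "pass", "short", "monoexon", "near_gene",
             "not_x", "high_cpc", "high_cpat")
  kinds <- kinds[seq_len(min(length(kinds), length(plus_mrna)))]
  cand_units <- plus_mrna[seq_along(kinds)]
  cand <- lapply(seq_along(kinds), function(k) {
    s <- block_start[cand_units[k]]
    kind <- kinds[k]
    off <- if (kind == "near_gene") s + plen + 400L else s + plen + 1000L
    # clean candidates sit >= 1000 bp from the flanking coding genes
    # (own gene ends at plen - 50; the next unit's minus-strand gene
    # begins 50 bp into the next block)
    exons <- if (kind == "monoexon") list(c(off, off + 300L))
    else if (kind == "short") list(c(off, off + 90L), c(off + 140L,
                                                        off + 230L))
    else list(c(off, off + 150L), c(off + 250L, off + 400L))
    list(id = sprintf("NOVEL%02d", k), kind = kind, exons = exons,
         class_code = if (kind == "not_x") "=" else "x")
  })

  # CpG islands: every anti-correlated promoter gets one; a fraction of
  # the others do as well
  island <- logical(N)
  island[anti_idx] <- TRUE
  others <- setdiff(seq_len(N), anti_idx)
  island[.sample_from(others, round(config$island_fraction * length(others)))] <-
    TRUE
  isl <- data.frame(
    chrom = "chr1",
    start = ifelse(strands == "+", tss1 - 1L - 200L, tss1 - 1L - 200L),
    end = ifelse(strands == "+", tss1 - 1L + 200L, tss1 - 1L + 200L))
  isl <- isl[island, , drop = FALSE]

  # decoy sex contigs
  chrX <- .rand_seq(2000L, 0.5)
  chrY <- .rand_seq(2000L, 0.5)

  # ---- write files ----
  fa <- file.path(out_dir, "genome.fa")
  .write_fasta(stats::setNames(
    lapply(list(chr1, chrX, chrY), paste, collapse = ""),
    c("chr1", "chrX", "chrY")), fa)

  gtf <- file.path(out_dir, "transcripts.gtf")
  lines <- character()
  for (i in seq_len(N)) {
    bt <- if (feature[i] == "mRNA") "protein_coding" else "lincRNA"
    for (e in mk_exons(i)) {
      lines <- c(lines, sprintf(
        "chr1\tmethcore_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; transcript_biotype \"%s\"; class_code \"=\";",
        e[1L] + 1L, e[2L], strands[i], genes[i], ids[i], bt))
    }
  }
  for (cc in cand) {
    for (e in cc$exons) {
      lines <- c(lines, sprintf(
        "chr1\tmethcore_sim\texon\t%d\t%d\t.\t+\t.\tgene_id \"%s\"; transcript_id \"%s\"; transcript_biotype \"lincRNA\"; class_code \"%s\";",
        e[1L] + 1L, e[2L], paste0("G", cc$id), cc$id, cc$class_code))
    }
  }
  writeLines(lines, gtf)

  bed <- file.path(out_dir, "cpg_islands.bed")
  writeLines(sprintf("%s\t%d\t%d\tCpG_island_%d", isl$chrom, isl$start,
                     isl$end, seq_len(nrow(isl))), bed)

  samples <- c(paste0("ca_", seq_len(config$n_pairs)),
               paste0("adj_", seq_len(config$n_pairs)))

  # linked gene set for the co-function network: the hub (first
  # anti-correlated gene) plus up to four partners; their expression later
  # shares a per-sample latent factor so that co-expression is genuine,
  # not just tumor/normal group structure
  anti_genes <- genes[anti_idx]
  hub <- anti_genes[1L]
  partners <- if (length(anti_genes) >= 2L)
    anti_genes[seq(2L, min(5L, length(anti_genes)))] else character()

  list(config = config,
       samples = samples,
       hub_gene = hub,
       linked_gene_ids = c(hub, partners),
       promoters = data.frame(
         transcript_id = ids, gene_id = genes, chrom = "chr1",
         start = block_start, end = block_start + plen,
         strand = strands, tss = tss1,
         cpg_class = classes, feature_class = feature,
         base_meth = unname(base), has_cpg_island = island,
         stringsAsFactors = FALSE),
       sequences = stats::setNames(
         vapply(seqs, paste, "", collapse = ""), ids),
       dmp_ids = stats::setNames(dmp_dir, ids[dmp_idx]),
       de_ids = stats::setNames(de_dir, ids[de_idx]),
       anticorrelated_ids = ids[anti_idx],
       candidate_models = cand,
       novel_lincrna_ids = vapply(
         cand[vapply(cand, function(x) x$kind == "pass", TRUE)],
         function(x) x$id, ""),
       files = list(fasta = fa, gtf = gtf, bed = bed))
}

# ---- methylome ----------------------------------------------------------

#' Generate per-sample CpG methylation call files
#'
#' Emits one Bismark-coverage-dialect file per sample
#' (`meth_<sample>.cov`). CpG sites sit at the CpG dinucleotides of each
#' promoter sequence; planted DMP promoters carry a tumor-normal group
#' mean difference of `delta_mu`; a small fraction of sites is emitted
#' below 5x coverage in every sample and decoy sites are placed on
#' chrX/chrY, both to exercise the downstream filters. With
#' `noise_sd = 0` levels and coverage are deterministic, so the planted
#' difference is recovered exactly.
#'
#' @param config a `sim_config`.
#' @param manifest manifest from [simulate_genome()].
#' @param out_dir output directory.
#' @return the manifest, augmented with `meth_files` and `promoter_meth`
#'   (the realized promoter x sample mean methylation, coverage-filtered).
#' @export
simulate_methylome <- function(config, manifest, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(manifest$promoters) || is.null(manifest$sequences) ||
      !file.exists(manifest$files$fasta))
    stop("manifest does not match the generated genome", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(config$seed + 202L,
             .simulate_methylome_impl(config, manifest, out_dir))
}

.simulate_methylome_impl <- function(config, manifest, out_dir) {
  pm <- manifest$promoters
  samples <- manifest$samples
  tumor <- grepl("^ca_", samples)
  noiseless <- config$noise_sd == 0
  max_sites <- 60L

  site_rows <- vector("list", nrow(pm))
  level_acc <- matrix(NA_real_, nrow(pm), length(samples),
                      dimnames = list(pm$transcript_id, samples))
  for (i in seq_len(nrow(pm))) {
    ch <- .seq_chars(manifest$sequences[[pm$transcript_id[i]]])
    offs <- .cpg_offsets(ch)
    if (!length(offs)) next
    if (length(offs) > max_sites)
      offs <- offs[round(seq(1L, length(offs), length.out = max_sites))]
    pos <- pm$start[i] + offs  # 1-based genomic position of the C
    ns <- length(pos)
    low <- stats::runif(ns) < config$low_coverage_fraction
    shift <- 0
    id <- pm$transcript_id[i]
    if (id %in% names(manifest$dmp_ids))
      shift <- if (manifest$dmp_ids[[id]] == "hyper") config$delta_mu
               else -config$delta_mu
    lv <- matrix(NA_real_, ns, length(samples))
    cv <- matrix(NA_integer_, ns, length(samples))
    for (s in seq_along(samples)) {
      m_group <- pm$base_meth[i] + if (tumor[s]) shift else 0
      m_s <- if (noiseless) m_group else
        min(0.98, max(0.02, m_group + stats::rnorm(1, 0,
                                                   config$noise_sd / 2)))
      lvl <- if (noiseless) rep(m_s, ns) else {
        nu <- m_s * (1 - m_s) / config$noise_sd^2 - 1
        if (nu <= 0) nu <- 1
        stats::rbeta(ns, m_s * nu, (1 - m_s) * nu)
      }
      cov <- if (noiseless) rep(as.integer(round(config$coverage_mean)), ns)
             else pmax(1L, stats::rpois(ns, config$coverage_mean))
      cov[low] <- sample(1:4, sum(low), replace = TRUE)
      mcount <- as.integer(round(lvl * cov))
      lv[, s] <- mcount / cov
      cv[, s] <- cov
    }
    ok <- cv >= 5L
    mean_ok <- vapply(seq_along(samples), function(s) {
      v <- lv[ok[, s], s]
      if (length(v)) mean(v) else NA_real_
    }, 0)
    level_acc[i, ] <- mean_ok
    site_rows[[i]] <- list(pos = pos, level = lv, cov = cv)
  }

  # decoy sex-chromosome sites
  decoy <- lapply(c("chrX", "chrY"), function(chr) {
    pos <- sort(sample(50:1950, 20L))
    list(chrom = chr, pos = pos)
  })

  files <- character(length(samples))
  for (s in seq_along(samples)) {
    rows <- lapply(seq_len(nrow(pm)), function(i) {
      sr <- site_rows[[i]]
      if (is.null(sr)) return(NULL)
      m <- as.integer(round(sr$level[, s] * sr$cov[, s]))
      data.frame(chrom = "chr1", pos = sr$pos,
                 m = m, u = sr$cov[, s] - m)
    })
    d <- do.call(rbind, rows)
    d <- d[order(d$pos), , drop = FALSE]
    for (dc in decoy) {
      cov <- as.integer(round(config$coverage_mean))
      m <- as.integer(round(0.5 * cov))
      d <- rbind(d, data.frame(chrom = dc$chrom, pos = dc$pos,
                               m = m, u = cov - m))
    }
    path <- file.path(out_dir, paste0("meth_", samples[s], ".cov"))
    writeLines(sprintf("%s\t%d\t%d\t%.6g\t%d\t%d", d$chrom, d$pos, d$pos,
                       100 * d$m / (d$m + d$u), d$m, d$u), path)
    files[s] <- path
  }
  manifest$meth_files <- stats::setNames(files, samples)
  manifest$promoter_meth <- level_acc
  manifest
}

# ---- expression + coding potential --------------------------------------

#' Generate FPKM and coding-potential tables
#'
#' Writes `expression.tsv` (transcripts x samples, columns `ca_1..ca_n`,
#' `adj_1..adj_n`) and `coding_potential.tsv` (CPC and CPAT scores
#' straddling the 0 and 0.364 thresholds). FPKM is log-normal with a
#' shared per-pair offset; planted DE transcripts carry the configured
#' fold change in every pair; anti-correlated transcripts have their
#' expression coupled to the realized per-sample promoter methylation so
#' that methylation and expression are negatively correlated across
#' samples; a few background transcripts are emitted below the
#' 0.01-FPKM floor to exercise the low-expression filter.
#'
#' @param config a `sim_config`.
#' @param manifest manifest from [simulate_methylome()].
#' @param out_dir output directory.
#' @return the manifest, augmented with `expr_file`, `scores_file`,
#'   `expression` and `low_expressed_ids`.
#' @export
simulate_expression <- function(config, manifest, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(manifest$promoter_meth))
    stop("manifest lacks the methylome stage; run simulate_methylome first",
         call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(config$seed + 303L,
             .simulate_expression_impl(config, manifest, out_dir))
}

.simulate_expression_impl <- function(config, manifest, out_dir) {
  pm <- manifest$promoters
  samples <- manifest$samples
  tumor <- grepl("^ca_", samples)
  pair_of <- as.integer(sub("^(ca|adj)_", "", samples))
  N <- nrow(pm)
  noiseless <- config$noise_sd == 0

  base <- exp(stats::rnorm(N, 1.5, 1))
  pair_off <- exp(stats::rnorm(config$n_pairs, 0, 0.05))
  # per-sample latent co-regulation factor shared by the linked gene set
  latent <- stats::rnorm(length(samples), 0, 3 * config$noise_sd)
  linked <- pm$gene_id %in% manifest$linked_gene_ids
  # linked genes respond to the factor with a sign matching their planted
  # expression direction, so every hub-partner pair is strongly
  # co-expressed (positively or negatively) beyond the group structure
  hub_tx <- pm$transcript_id[pm$gene_id == manifest$hub_gene][1L]
  hub_dir <- manifest$de_ids[[hub_tx]]
  link_sign <- ifelse(!is.na(match(pm$transcript_id,
                                   names(manifest$de_ids))) &
                        manifest$de_ids[pm$transcript_id] == hub_dir,
                      1, -1)

  low_n <- max(3L, round(0.02 * N))
  eligible <- setdiff(pm$transcript_id,
                      c(names(manifest$dmp_ids), names(manifest$de_ids)))
  low_ids <- .sample_from(eligible, min(low_n, length(eligible)))
  base[match(low_ids, pm$transcript_id)] <- 0.002

  fpkm <- matrix(0, N, length(samples),
                 dimnames = list(pm$transcript_id, samples))
  for (i in seq_len(N)) {
    id <- pm$transcript_id[i]
    de_dir <- if (id %in% names(manifest$de_ids))
      manifest$de_ids[[id]] else NA
    for (s in seq_along(samples)) {
      mult <- 1
      if (!is.na(de_dir) && tumor[s]) {
        mult <- if (de_dir == "up") config$planted_fc
                else 1 / config$planted_fc
      }
      noise <- if (noiseless) 1 else exp(stats::rnorm(1, 0,
                                                      config$noise_sd))
      co <- if (linked[i]) exp(link_sign[i] * latent[s]) else 1
      fpkm[i, s] <- base[i] * pair_off[pair_of[s]] * mult * co * noise
    }
  }

  expr_file <- file.path(out_dir, "expression.tsv")
  out <- cbind(data.frame(transcript_id = rownames(fpkm)),
               as.data.frame(fpkm))
  utils::write.table(out, expr_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # coding-potential scores for every transcript plus the novel
  # candidates; values straddle the CPC (0) and CPAT (0.364) thresholds
  cand <- manifest$candidate_models
  score_rows <- list(data.frame(
    transcript_id = pm$transcript_id,
    cpc = ifelse(pm$feature_class == "mRNA",
                 stats::runif(N, 1, 3), stats::runif(N, -2, -0.5)),
    cpat = ifelse(pm$feature_class == "mRNA",
                  stats::runif(N, 0.5, 0.95),
                  stats::runif(N, 0.05, 0.3))))
  for (cc in cand) {
    cpc <- if (cc$kind == "high_cpc") stats::runif(1, 0.5, 2)
           else stats::runif(1, -1.5, -0.2)
    cpat <- if (cc$kind == "high_cpat") stats::runif(1, 0.4, 0.9)
            else stats::runif(1, 0.05, 0.3)
    score_rows[[length(score_rows) + 1L]] <-
      data.frame(transcript_id = cc$id, cpc = cpc, cpat = cpat)
  }
  scores <- do.call(rbind, score_rows)
  scores$cpc <- round(scores$cpc, 4)
  scores$cpat <- round(scores$cpat, 4)
  scores_file <- file.path(out_dir, "coding_potential.tsv")
  utils::write.table(scores, scores_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest$expression <- fpkm
  manifest$low_expressed_ids <- low_ids
  manifest$expr_file <- expr_file
  manifest$scores_file <- scores_file
  manifest
}

# ---- GO + PPI -----------------------------------------------------------

#' Generate the toy GO ontology, annotations and PPI edge list
#'
#' Builds, per GO branch (BP, CC, MF), a DAG of small disjoint
#' components. A designated hub gene (the first anti-correlated gene)
#' shares a leaf term with each of its linked partners in every branch,
#' so exactly the hub-partner pairs clear the 0.2 average-similarity
#' criterion; all other genes receive private terms. The PPI list
#' contains the hub as a seed with four direct neighbors, one
#' neighbor-neighbor link, and background edges.
#'
#' @param config a `sim_config`.
#' @param manifest manifest from earlier stages (needs `promoters` and
#'   `anticorrelated_ids`).
#' @param out_dir output directory.
#' @return the manifest, augmented with `go_file`, `annotation_file`,
#'   `ppi_file`, `hub_gene`, `linked_gene_pairs` and `ppi_module`.
#' @export
simulate_go_ppi <- function(config, manifest, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .with_seed(config$seed + 404L,
             .simulate_go_ppi_impl(config, manifest, out_dir))
}

.simulate_go_ppi_impl <- function(config, manifest, out_dir) {
  pm <- manifest$promoters
  gene_of <- stats::setNames(pm$gene_id, pm$transcript_id)
  if (length(manifest$linked_gene_ids) < 2L)
    stop("need at least two linked genes for planted pairs",
         call. = FALSE)
  hub <- manifest$hub_gene
  partners <- setdiff(manifest$linked_gene_ids, hub)
  ns_long <- c(BP = "biological_process", CC = "cellular_component",
               MF = "molecular_function")

  terms <- list(); edges <- list(); annot <- list()
  add_term <- function(id, ns) terms[[length(terms) + 1L]] <<-
    data.frame(id = id, namespace = ns)
  add_edge <- function(ch, pa, rel) edges[[length(edges) + 1L]] <<-
    data.frame(child = ch, parent = pa, relation = rel)
  add_annot <- function(g, t, b) annot[[length(annot) + 1L]] <<-
    data.frame(gene = g, term = t, branch = b)

  for (b in names(ns_long)) {
    # shared components: leaf_k is_a mid_k for each hub-partner pair
    for (k in seq_along(partners)) {
      leaf <- sprintf("GO:%s:L%02d", b, k)
      mid <- sprintf("GO:%s:M%02d", b, k)
      add_term(leaf, ns_long[[b]]); add_term(mid, ns_long[[b]])
      add_edge(leaf, mid, if (k %% 2L) "is_a" else "part_of")
      add_annot(hub, leaf, b)
      add_annot(partners[k], leaf, b)
    }
    # private components for every other gene
    others <- setdiff(pm$gene_id, c(hub, partners))
    for (j in seq_along(others)) {
      leaf <- sprintf("GO:%s:P%04d", b, j)
      root <- sprintf("GO:%s:PR%04d", b, j)
      add_term(leaf, ns_long[[b]]); add_term(root, ns_long[[b]])
      add_edge(leaf, root, "is_a")
      add_annot(others[j], leaf, b)
    }
  }

  terms <- do.call(rbind, terms)
  edges <- do.call(rbind, edges)
  annot <- do.call(rbind, annot)

  go_file <- file.path(out_dir, "ontology.obo")
  lines <- c("format-version: 1.2", "ontology: methcore-sim", "")
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    pa <- edges[edges$child == id, , drop = FALSE]
    lines <- c(lines, "[Term]", paste0("id: ", id),
               paste0("namespace: ", terms$namespace[i]),
               if (nrow(pa)) unlist(lapply(seq_len(nrow(pa)), function(k)
                 if (pa$relation[k] == "is_a")
                   paste0("is_a: ", pa$parent[k])
                 else paste0("relationship: part_of ", pa$parent[k]))),
               "")
  }
  writeLines(lines, go_file)

  annotation_file <- file.path(out_dir, "go_annotations.tsv")
  utils::write.table(annot, annotation_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # PPI: seed star around the hub + one neighbor-neighbor link +
  # background edges among other genes
  nbrs <- c(partners[seq_len(min(3L, length(partners)))], "EXT1")
  ppi <- data.frame(gene_a = hub, gene_b = nbrs)
  ppi <- rbind(ppi, data.frame(gene_a = nbrs[1L], gene_b = nbrs[2L]))
  others <- setdiff(pm$gene_id, c(hub, partners))
  bg <- others[seq_len(min(6L, length(others)))]
  if (length(bg) >= 2L)
    ppi <- rbind(ppi, data.frame(gene_a = bg[-length(bg)],
                                 gene_b = bg[-1L]))
  ppi_file <- file.path(out_dir, "ppi.tsv")
  utils::write.table(ppi, ppi_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest$hub_gene <- hub
  manifest$linked_gene_pairs <- data.frame(
    gene_a = pmin(hub, partners), gene_b = pmax(hub, partners),
    stringsAsFactors = FALSE)
  manifest$ppi_module <- list(
    nodes = sort(c(hub, nbrs)),
    edges = rbind(data.frame(gene_a = hub, gene_b = nbrs),
                  data.frame(gene_a = nbrs[1L], gene_b = nbrs[2L])))
  manifest$go_file <- go_file
  manifest$annotation_file <- annotation_file
  manifest$ppi_file <- ppi_file
  manifest
}

#' Generate the complete synthetic study
#'
#' Runs all four generator stages and writes every pipeline input file to
#' `out_dir`. With a fixed configuration (including the seed) the emitted
#' files are byte-identical across runs.
#'
#' @param config a `sim_config` (default configuration when omitted).
#' @param out_dir output directory.
#' @return the ground-truth manifest: promoter table with planted classes
#'   and baselines, planted DMP/DE/anti-correlated id sets with
#'   directions, linked gene pairs, the PPI seed module, expected novel
#'   lincRNA ids, realized promoter methylation, and all file paths.
#' @export
simulate_ptc_study <- function(config = simulation_config(), out_dir) {
  manifest <- simulate_genome(config, out_dir)
  manifest <- simulate_methylome(config, manifest, out_dir)
  manifest <- simulate_expression(config, manifest, out_dir)
  simulate_go_ppi(config, manifest, out_dir)
}
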