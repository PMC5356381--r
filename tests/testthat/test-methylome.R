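make_cov_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".cov",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("Bismark-coverage parsing recomputes levels from counts", {
  p <- make_cov_file("chr1\t100\t100\t75.0\t3\t1")
  d <- read_cpg_calls(p)
  expect_equal(d$level, 0.75)
  expect_equal(d$coverage, 4L)
  expect_equal(d$pos, 100L)
  # percent inconsistent with counts
  p2 <- make_cov_file("chr1\t100\t100\t90.0\t1\t1")
  expect_error(read_cpg_calls(p2), "inconsistent")
  # zero-coverage site skipped with a warning
  p3 <- make_cov_file(c("chr1\t100\t100\t50.0\t1\t1",
                        "chr1\t200\t200\t0\t0\t0"))
  expect_warning(d3 <- read_cpg_calls(p3), "zero coverage")
  expect_equal(nrow(d3), 1L)
  # malformed line is reported
  p4 <- make_cov_file("chr1\tabc\t100\t50\t1\t1")
  expect_error(read_cpg_calls(p4))
})

test_that("CpG calls survive a write/read round trip", {
  set.seed(501)
  cov <- sample(5:50, 30, replace = TRUE)
  m <- rbinom(30, cov, 0.4)
  calls <- data.frame(chrom = "chr1", pos = sort(sample(1:10000, 30)),
                      level = m / cov, coverage = cov)
  path <- withr::local_tempfile(fileext = ".cov")
  write_cpg_calls(calls, path)
  back <- read_cpg_calls(path)
  expect_equal(back$level, calls$level)
  expect_equal(back$coverage, calls$coverage)
  expect_equal(back$pos, calls$pos)
})

make_samples <- function(tab) {
  # tab: data.frame chrom, pos, then one coverage column per sample;
  # level fixed at 0.5
  lapply(grep("^cov", names(tab), value = TRUE), function(cn) {
    data.frame(chrom = tab$chrom, pos = tab$pos,
               level = 0.5, coverage = tab[[cn]])
  })
}

test_that("shared-site filter applies coverage and sex-chromosome rules", {
  tab <- data.frame(chrom = c("chr1", "chr1", "chrX", "chr1"),
                    pos = c(100, 200, 300, 400),
                    cov1 = c(4, 10, 30, 5),
                    cov2 = c(4, 10, 30, 4))
  s <- make_samples(tab)
  m <- filter_shared_sites(s, min_coverage = 5)
  # site 100: below 5 in every sample -> dropped; chrX dropped;
  # site 400: >=5 in one sample -> retained
  expect_equal(m$sites$pos, c(200L, 400L))
  expect_false(any(m$sites$chrom %in% c("chrX", "chrY", "X", "Y")))
  # a site absent from one sample is not shared
  s2 <- list(data.frame(chrom = "chr1", pos = c(1, 2), level = 0.5,
                        coverage = 10),
             data.frame(chrom = "chr1", pos = 1, level = 0.5,
                        coverage = 10))
  m2 <- filter_shared_sites(s2)
  expect_equal(m2$sites$pos, 1L)
  # empty intersection errors
  s3 <- list(data.frame(chrom = "chr1", pos = 1, level = 0.5,
                        coverage = 10),
             data.frame(chrom = "chr1", pos = 2, level = 0.5,
                        coverage = 10))
  expect_error(filter_shared_sites(s3), "shared")
})

toy_matrix <- function(pos, levels) {
  # levels: sites x samples
  structure(list(sites = data.frame(chrom = "chr1", pos = pos),
                 level = levels,
                 coverage = matrix(10, nrow(levels), ncol(levels))),
            class = "cpg_matrix")
}

test_that("promoter methylation is the unweighted site mean, NA when empty", {
  lv <- matrix(c(0.2, 0.4, 0.9), ncol = 1,
               dimnames = list(NULL, "s1"))
  m <- toy_matrix(c(150, 160, 5000), lv)
  pr <- data.frame(transcript_id = c("a", "b"), chrom = "chr1",
                   start = c(100, 2000), end = c(200, 2100))
  pm <- promoter_methylation(m, pr)
  expect_equal(pm["a", "s1"], 0.3)
  expect_true(is.na(pm["b", "s1"]))
  # brute-force oracle on random sites
  set.seed(502)
  pos <- sort(sample(1:5000, 50))
  lv <- matrix(runif(100), ncol = 2, dimnames = list(NULL, c("s1", "s2")))
  m2 <- toy_matrix(pos, lv)
  pr2 <- data.frame(transcript_id = "p", chrom = "chr1",
                    start = 1000, end = 3000)
  inside <- pos - 1 >= 1000 & pos - 1 < 3000
  expect_equal(unname(promoter_methylation(m2, pr2)[1, ]),
               unname(colMeans(lv[inside, ])))
})

test_that("tumor-normal difference is antisymmetric under group swap", {
  lv <- rbind(a = c(0.8, 0.8, 0.8, 0.2, 0.2, 0.2),
              b = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  colnames(lv) <- paste0("s", 1:6)
  g <- rep(c("tumor", "normal"), each = 3)
  d <- methylation_difference(lv, g)
  expect_equal(d$delta[d$transcript_id == "a"], 0.6)
  expect_equal(d$delta[d$transcript_id == "b"], 0)
  swapped <- methylation_difference(lv, rev(g))
  expect_equal(swapped$delta, -d$delta)
  # promoters with an absent value are excluded
  lv2 <- rbind(lv, c = c(NA, 0.5, 0.5, 0.5, 0.5, 0.5))
  expect_false("c" %in% methylation_difference(lv2, g)$transcript_id)
  expect_error(methylation_difference(lv, rep("tumor", 6)), "normal")
})

test_that("top-5% DMP rule calls ceil(qN) per feature class, keeping ties", {
  set.seed(503)
  deltas <- data.frame(
    transcript_id = sprintf("t%02d", 1:40),
    mean_tumor = 0.5, mean_normal = 0.5,
    delta = c(0.5, -0.5, runif(38, -0.1, 0.1)))
  fc <- setNames(rep("mRNA", 40), deltas$transcript_id)
  dmp <- call_dmps(deltas, fc)
  expect_equal(sort(dmp$transcript_id), c("t01", "t02"))
  expect_equal(dmp$direction[dmp$transcript_id == "t01"], "hyper")
  expect_equal(dmp$direction[dmp$transcript_id == "t02"], "hypo")
  # all-tied nonzero deltas are all called
  deltas2 <- data.frame(transcript_id = sprintf("u%02d", 1:25),
                        mean_tumor = 0.6, mean_normal = 0.4, delta = 0.2)
  fc2 <- setNames(rep("mRNA", 25), deltas2$transcript_id)
  expect_equal(nrow(call_dmps(deltas2, fc2)), 25L)
  # zero deltas are never called
  deltas3 <- deltas2
  deltas3$delta <- 0
  expect_equal(nrow(call_dmps(deltas3, fc2)), 0L)
  # small classes are rejected
  expect_error(call_dmps(deltas[1:10, ], fc[1:10]), "fewer than 20")
})

test_that("DMP thresholds are set within each feature class separately", {
  set.seed(504)
  # mRNA deltas much larger than lncRNA deltas; per-class ranking must
  # still call lncRNA DMPs
  deltas <- data.frame(
    transcript_id = c(sprintf("m%02d", 1:40), sprintf("l%02d", 1:40)),
    mean_tumor = 0.5, mean_normal = 0.5,
    delta = c(runif(40, 0.3, 0.6), runif(40, 0.01, 0.05)))
  fc <- setNames(rep(c("mRNA", "lncRNA"), each = 40),
                 deltas$transcript_id)
  dmp <- call_dmps(deltas, fc)
  expect_equal(sum(dmp$feature_class == "mRNA"), 2L)
  expect_equal(sum(dmp$feature_class == "lncRNA"), 2L)
})

test_that("methylation states use strict 0.2/0.6 cuts", {
  expect_equal(label_methylation_state(c(0.1, 0.2, 0.5, 0.6, 0.7)),
               c("hypomethylated", "intermediate", "intermediate",
                 "intermediate", "hypermethylated"))
  expect_error(label_methylation_state(1.2), "0, 1")
})

test_that("TSS profile aggregates by signed distance and skips empty bins", {
  # one plus-strand promoter, uniform methylation 0.5
  seqs <- strrep("ACGT", 500)
  pr <- data.frame(transcript_id = "p", chrom = "chr1", start = 0,
                   end = 2000, strand = "+", tss = 1501,
                   sequence = seqs)
  pos <- seq(10, 1990, by = 40)
  lv <- matrix(0.5, length(pos), 2, dimnames = list(NULL, c("s1", "s2")))
  m <- toy_matrix(pos, lv)
  prof <- tss_profile(m, pr, bin_width = 250)
  expect_true(all(abs(prof$methylation - 0.5) < 1e-12))
  expect_equal(prof$bin_start, seq(-1500, 250, by = 250))
  expect_error(tss_profile(m, pr, bin_width = 0), "positive")
  # CpG-dense center: the bin containing the TSS has the highest ratio
  center <- paste0(rand_dna(1500, 0.4), strrep("CG", 100),
                   rand_dna(300, 0.4))
  pr2 <- data.frame(transcript_id = "q", chrom = "chr1", start = 0,
                    end = 2000, strand = "+", tss = 1501,
                    sequence = center)
  prof2 <- tss_profile(m, pr2, bin_width = 200)
  expect_equal(prof2$bin_start[which.max(prof2$cpg_ratio)], 0)
})
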