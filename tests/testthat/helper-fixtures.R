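# Shared fixtures. The default synthetic study and its pipeline run are
# generated once per test session and reused across test files.

.fixtures <- new.env(parent = emptyenv())

sim_study <- function() {
  if (is.null(.fixtures$man)) {
    dir <- file.path(tempdir(), "methcore_default_study")
    .fixtures$man <- simulate_ptc_study(simulation_config(), dir)
    .fixtures$dir <- dir
  }
  list(man = .fixtures$man, dir = .fixtures$dir)
}

pipeline_result <- function() {
  if (is.null(.fixtures$res))
    .fixtures$res <- run_ptc_pipeline(sim_study()$dir)
  .fixtures$res
}

# small balanced study for generator-focused tests
sim_small <- function() {
  if (is.null(.fixtures$small)) {
    dir <- file.path(tempdir(), "methcore_small_study")
    cfg <- simulation_config(
      n_promoters_per_class = c(HCP = 30L, ICP = 30L, LCP = 30L),
      n_planted_dmp = 4L, n_planted_de = 4L, n_anticorrelated = 2L,
      seed = 11L)
    .fixtures$small <- list(man = simulate_ptc_study(cfg, dir),
                            cfg = cfg, dir = dir)
  }
  .fixtures$small
}

# random DNA string
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# independent CpG-ratio oracle: literal dinucleotide scan
cpg_ratio_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n_cg <- 0L
  for (i in seq_len(length(ch) - 1L))
    if (ch[i] == "C" && ch[i + 1L] == "G") n_cg <- n_cg + 1L
  n_c <- sum(ch == "C")
  n_g <- sum(ch == "G")
  if (n_c == 0L || n_g == 0L) return(0)
  n_cg * length(ch) / (n_c * n_g)
}

# independent window classifier: moving sums via stats::filter
classify_oracle <- function(seq, window = 500L) {
  ch <- strsplit(seq, "")[[1]]
  isC <- as.numeric(ch == "C")
  isG <- as.numeric(ch == "G")
  pair <- as.numeric(ch[-length(ch)] == "C" & ch[-1] == "G")
  wsum <- function(x, w) {
    f <- stats::filter(x, rep(1, w), sides = 1)
    as.numeric(f[!is.na(f)])
  }
  nC <- wsum(isC, window)
  nG <- wsum(isG, window)
  # a window starting at i covers pair start positions i..i+window-2
  nCG <- wsum(pair, window - 1L)
  nCG <- nCG[seq_len(length(nC))]
  ratio <- ifelse(nC * nG == 0, 0, nCG * window / (nC * nG))
  gc <- (nC + nG) / window
  if (any(ratio > 0.75 & gc > 0.55)) "HCP"
  else if (!any(ratio > 0.48)) "LCP"
  else "ICP"
}
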