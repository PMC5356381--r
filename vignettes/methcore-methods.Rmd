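---
title: "Methods: integrated promoter methylation and expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated promoter methylation and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`methcore` analyzes matched tumor/normal designs in which each patient
contributes one tumor and one adjacent-normal sample, profiled both by
reduced representation bisulfite sequencing (RRBS, giving per-CpG
methylation calls) and by RNA-seq (giving per-transcript FPKM). This
vignette documents the model behind each stage, the tunable parameters
and their defaults, the design choices made where the procedure was
genuinely open, what the synthetic-data generator does and does not
emulate, and the package's known limitations.

## Promoter definition and CpG-density classes

The promoter of a transcript is the fixed window from 1500 bp upstream
of the transcription start site to 500 bp downstream, strand-aware and
clipped at contig boundaries. Internally all intervals are 0-based
half-open; GTF input (1-based closed) and BED input (native 0-based)
are converted on read, so `extract_promoter(10001, "+", len)` yields
`[8500, 10500)`.

CpG density is measured by the observed/expected CpG ratio
`(#CpG x length) / (#C x #G)` and by GC content. A promoter is
classified by sliding a 500-bp window along its sequence:

* **HCP** — some window has CpG ratio > 0.75 *and* GC content > 0.55;
* **LCP** — no window has CpG ratio > 0.48;
* **ICP** — neither.

Three numerical choices matter here. First, the window step is 1 bp:
the classification is defined over *all* windows, which is the
strictest reading and costs nothing at 2-kb promoters (the
implementation uses cumulative sums, so a promoter is classified in
O(length)). Second, all thresholds are strict inequalities — a window
at exactly ratio 0.75 or GC 0.55 does not qualify. Third, ambiguous
bases (N) are excluded from the C, G and CpG counts but still count
toward window length; this is deterministic and biases the ratio
downward rather than inventing CpGs. A sequence with no C or no G has
ratio 0 by convention rather than 0/0.

The promoter-level `cpg_ratio`/`gc_content` fields are computed over
the whole promoter (used for TSS-distance profiles); the class label
always comes from the window scan.

## Site filters and differential methylation

Per-sample CpG calls arrive in the Bismark-coverage dialect (chrom,
position, position, percent, count methylated, count unmethylated).
The methylation level is always recomputed from the counts — the
percent column is only cross-checked (to 0.5 points) so rounded
percentages never propagate. Sites with zero total coverage are
skipped with a warning rather than treated as level 0.

The shared site set keeps sites that are (i) not on chrX/chrY, (ii)
covered at least 5x in *at least one* sample, and (iii) present in
every sample. Reading the coverage rule as "at least one sample"
followed by an all-sample intersection reproduces the semantics of a
single shared site list across samples; the alternative reading
("5x in every sample") is stricter and can be obtained by
pre-filtering each sample's table, but it is not the default.

Promoter methylation is the unweighted mean of site levels inside the
promoter; a promoter with no covered site is *absent* (NA), never 0,
and absent promoters are excluded from differential ranking rather
than being ranked as unchanged.

The tumor-normal difference is a difference of group means (not a mean
of per-pair differences — the two coincide for balanced complete
designs, and group-mean language matches how such contrasts are usually
reported). Within each feature class (mRNA promoters and lncRNA
promoters separately, since the two populations have different
methylation distributions), promoters whose |difference| reaches the
`ceiling(0.05 N)`-th largest value are called differentially
methylated. Ties at the threshold are all kept — with an empirical
quantile this is the only convention under which the called count can
slightly exceed 5% of N, which is also what published counts of this
design show. A difference of exactly 0 is never called regardless of
ties. Classes with fewer than 20 promoters raise an error because a
5% empirical quantile on fewer than 20 observations is a single order
statistic with huge variance.

Methylation states for reporting use strict cuts: below 0.2
hypomethylated, above 0.6 hypermethylated, otherwise intermediate.

## Differential expression

Transcripts with FPKM < 0.01 in strictly more than 50% of samples are
removed first. Fold changes are computed per matched pair as
`(tumor + c) / (normal + c)` with pseudocount `c = 0.01` — the same
scale as the expression floor, so a zero/zero pair yields FC 1 rather
than NaN, while any expressed value dominates the pseudocount.

A transcript is called up-regulated when FC > 1.5 in *every* pair and
down-regulated when FC < 2/3 in every pair; in both cases a p-value
below 0.05 is also required. The p-value is a pluggable function of
the per-pair log2 fold changes. The package's default is a one-sample
t-type test of the log2 fold changes against 0: the defining criterion
of this design is the fold-change-in-every-pair rule, and the p-value
is a secondary consistency check, so the package deliberately does not
couple the rule to any particular count-model machinery — any test
(including a negative-binomial one computed externally) can be passed
through `test=`. A degenerate input (constant log2 fold changes, where
a t statistic is undefined) reports p = 1, i.e. the test abstains
rather than rubber-stamping; with three pairs this also means a
perfectly noise-free simulated fold change is *not* called, which is
visible in the noiseless generator tests.

## Novel lincRNA cascade

Candidates pass all seven of: length > 200 nt (summed exonic length),
more than one exon, assembler class code `x` (novel, intergenic
relative to known annotation), no exonic overlap (>= 1 bp, either
strand) with any known transcript, distance >= 1000 bp from the
nearest protein-coding gene span, CPC < 0, and CPAT < 0.364. "Within
1000 bp" excludes strictly-closer candidates, so a gap of exactly
1000 bp survives; the coding-potential cutoffs are strict, so a CPAT
score of exactly 0.364 is rejected. The filters are pure predicates,
so their order cannot change the result. CPC/CPAT scores are consumed
from a table — the scoring algorithms themselves are upstream tools,
not part of this package.

## Integration gates

Candidate methylation-regulated genes must pass three gates:

1. **Sign consistency** — present in both the DE and DMP sets with
   (hyper, down) or (hypo, up) direction pairs; discordant
   combinations are discarded, not just down-weighted.
2. **CpG island** — the promoter overlaps (>= 1 bp, half-open
   semantics) at least one annotated CpG island.
3. **Negative correlation** — Pearson correlation between per-sample
   promoter methylation and expression is negative with two-sided
   p < 0.05 (the t transform on n-2 degrees of freedom, exactly as
   `cor.test`). All samples, tumor and normal pooled, enter the
   correlation: with three pairs, six points is the minimum that makes
   the screen meaningful, and pooling uses the full dynamic range that
   the group contrast creates. The test is two-sided with a post-hoc
   sign requirement rather than one-sided, matching the usual
   "negatively correlated, p < 0.05" reporting convention.

When several transcripts of one gene survive, the transcript with the
largest |methylation difference| represents the gene, giving one row
per gene.

## Co-function network

For every unordered pair of candidate genes an edge requires all three
of:

* **Co-expression** — Pearson correlation with a permutation p-value
  below 0.05 from 1000 seeded shuffles of one vector. The estimator is
  add-one: `p = (1 + #{|r_perm| >= |r_obs|}) / (n_perm + 1)`, which is
  never 0 and is bounded below by 1/(n_perm+1). With six samples the
  permutation group is small (720 orderings), so the achievable p
  granularity is coarse; this is a property of the design, not of the
  implementation, and it is why the generator plants genuine
  co-regulation rather than relying on the tumor/normal contrast alone
  (see below).
* **Functional similarity** — Wang's graph-based GO term similarity
  with edge weights 0.8 (is_a) and 0.6 (part_of), combined to gene
  level by the best-match average (mean of row and column maxima of
  the term-pair similarity matrix), per branch; the BP/CC/MF branch
  scores are averaged and must exceed 0.2 (strict). These constants
  are the conventional defaults of the graph-based measure. A branch
  in which either gene has no annotation scores 0 *and still enters
  the three-branch average* — a strict reading of "average over BP,
  CC and MF" that penalizes poorly annotated genes rather than
  silently renormalizing.
* **Co-methylation** — Pearson correlation of promoter methylation
  with analytic (t-transform) p < 0.05. Permutations are reserved for
  the expression criterion only; the methylation criterion is analytic
  by design.

The edge weight is the *signed* co-methylation coefficient; taking
absolute values is left to presentation. Node degree ranks genes (ties
broken lexicographically), and the PPI module of a seed gene is the
exact induced subgraph on the seed plus its direct neighbors —
seed-neighbor and neighbor-neighbor links, nothing else.

Enrichment arithmetic uses the exact hypergeometric machinery: the
two-sided Fisher test sums the probabilities of all tables at fixed
margins no more probable than the observed one, and set enrichment is
the upper-tail hypergeometric probability.

## The synthetic-data generator

The generator emulates the study *design* — three matched tumor/normal
pairs profiled for promoter methylation and expression — at desk
scale, with every planted effect recorded in a manifest so that
downstream recovery is measurable. What it emulates:

* an HCP-dominant promoter landscape (default 240/40/20 HCP/ICP/LCP,
  i.e. 80/13/7%, matching the qualitative dominance of high-CpG
  promoters in mammalian annotation), one 2-kb promoter block per
  transcript laid along `chr1` with alternating strands, plus chrX/chrY
  decoy contigs carrying methylation calls that the sex-chromosome
  filter must remove;
* class-targeted sequence composition: HCP promoters carry a CpG-dense
  core (CpG-unit sampling at 35% with GC-0.55 filler), ICP promoters
  are CpG-depleted to a window ratio around 0.55, LCP promoters to
  around 0.1, so the window classifier recovers the intended class
  (>= 95% agreement at defaults; misclassification is possible in the
  tails and is part of what the agreement criterion measures);
* CpG-site methylation at the actual CpG dinucleotides of each
  promoter (up to 60 sites), beta-distributed around a per-sample
  promoter mean with class baselines 0.1/0.4/0.7 (HCP low, LCP high),
  Poisson coverage around 30x, a 2% fraction of sites emitted below 5x
  in every sample, and a planted group shift of 0.3 in 5% of promoters
  (direction chosen among those feasible for the baseline);
* log-normal FPKM with a shared per-pair offset; planted
  differentially expressed transcripts carry a 4-fold change in every
  pair; planted *anti-correlated* genes are both shifted in
  methylation and fold-changed in expression with opposite signs, and
  all of them receive CpG islands;
* a linked subset of the anti-correlated genes (a hub plus up to four
  partners) shares a per-sample latent co-regulation factor, with a
  per-gene sign matching each gene's expression direction. This is
  deliberate: with six samples, the tumor/normal contrast alone leaves
  about 72 of 720 orderings that preserve the grouping, so a
  two-sided permutation p cannot reach 0.05 on group structure alone —
  co-expression edges must reflect sample-level co-variation, as they
  do for genuinely co-regulated genes;
* a toy GO DAG of small disjoint components per branch in which the
  hub shares a leaf term with each partner (best-match average 0.4)
  while all other genes hold private components (similarity exactly
  0), and a PPI list containing the hub as a star with a
  neighbor-neighbor link plus background edges.

With `noise_sd = 0` every stochastic layer collapses: coverage is
constant, site levels equal the group means, and because the class
baselines and the default shift are multiples of 0.1 while coverage is
30, rounded read counts reproduce the levels exactly — the planted
difference of 0.3 is recovered to machine precision, which the tests
assert as equalities, not tolerances.

What the generator does **not** emulate: read-level data (no FASTQ, no
bisulfite-conversion error), genome-scale site counts (tens of
thousands of shared CpGs rather than the ~10^6 of a real RRBS run),
linkage disequilibrium between neighboring promoters, realistic GO
topology, or biological confounders (cellular composition, batch).
Passing the recovery tests therefore shows the *procedures* are
correct and well-calibrated at the planted effect sizes; it does not
certify performance on real tissue data, where effect sizes, noise
structure and annotation quality are all less favorable.

## Problem sizes and runtime choices

Defaults were chosen once as a realistic desk-scale configuration:
300 promoters across the three classes, 3 pairs, ~40 CpG sites per
promoter (~17,000 shared sites), 1000 permutations per network pair,
and 500 null simulations for the type-I calibration. These sizes keep
a full generate-and-analyze cycle under a minute while leaving every
statistic in a regime where its calibration is measurable (e.g. the
permutation type-I error estimate has a standard error of about 0.01
at 500 simulations).

## Known limitations

* The DMP rule is a rank cutoff, not a test: it always calls ~5% of
  promoters per class, even under the global null. Its planted-effect
  recall is meaningful; its false-call count is fixed by construction.
* With three pairs the default DE p-value has two degrees of freedom;
  it guards against inconsistent fold changes but has little power in
  itself. Substituting a count-based test via `test=` is recommended
  when read counts are available.
* The permutation co-expression test is granular at small n (minimum
  two-sided p of ~1/360 at n = 6 even before sampling error); edges at
  the 0.05 boundary should be read accordingly.
* Gene-level collapse keeps a single transcript per gene by |delta|;
  isoform-specific methylation regulation is out of scope.
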