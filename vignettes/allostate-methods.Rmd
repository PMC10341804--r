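---
title: "Chromatin-state analysis of allopolyploid genomes with allostate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatin-state analysis of allopolyploid genomes with allostate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allostate)
```

## Scope and model

`allostate` analyses binned chromatin signal in an allotetraploid genome
whose chromosomes carry an A or D subgenome label. All coordinates are
0-based, half-open (the BED convention); GFF3 input is converted on read, so
BED files round-trip bit-exactly. The pipeline has four statistical cores:

1. **Binarization.** For each mark, per-bin fragment counts (200-bp bins by
   default, replicates pooled to maximise depth) are reduced to
   presence/absence. The expected background rate in bin *i* is the Mock
   control count rescaled to the ChIP library depth, floored at the global
   ChIP mean (so an uninformative or absent control degrades gracefully to
   a global Poisson test). A bin is called present when the Poisson upper
   tail $P(X \ge c_i \mid \lambda_i)$ is at most the binarization threshold
   (default $10^{-4}$).

2. **The chromatin-state HMM.** States $1..K$ (default $K = 6$) evolve along
   each chromosome by a row-stochastic transition matrix; chromosomes are
   independent sequences started from the initial distribution. Given state
   $k$, the binarized marks are independent Bernoulli draws with success
   probabilities $p_{km}$ — the "enrichment probability" per mark shown in
   emission heatmaps. Learning is Baum–Welch EM: a scaled forward–backward
   E-step (implemented in C++; the per-bin emission log-probabilities are
   max-shifted before exponentiation so near-deterministic emissions do not
   underflow) and the closed-form M-step. The log-likelihood is
   non-decreasing at every iteration — asserted in the tests across
   hundreds of random starts. Emission probabilities are clamped to
   $[10^{-6}, 1 - 10^{-6}]$ to avoid degenerate zeros; convergence is
   declared when the log-likelihood improves by less than `tol` (default
   $10^{-4}$) or after `max_iter` (default 200) iterations; the best of
   `n_restarts` (default 10) seed-derived random initialisations is kept,
   making the fit fully deterministic given the seed. Decoding is Viterbi
   (joint MAP path, the default) or per-bin posterior argmax; both label
   every bin exactly once, and maximal equal-state runs become the state
   intervals of the segmentation.

3. **A negative-binomial DE test.** Library sizes are normalized by
   median-of-ratios. Per-gene dispersion comes from the method of moments
   on the pooled within-group variance, moderated by taking the maximum of
   the gene-wise estimate and the common (trimmed-mean) dispersion across
   expressed genes — with two or three replicates the gene-wise estimate
   alone is far too noisy, and the maximum is the conservative direction.
   The Wald statistic for the log2 ratio of normalized group means uses the
   NB variance model $\mathrm{Var}(X) = \mu + \alpha\mu^2$, i.e.
   $\mathrm{Var}(\log_2 \bar{X}) \approx (1/(n\mu) + \alpha/n)/\ln^2 2$
   per group, and is referred to the standard normal; p-values are
   Benjamini–Hochberg adjusted. Calls use the usual thresholds: FDR
   $\le 0.05$ and $|\log_2 \mathrm{FC}| > 1$. The test is validated for
   type-I error under a global null and for power at a planted 8-fold
   change, not for equality with any particular reference implementation.

4. **Exact enrichment kernels.** Fisher's exact test sums hypergeometric
   probabilities of all tables (at fixed margins) no more probable than the
   observed one — the standard two-sided definition, checked against
   explicit enumeration to $10^{-10}$. The Wilcoxon rank-sum p-value is
   computed by complete enumeration of rank splits whenever both groups
   have at most 10 observations (ties handled naturally), and otherwise by
   the tie-corrected normal approximation without continuity correction.

## Pipeline semantics and tunable parameters

All defaults live in `pipeline_config()` and are the study settings, so the
zero-edit configuration is "paper mode":

| parameter | default | meaning |
|---|---|---|
| `bin_width` | 200 bp | chromatin bin size |
| `binarize_p` | 1e-4 | Poisson tail threshold for mark presence |
| `K` | 6 | number of chromatin states |
| `peak_p`, `peak_fc` | 1e-10, 5 | broad-peak Poisson tail and fold-change cuts |
| `promoter_len` | 500 bp | promoter = bases immediately upstream of the TSS |
| `de_alpha`, `de_lfc` | 0.05, 1 | DEG thresholds (FDR, \|log2FC\|) |
| `rbh_e`, `rbh_cov`, `rbh_id` | 1e-5, 50, 50 | homoeolog RBH cuts |
| `kmeans_k` | 5 | gene histone-signature clusters |

Further semantics, fixed once and documented here:

* **Fragments are assigned to the single bin containing their midpoint**, so
  binning conserves fragment counts exactly. The terminal bin of a
  chromosome is kept at reduced width; RPKM always uses the nominal bin
  width.
* **Peak consensus** is anchored on replicate 1: a peak is retained when it
  overlaps any replicate-2 peak by at least one base, and its interval is
  widened to the union of itself and all overlapping replicate-2 peaks.
  The cross-mark overlap statistic counts a peak as overlapped when at
  least 50% of its bases are covered by the other set; the fraction is
  asymmetric per ordered pair of marks.
* **Peak annotation** uses the peak midpoint with precedence
  gene > TE > intergenic when features overlap, so the three categories
  partition every peak set.
* **The element map** partitions the genome into promoter, exon, intron and
  intergenic bases with precedence promoter > exon > intron on overlapping
  annotation; the intron class is gene body minus exons minus
  promoter-claimed bases, and promoter bases are excluded from intergenic.
  Background rows of the proportion tables are the whole-genome element (or
  TE-class) composition.
* **Gene-state assignment** gives each gene the state covering most bases of
  its promoter; a tie goes to the state at the promoter's 5'-most base
  (farthest upstream in transcription orientation). A promoter that clamps
  to zero length at a chromosome edge yields `"unsegmented"`, and such
  genes are excluded from transition denominators (the excluded ids are
  reported).
* **Cross-condition comparability.** One model is trained on the
  condition-1 binarized data and applied in decode-only mode to both
  conditions, so state identities match across conditions by construction.
  For independently trained models, `match_states()` aligns states to a
  reference emission matrix by greedy minimal total-variation assignment —
  the same utility maps learned states onto planted simulation states in
  the tests.
* **State relabelling.** EM state indices are arbitrary, so fitted models
  are canonicalised by lexicographic descending sort of emission vectors in
  mark order, ties broken by original index; the operation is idempotent
  and applied consistently to model and segmentation.
* **RBH classification.** A query's best hit is its lowest-E-value hit
  (ties: higher identity, then lexicographically smaller target id). Pairs
  require mutual best hits with both hits passing all three cuts. A gene
  is subgenome-unique when *every* cross-subgenome hit fails the
  coverage-or-identity similarity requirement (or it has none); genes with
  passing but non-reciprocal hits form a third, reported-but-unanalysed
  class.
* **Homoeolog expression bias** reuses the NB test with the two pair
  members as pseudo-conditions across RNA replicates; a pair with a member
  missing from the count matrix is categorised balanced and logged.
* **k-means clustering** operates on per-mark z-scored gene-body RPKM, with
  seeded k-means++ initial centers followed by Lloyd iterations, and labels
  renumbered by descending cluster size — deterministic given the seed.
  Genes are pre-filtered to those with at least one histone peak in the
  gene body (`genes_with_body_peaks()`).

## The synthetic data generator

`simulation_config()` describes a toy allotetraploid designed to exercise
every pipeline stage against known truth:

* a 3-Mb genome — two 1-Mb A chromosomes and two 0.5-Mb D chromosomes,
  preserving the roughly 2:1 A:D genome-size ratio of tetraploid cotton at
  1/700 scale — with 800 A and 500 D genes (non-overlapping, at least
  500 bp upstream clearance, 1–3 exons) and 400 TEs from a
  Gypsy/Copia/hAT/Helitron/CACTA mixture;
* a hidden six-state Markov chain per 200-bp bin whose default emission
  matrix mirrors the canonical plant chromatin-state repertoire (Polycomb,
  quiescent, open-only, active-promoter-like, acetylation-dominated open,
  transcribed-inaccessible) and whose sticky transition matrix funnels mass
  back to the quiescent state so that it dominates the genome (roughly
  70–80% at stationarity, matching the scale of real genomes);
* per-bin Poisson fragment counts with rate
  `rate_low + p_km * (rate_high - rate_low)` (defaults 0.2 and 6 per
  replicate) for each of five histone marks and DNase, two replicates, two
  conditions, plus a Mock control at the background rate;
* planted structure: 15% of genes have their condition-2 promoter bins
  switched to a different state (quiescent promoters preferentially switch
  to the open state); switches out of (into) the quiescent state are
  coupled to planted up- (down-) regulation with probability 0.8; a further
  20% of genes receive a random four-fold expression change; homoeolog
  pairs share baseline negative-binomial means (dispersion 0.05, log-normal
  mean grid), while A-subgenome-unique genes get a two-fold expression
  bias — so subgenome bias lives in the unique genes and pairs stay
  balanced;
* similarity tables that guarantee exact RBH recovery: mutual best hits
  above all cuts for planted pairs, sub-threshold hits for unique genes,
  and passing-but-non-reciprocal decoy hits for the remainder.

Everything is deterministic given the seed, and all truth labels are
exported (`truth/` directory in pipeline runs) for recovery tests.

**What the generator does not emulate** — and therefore what passing tests
do not show about real data: read-level sequencing artefacts (mappability,
GC bias, duplicates), spatially varying background, fragment-size effects,
overlapping or nested genes, isoform structure, TE sequence evolution, and
the mixture of partial homology real proteomes produce. Counts are Poisson
per bin rather than simulated reads, which is sufficient for validating
binarization and HMM inference but not aligner behaviour. The planted
emission signal is proportional to the Bernoulli emission probability, so
learned emissions on synthetic ChIP tracks are a monotone transform rather
than a copy of the planted matrix; exact emission recovery is instead
validated on data drawn directly from the Bernoulli model
(`simulate_binary_from_hmm()`), where a planted six-state, six-mark model
at 200,000 bins is recovered to better than 0.01 per entry.

## Numerical choices and degenerate inputs

* Forward/backward use per-position scaling plus a per-bin max-shift of the
  emission log-probabilities; Viterbi works entirely in log space with
  probabilities floored at 1e-300 before the logarithm.
* An EM transition row with no expected visits falls back to uniform.
* `fisher_exact` compares table probabilities with a relative tolerance of
  1e-7 when accumulating the two-sided tail, the standard guard against
  ties broken by floating-point noise.
* Zero-variance tracks make replicate correlation undefined — an error, not
  a silent NA. Empty peak-set A makes the overlap fraction undefined —
  likewise an error. All-zero genes are reported `ns` with FDR 1.
* Metagene positions beyond a chromosome edge are dropped from the mean at
  that offset; an offset with no usable gene is `NaN`.
* `bias_summary()` works from counts, so the headline percentage can be
  reproduced from published tables without re-running the DE machinery.

## Problem sizes used in the validation suite

The tests and the acceptance script size their simulations to be decisive
yet quick: oracle comparisons use sequences of length ≤ 8 where exhaustive
path enumeration is feasible; EM behaviour is checked on 300–20,000-bin
genomes; planted-model recovery uses 100,000–200,000 bins with 5–10
restarts; DE calibration uses 50–200 simulation replicates of 100–2,000
genes; the end-to-end pipeline runs the full 3-Mb toy genome. The complete
suite runs in a few minutes on one CPU.

## Known limitations

* The peak caller is deliberately minimal: no local-lambda sliding windows,
  no model building, no q-values — it is a specified, testable stand-in,
  not a MACS2 replacement.
* The DE test targets calibration and power, not feature parity with
  DESeq2 (no shrunken fold changes, no outlier replacement, no independent
  filtering).
* Joint binarization of two conditions against a shared background is not
  implemented; cross-condition comparability is achieved by decoding both
  conditions with one model (or post-hoc emission matching).
* K selection is the user's; the package fits the requested K and reports
  likelihoods, nothing more.
* GO enrichment of gene groups is out of scope; gene lists per transition
  group and cluster are exported for external tools.
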