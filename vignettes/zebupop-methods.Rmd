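---
title: "Methods and design of zebupop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of zebupop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

zebupop implements the population-genomic analysis flow used for SNP-array
surveys of livestock breeds: quality control, LD pruning, diversity and
F-statistics, structure and admixture inference, hierarchical AMOVA,
LD-based effective population size, and pairwise F\_ST selection scans with
interval annotation. This vignette documents the statistical models, the
parameter choices, and the design decisions, in the order the pipeline runs
them.

## Quality control

`filter_samples()` and `filter_snps()` reproduce the standard PLINK-style
cascade with the boundary semantics taken literally:

* samples are removed when their missing-call fraction over **autosomal**
  markers is strictly greater than `mind_max` (default 0.1) — a sample
  exactly at the boundary is kept;
* markers are removed when call rate ≤ `cr_min` (0.95), minor allele
  frequency ≤ `maf_min` (0.05) or Hardy–Weinberg exact p ≤ `hwe_alpha`
  (0.001) — all inclusive at the boundary;
* stages run in a fixed order (autosome → call rate → MAF → HWE) and the
  `QcReport` counts telescope exactly, so `n_in - n_removed = n_out` at
  every stage.

The HWE test is the exact conditional test (no mid-p): given the allele
totals, the p-value sums the probabilities of all heterozygote counts of
the same parity whose conditional probability does not exceed the observed
one. It is computed in log-factorial space and is verified in the test
suite against an independent enumeration oracle built on the
probability-ratio recurrence, exhaustively for all genotype triples with
total ≤ 30. HWE is computed on the pooled sample by default, mirroring the
single-pass convention of array QC; because pooling confounds the Wahlund
effect with genotyping error, a `hwe_by_pop` option tests within
populations and removes a marker on its smallest per-population p.

## Weir–Cockerham F-statistics

`wc_fst_per_locus()` implements the biallelic moment estimator with
per-locus components *a* (among populations), *b* (among individuals
within populations) and *c* (within individuals), built from the weighted
allele frequency mean, the among-population variance `s²`, the weighted
heterozygote fraction, and the sample-size correction `n_c`. Two
conventions are enforced throughout:

* aggregation over loci is always the **ratio of sums** `Σa / Σ(a+b+c)`,
  never the mean of per-locus ratios;
* loci with `a + b + c = 0` (monomorphic) are excluded from aggregates,
  and loci with fewer than two populations called, a population entirely
  missing, or a mean sample size of one are undefined (`NA`).

Missing genotypes are handled by using per-locus called counts as the
`n_i`. The estimator is validated two independent ways: against a literal
scalar transcription of the published equations on random unbalanced
configurations, and against a gametic nested-ANOVA route (see AMOVA below)
that reproduces *a*, *b*, *c* to machine precision.

## Diversity summaries and differentiation indices

Per-breed tables report observed heterozygosity, the **unbiased** expected
heterozygosity `2p̂q̂ · 2n/(2n−1)`, mean MAF, and an inbreeding coefficient
computed per sample from excess homozygosity,
`F = (O_hom − E_hom)/(L_called − E_hom)`, averaged within breeds.
Monomorphic loci are included in the averages as zeros, which keeps the
breed means comparable across marker panels.

The differentiation indices use the plain gene diversity `2pq` (no
small-sample correction): per locus, `H_S` is the unweighted mean of the
within-population diversities, `H_T` the diversity of the unweighted mean
frequency, `D_ST = H_T − H_S`, and Jost's
`D_est = (k/(k−1)) · (H_T − H_S)/(1 − H_S)`. The uncorrected form is
deliberate: with the unbiased estimator, identical populations would give a
*negative* `D_ST`, violating `H_T ≥ H_S`; with the plain form the
inequality is Jensen-exact and identical populations give exactly zero.
Loci are averaged after the per-locus computation; loci with `H_S = 1` are
excluded from the `D_est` mean.

Nei's standard genetic distance (1972) is
`D = −ln(J_xy / sqrt(J_x J_y))` on biallelic frequencies; a zero
cross-identity returns `Inf` with a warning rather than an error, so a
fully fixed pair does not crash a distance matrix.

## Structure: IBS, MDS, admixture EM

The genomic relationship is the identity-by-state matrix, the mean of the
per-locus allele-sharing score `(2 − |g_i − g_j|)/2` over pairwise-called
loci. Principal-coordinate projection (`mds_projection()`) double-centres
`D = 1 − IBS`; the variance explained by a component is its eigenvalue as
a percentage of the positive-eigenvalue sum, and component signs are fixed
so the largest-magnitude coordinate is positive (classical MDS is
sign-indeterminate). PCA-on-IBS and MDS are the same operation here, and
are treated as one.

`admixture_em()` maximizes the standard admixture likelihood
`log L = Σ_{il} [g_il log Σ_k q_ik p_kl + (2−g_il) log Σ_k q_ik (1−p_kl)]`
by EM: each allele copy is split among clusters by responsibility, and `Q`
and `P` are re-estimated from expected copy counts. This is the
point-estimation counterpart of Bayesian model-based clustering: same
likelihood, deterministic given the seed. Numerical choices:

* `P` is clamped to `[1e−9, 1 − 1e−9]` after each update so monomorphic
  clusters cannot produce infinite log-terms; the log-likelihood is
  evaluated with mixture probabilities clamped at `1e−12`. The EM
  monotonicity guarantee therefore holds up to that clamping; the tests
  assert non-decrease at a relative tolerance of `1e−6`.
* Convergence is relative log-likelihood change below `tol = 1e−6`, with a
  2000-iteration cap; multiple random restarts (`restarts`) return the
  best final likelihood.
* Missing genotypes contribute nothing to the likelihood (per-entry
  omission), and `Q` rows are renormalized to sum to one.

`choose_k()` fans a master seed into per-(K, run) seeds, reports the mean
and best final log-likelihood per K, and selects the argmax of the mean
curve; the raw curve is returned because a plateau is often the honest
answer and is best judged by eye.

## Hierarchical AMOVA and F-statistics

Both operate at the **gametic** level: each individual contributes two
pseudo-gametes, with heterozygotes split allele-count-preservingly (the
assignment is arbitrary but consistent, and mismatch counts are invariant
to it). A within-individual stratum only exists at this level, which is
why the gametic representation was chosen.

`amova()` partitions squared gametic distances — allele mismatch counts
over pairwise-called loci, rescaled by `L/L_called` — across up to four
nested levels. Variance components are obtained by equating the observed
SSDs to their expectations; the expectation coefficients are computed
*numerically from the design* (for each pair of nesting levels,
`Σ_u (n_u − Σ_v n_v²/n_u)`), so unbalanced layouts need no special-case
algebra. Negative components are retained and percentages are taken over
all defined components, so they always sum to 100. Permutation tests use
the standard scheme per level — whole populations among groups,
individuals among populations within groups, gametes among individuals
within populations — and, for the within-individual stratum, gametes among
individuals across the whole sample, one-sided toward a *deficit* of
within-individual variation (the excess-homozygosity direction). P-values
carry the `(hits+1)/(n_perm+1)` correction; with the default 1023
permutations the smallest attainable p is 1/1024. P-values are
deterministic given the seed; the variance components (though not the
individual permutation draws) are invariant to sample order.

`hierarchical_fstats()` runs the same nested ANOVA per locus on gamete
allele values for the hierarchy total → factor 1 → … → factor m →
individual → gamete, with factors made strictly nested by crossing each
with the levels above it. Components are summed over loci and converted to
F-statistics: the F of inner level *u* against enclosing level *v* is the
ratio of the summed components between them to the summed components below
*v*. For a single factor this reproduces the Weir–Cockerham `F_ST`
(against Total) and `F_IS` (Individual against the factor) exactly — the
package's tests assert agreement to `1e−10` — which is the designed
cross-check between the two modules.

## LD, pruning and effective population size

`genotype_r2()` is the squared Pearson correlation of dosages over
pairwise-complete samples; zero variance at either locus is an undefined
sentinel, not zero. `ld_prune()` is a deterministic greedy analogue of
window-based pruning: scanning left to right within each chromosome, any
later locus within 500 kb correlated above `r² = 0.5` with a kept locus
triggers removal of the lower-MAF locus of the pair (tie → the downstream
locus). The surviving set provably contains no within-window pair above
the threshold, and the operation is idempotent.

`ld_decay_bins()` assigns all intra-chromosomal pairs to physical-distance
bins and converts bin midpoints to Morgans with the linear map
100 Mb = 1 Morgan (no Haldane/Kosambi option: the linear map is the
assumption the downstream inversion uses). `ne_trajectory()` inverts the
drift expectation per bin:

* `r²_adj = mean r² − 1/(βn)` with β = 2 for phased and 1 for unphased
  data (`n = Inf` disables the correction);
* `Ne = (1/4c) (1/r²_adj − α)` and `t = 1/(2c)` generations;
* bins with non-positive `r²_adj` or `Ne` are flagged and dropped.

The drift constant α defaults to 2.2 (the mutation-adjusted value used by
LD-based Ne software), with 1 and 2 the other conventional choices; the
inversion `ne_trajectory(expected_r2_curve(Ne, ·))` is exact whenever the
same α, β and n are used on both sides. Per-breed Ne is computed on
post-QC, *pre-pruning* genotypes: LD is the signal here, so pruning is
reserved for the diversity and structure stages.

## Synthetic cohorts and what they do (not) emulate

`simulate_cohort()` uses the Balding–Nichols model: population frequencies
`p_kl ~ Beta(p_l(1−F_k)/F_k, (1−p_l)(1−F_k)/F_k)` around a uniform
ancestral law on [0.05, 0.95], pure or Dirichlet ancestry per individual,
and each allele copy drawn by sampling a cluster from the individual's Q
row. Balding–Nichols was chosen because F\_ST is its explicit parameter,
making parameter recovery the natural acceptance surface; the ancestral
range keeps the post-QC MAF spectrum in the 0.2–0.3 band typical of
commercial array panels. `F_k = 0` is handled exactly (population at the
ancestral frequencies) and `F_k = 1` rejected as a degenerate Beta.

`simulate_ld_cohort()` generates haplotypes by a first-order copying chain
whose latent uniform is retained between adjacent loci with probability
`exp(−λ·c)`; with a per-haplotype recombination intensity
`λ ~ Gamma(shape 1/2, scale 4Ne)` the mixture makes the pairwise
haplotype correlation *exactly* `(1 + 4Ne·c)^{−1/2}` at every distance —
the analytic calibration replaces a forward-in-time simulation, keeping
the generator fast and its target curve known in closed form. The allele
frequency is drawn once per chromosome because a locus-varying frequency
under the shared-uniform coupling would attenuate the correlation below
the target. Consequences worth knowing:

* all loci on a chromosome share one frequency — realistic LD decay, but
  not a realistic site-frequency spectrum;
* the Gamma mixture gives individual haplotypes heterogeneous "effective
  recombination histories", so single-chromosome r² bin means have heavy
  inter-seed variance; Ne recovery is therefore run over several
  chromosomes (the tests use 4 × 1500 markers, 200 samples), where it
  lands within ±20 % of truth.

Neither generator emulates ascertainment bias, genotyping error beyond
missingness-at-random, family structure, or selection; passing tests show
estimator correctness under the stated models, not robustness to those
real-data features.

## Selection scan

`pairwise_scan()` computes the two-breed Weir–Cockerham θ per locus.
`call_sweeps()` thresholds at θ ≥ 0.25 (the 0.50 tier selects the top
signatures), merges peaks within one flank (1 Mb) of each other on a
chromosome — so a single sweep is not double-reported — and spans each
region `peak ± 1 Mb`, clipped at the chromosome start. Intervals are
half-open 0-based internally and reported 1-based. The optional
significance filter permutes breed labels among the pair's samples,
recomputes θ at the peak locus in closed form from per-group sufficient
statistics, and retains regions with `p < alpha`; one set of permutations
is shared across peak loci within a scan. The default `alpha = 1e−4` and
the alternative 0.001 are both plain arguments because the two conventions
coexist in practice.

A property worth stating plainly: under a Balding–Nichols background at
F = 0.05 with no sweeps, the scan does **not** return zero regions. The
Beta tail places roughly 1–2 % of loci at true per-locus differentiation
above 0.25, and the label-permutation null — which tests exchangeability,
i.e. *any* differentiation — correctly rejects for them. Distinguishing
"unusually differentiated for this genome" from "differentiated at all"
would require an outlier-style null (e.g. permuting against the
genome-wide θ distribution), which is out of scope here; the filter's
measured job is to remove sampling-noise threshold crossings, which it
does, while fixed-difference sweeps are recovered essentially always.

Annotation attaches gene and QTL features overlapping a region by ≥ 1 bp
under half-open semantics (a feature starting exactly at the region end is
not attached), tallies QTLs by the seven canonical trait classes (MY, MC,
R, M/C, H, P, M; unknown labels pass through untallied with a warning),
and the two-proportion z test compares QTL class counts between contrasts
with the pooled-variance statistic.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes the stages in the order above, writes each table
as CSV plus a JSON manifest recording the seed, every effective threshold
and the stage counts, and derives per-stage seeds from the single global
seed through one `sample.int()` draw, so any stage can be reproduced in
isolation. All defaults are the analysis-standard settings listed in
`run_config()`.

The test and acceptance workloads use desk-scale sizes chosen to make
Monte-Carlo noise small relative to the asserted tolerances while keeping
a full run in tens of seconds: 200 samples × 5000 loci for divergence
recovery (5 seeds per F), 4 × 1500 markers for Ne recovery, 60 × 800 for
admixture recovery, and 20 replicates of 32 × 1000 for the scan
properties. The acceptance script additionally runs a 112-animal,
7-breed, 5000-marker cohort shaped like a typical indicine breed survey
(per-breed sizes 13–18, divergence 0.05, 1 % missingness) through the full
QC → pruning → diversity → structure → AMOVA flow.

## Known limitations

* The scan's permutation filter tests exchangeability, not outlierness
  (see above).
* `D_est` uses the plain (uncorrected) gene diversities; small samples
  therefore bias `H_S` slightly downward.
* The LD generator's per-chromosome allele frequency and Gamma-mixture
  construction are calibrated for the r² *mean curve*, not for haplotype
  diversity statistics; do not use it to benchmark haplotype-based
  methods.
* AMOVA requires every gamete pair to share at least one called locus;
  cohorts sparser than that need imputation or stricter QC first.
* Admixture EM finds local maxima; use `restarts` (and `choose_k()`'s
  replicate runs) rather than trusting a single run.
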