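# zebupop

Population-genomic analysis of SNP-array genotyped livestock breeds, built
for surveys of the kind run on indicine (zebu) cattle: a handful of breeds,
a dense chip, and the standard question set — how diverse is each breed,
how are they structured, how large were their ancestral populations, and
which genomic regions set them apart.

The package covers the full flow as composable functions plus a
config-driven pipeline:

* **IO** — PLINK text PED/MAP read/write, allele-dosage conversion, BED and
  GFF3 feature tracks (unified to half-open 0-based intervals).
* **QC** — sample missingness (MIND > 0.1), SNP call rate (CR ≤ 0.95), MAF
  (≤ 0.05) and a Hardy–Weinberg exact test (p ≤ 0.001), autosomes only,
  with telescoping stage reports.
* **Diversity** — observed/expected heterozygosity, MAF, per-sample
  inbreeding F; Weir–Cockerham F_ST with per-locus variance components
  *a*, *b*, *c* and the ratio-of-sums aggregate θ = Σa / Σ(a+b+c);
  pairwise θ and Nei (1972) distances; H_S, H_T, D_ST and Jost's D_est.
* **Structure** — identity-by-state relationship matrix, classical MDS with
  variance-explained percentages, maximum-likelihood admixture by EM
  (ancestry matrix Q, cluster frequencies P, monotone log-likelihood), and
  K selection by mean log-likelihood.
* **AMOVA** — hierarchical analysis of molecular variance on gametic
  mismatch distances (groups / populations / individuals / within
  individuals) with permutation tests, and hierarchical F-statistics over
  nested factors that reduce exactly to F_ST/F_IS for a single factor.
* **Ne** — LD decay binned by map distance (100 Mb = 1 Morgan), inverted
  per bin via Ne = (1/4c)(1/r²_adj − α) at generation t = 1/(2c).
* **Selection scan** — pairwise-breed per-locus θ, sweep calling at
  θ ≥ 0.25 with ±1 Mb flanks and peak merging, an optional
  label-permutation significance filter, gene/QTL annotation, and a
  two-proportion z test for QTL class counts.
* **Synthetic cohorts** — a Balding–Nichols generator (per-population
  frequencies Beta-distributed around an ancestral law, so F_ST is known
  by construction), Dirichlet admixture, missingness injection, and an
  LD cohort generator whose pairwise haplotype correlation is exactly
  (1 + 4·Ne·c)^(−1/2) by analytic calibration — every downstream stage can
  be tested against ground truth.

## Worked example

```r
library(zebupop)

# simulate a three-breed cohort with known divergence
sim <- simulate_cohort(sim_spec(
  n_pops = 3, fst = c(0.05, 0.05, 0.20), n_per_pop = 16,
  n_snps = 2000, n_chrom = 2, missing_rate = 0.01, seed = 42))
cohort <- sim$cohort
cohort
#> <cohort> 48 samples x 2000 variants
#> populations: P1 (16), P2 (16), P3 (16)
#> missing calls: 0.99%

qc <- filter_snps(filter_samples(cohort, mind_max = 0.1)$cohort)
qc$report
#> QC cascade:
#>   autosome               2000 ->   2000 (removed 0)
#>   call_rate              2000 ->   1977 (removed 23, threshold 0.95)
#>   maf                    1977 ->   1854 (removed 123, threshold 0.05)
#>   hwe                    1854 ->   1842 (removed 12, threshold 0.001)

dos <- to_dosage(qc$cohort, "minor")
wc_fst_per_locus(dos)
#> <fst_components> 1842 loci, 3 populations; global theta = 0.1031
#> defined per-locus theta: 1842; range -0.039 .. 0.586
round(pairwise_fst(dos), 3)
#>       P1    P2    P3
#> P1 0.000 0.056 0.127
#> P2 0.056 0.000 0.127
#> P3 0.127 0.127 0.000
```

The pairwise table reads directly as breed differentiation: P1 and P2 were
simulated at divergence 0.05 each (pairwise expectation ≈ 0.05–0.06 after
shared drift), P3 at 0.20, and the estimates land on those targets.

```r
mds_projection(ibs_matrix(dos))
#> <mds_projection> 48 samples, 3 components
#> variance explained (%): 15.8, 7.4, 2.8

fit <- admixture_em(dos, K = 3, seed = 1, restarts = 2)
round(membership_table(fit, attr(dos, "pops")), 3)
#>     [,1]  [,2]  [,3]
#> P1 0.029 0.920 0.051
#> P2 0.867 0.103 0.030
#> P3 0.003 0.002 0.996
```

Each breed's samples assign > 86 % of their genome to an own cluster —
the membership table is the admixture analogue of a structure bar plot,
one row per pre-defined population.

```r
ld <- simulate_ld_cohort(ne = 100, n_samples = 100, chrom_length_bp = 5e7,
                         n_snps = 1500, n_chrom = 4, seed = 7)
bins <- ld_decay_bins(to_dosage(ld$cohort), n_bins = 30,
                      min_dist_bp = 2e5, max_dist_bp = 3e6)
head(ne_trajectory(bins, n = 100, alpha = 1), 3)
#>          t       ne   c_morgan     r2_adj
#> 1 16.93002 114.1913 0.02953333 0.06901409
#> 2 17.48252 114.9205 0.02860000 0.07068685
#> 3 18.07229 115.7719 0.02766667 0.07240033
```

The trajectory recovers the simulated Ne = 100 within sampling error,
reading "about 17 generations ago the effective size was ≈ 114".

For a full run — QC through selection scans, with CSV tables and a JSON
manifest — use the pipeline:

```r
cfg <- run_config("cohort.ped", "cohort.map",
                  overrides = list(amova_group_col = "dairy_level",
                                   seed = 42))
run_pipeline(cfg, "results/")
```

A thin command-line wrapper is provided in
`inst/scripts/run_pipeline.R` (`Rscript run_pipeline.R --config run.yaml
--out results/`).

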