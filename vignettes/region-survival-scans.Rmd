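---
title: "Candidate-gene survival scans with max-T permutation and meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene survival scans with max-T permutation and meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(survscan)
library(dplyr)
```

## The analysis this package implements

survscan implements a candidate-gene association pipeline for survival
outcomes, of the kind used to test whether common variants in a family of
genes (say, heat shock protein and heat shock factor genes) associate with
all-cause mortality across several population-based cohorts:

1. **SNP quality control.** Imputed dosages are filtered on Hardy–Weinberg
   equilibrium (chi-square p ≥ 1e-4), call rate (≥ 95%), imputation
   R² (> 0.8) and minor allele frequency (> 0.05).
2. **Per-SNP Cox scan.** For each SNP, a semi-parametric Cox proportional
   hazards model of time to death, additive in the coded-allele dosage and
   adjusted for baseline age and sex, restricted to individuals older
   than 55 at baseline. The per-SNP statistic is the 1-df Wald chi-square
   of the dosage term.
3. **Region-wide max-T permutation.** Candidate genes ± 100 kb are merged
   into regions of interest; within each region, phenotypes are permuted as
   intact tuples against fixed genotypes and the null distribution of the
   region-wide *maximum* Wald statistic is accumulated (default B = 10,000).
   Each SNP's family-wise empirical p is the proportion of null maxima at or
   above its observed statistic; regions with empirical p < 0.10 are
   "suggestive".
4. **Backward stepwise selection.** Within suggestive regions, a joint
   multi-SNP Cox model is reduced by repeatedly removing the least
   significant SNP until all remaining SNP terms are nominally significant
   (p < 0.05), yielding the independently associated SNPs.
5. **Replication and meta-analysis.** Selected SNPs are scanned in the
   replication cohorts; per-cohort log hazard ratios are pooled by
   fixed-effects inverse variance, effect-direction consistency is
   summarized as a `+`/`-` string in a fixed cohort order, and the joint p
   is judged against a Bonferroni threshold of 0.05 divided by the number
   of validated SNPs.

Because individual-level cohort data of this kind cannot be shipped, the
package carries a simulator that reproduces the *statistical structure* the
pipeline assumes, so that every stage is testable end to end.

## The model and its assumptions

For individual $i$ with dosage $g_i \in [0,2]$, age $a_i$ and sex $s_i$, the
hazard is

$$\lambda_i(t) = \lambda_0(t)\,
  \exp(\beta_g g_i + \beta_a a_i + \beta_s s_i),$$

on the *time-on-study* scale: follow-up years since baseline, with age as a
covariate rather than as the time scale. That matches the adjustment
"for age at blood collection and sex" and is the model both the scan and
the simulator use, so parameter-recovery tests are internally consistent.
$\exp(\beta_g)$ is the hazard ratio per additional coded allele; the coded
allele is fixed by the annotation table and never re-inferred from
frequency, so effect orientation cannot flip between cohorts. Ties are
handled by the Efron approximation; the small-n oracle tests use tie-free
data, where Efron, Breslow and the exact likelihood coincide.

## What the simulator emulates — and what it does not

`simulate_haplotypes()` draws binary haplotypes from a first-order Markov
chain: SNP $j$ is Bernoulli with its specified frequency, correlated with
SNP $j-1$ so that adjacent alleles have correlation $\sqrt{r^2_{adj}}$.
This produces geometrically decaying LD along the region — correlated test
statistics, which is all the max-T correction needs — but no recombination
hotspots, no allele-frequency spectrum, no demography. Not every
(frequency, correlation) pair is achievable for binary variables; requests
beyond the Fréchet bound fail with an explicit error naming the SNP pair.

`genotypes_from_haplotypes()` pairs haplotypes at random, so genotypes are
in Hardy–Weinberg proportions in expectation. `add_imputation_noise()`
blurs hard genotypes into dosages whose variance ratio against the binomial
variance $2p(1-p)$ — the usual imputation R² — hits a target: a linear
shrink toward the SNP mean plus Gaussian jitter, clipped to $[0,2]$, with
the shrink factor calibrated by bisection because clipping removes tail
variance. The construction keeps the regression of truth on dosage at
slope 1, the property a conditional-expectation dosage has, which is why
scanning noisy dosages stays approximately unbiased for $\beta_g$.

`simulate_survival()` draws event times from a Weibull
proportional-hazards model, $T = \lambda(-\log U / e^{lp})^{1/\rho}$, with
administrative censoring at a fixed follow-up horizon. Baseline age is
normal truncated at 55 (the eligibility age), sex Bernoulli. The default
nine-cohort design (`example_cohort_specs()`) mirrors a large aging
consortium: one discovery cohort of ~6,000 with ~53% deceased, and eight
replication cohorts of 620–4,511 individuals with death fractions
0.17–0.53 and 5–16 year follow-up; Weibull scales are solved from the
target death fraction via `weibull_scale_for_event_fraction()` with shape
1.3 (hazard rising with time on study, as for old-age mortality). Exact
per-cohort event-time distributions of any real consortium are not targeted
— means are matched approximately, which is enough for power and
calibration experiments.

Two deliberate simplifications matter for interpreting green tests:
genotypes are drawn independently of age and sex, so the simulator cannot
produce genotype–covariate confounding (the confounding test constructs an
age-dependent genotype explicitly); and phenotype tuples are exchangeable
across individuals, which is exactly the assumption the permutation test
needs — real cohorts satisfy it only approximately (e.g. under population
structure correlated with survival).

## Worked example

```{r pipeline, message = FALSE}
blk <- ld_block_spec(10, maf = 0.35, adj_r2 = 0.8)
eff <- effect_spec(causal_snp_index = 5, beta_g = log(0.8))
cohorts <- example_cohort_specs(1)[1:3] # discovery + two replications
sims <- simulate_multi_cohort(cohorts, blk, eff, master_seed = 1,
                              imp_r2 = 0.95)

qc <- apply_qc(snp_summary(sims$geno[[1]]))
qc_report(qc)

pr <- roi_permutation(
  sims$geno[[1]], sims$phen[[1]], snp_ids = qc$snp_id[qc$pass],
  config = perm_config(n_perm = 500, seed = 2), roi_id = "demo"
)
glance(pr)

sel <- backward_select(sims$geno[[1]], sims$phen[[1]], qc$snp_id[qc$pass])
sel$selected

est <- purrr::map2_dfr(sims$geno, sims$phen,
                       ~ scan_snps(.x, .y, snp_ids = sel$selected[1]))
est$cohort <- sims$cohort
meta <- fixed_effect_meta(est, snp_id = sel$selected[1],
                          bonferroni_alpha = bonferroni_threshold(0.05, 3))
meta
```

`autoplot(meta)` draws the forest plot; `autoplot(pr)` the null-maximum
histogram.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| ROI margin | 100 kb each side | regulatory neighbourhood of a candidate gene; overlapping windows merge |
| HWE p, call rate | ≥ 1e-4, ≥ 95% (inclusive) | genotype-level QC; boundary conventions mirror the stated criteria exactly |
| imputation R², MAF | > 0.8, > 0.05 (strict) | dosage-quality and frequency filters; strict bounds, so MAF exactly 0.05 fails |
| B (permutations) | 10,000 | resolves empirical p to 1e-4; tests use 500–2,000 for runtime |
| suggestive threshold | empirical p < 0.10 (strict) | screening level for carrying a region into selection |
| stepwise alpha | 0.05 | nominal significance to stay in the joint model |
| collinearity prune | dosage r² > 0.95 | keeps the joint likelihood well-conditioned; escalates 0.95 → 0.8 → 0.5 on non-convergence |
| CI quantile | 1.959964 | full-precision normal quantile, so `se_from_ci()` inverts CI construction to 1e-12 |

## Numerical and design choices

* **Empirical p estimator.** The literal proportion r/B of null maxima at
  or above the observed statistic, ties counted; it can return exactly 0.
  The (r+1)/(B+1) variant is available (`perm_config(estimator =
  "add_one")`) but off by default. With r/B and B = 500, the probability a
  null region is flagged at 0.10 is 50/501 ≈ 0.0998 — calibrated, as the
  acceptance test verifies empirically.
* **One permutation stream per replicate, shared by all SNPs.** Required
  for a valid region-wide maximum; per-SNP streams would destroy the joint
  null. Covariates are permuted together with the outcome as intact tuples,
  preserving the outcome–covariate relationship and breaking only the
  genotype–phenotype link. Internally the engine permutes genotype rows by
  the inverse permutation — the identical set of pairs, so identical
  statistics (asserted exactly in tests) — letting it reuse one
  time-sorted phenotype across the roughly B × m partial-likelihood fits.
* **Statistic.** The Wald chi-square of the dosage term. For 1-df tests
  Wald, score and −log p are monotone transforms of each other at a given
  fit, so the max-T ranking is essentially unchanged; Wald is what the
  per-SNP scan already produces.
* **Stepwise details.** Selection starts from *all* QC-passing SNPs in the
  region (the standard backward procedure), not only nominally significant
  ones; only SNP terms are removal candidates; the replication estimate
  carried forward is the single-SNP marginal, not the joint coefficient.
  A selected SNP's meta-analysed effect still carries winner's-curse bias
  when the discovery cohort is included — visible in the acceptance
  script's synthetic run, where the causal-SNP meta is unbiased but the
  selected-SNP meta can overshoot.
* **Fixed effects, not random effects.** Inverse-variance fixed-effects
  pooling is the convention for this design and is what reproduces the
  worked example's pooled row from its inputs; Cochran's Q and I² are
  reported but gate nothing.
* **HWE on dosages.** The HWE chi-square is computed on hard calls
  (rounded dosages) and skipped entirely for SNPs with imputation R²
  below 0.3, where hard calls are meaningless. The chi-square is used
  rather than the exact test; the test suite shows by exhaustive sweep
  (n ≤ 50) that within the chi-square's applicability region the two
  agree on pass/fail at 1e-4 except when both p-values sit in the
  immediate neighbourhood of the threshold — outside that region (lone
  rare homozygotes) the asymptotic tail is simply not trustworthy, a
  known limitation of the chi-square filter.
* **Missing data.** Per-SNP complete case: an individual missing one SNP's
  dosage leaves only that SNP's model. Readers reject invalid values
  (dosages outside [0,2], negative times, non-binary codes) rather than
  coercing.
* **Degenerate fits.** Constant dosages raise a classed error in
  `cox_fit()` and become `status = "constant_dosage"` rows in the scan;
  non-convergent fits are flagged, never silent NaNs; in a permutation
  replicate a failed SNP simply contributes nothing to that replicate's
  maximum (counted and reported).

## Problem sizes used by the test suite

Calibration and power statements are asserted at sizes chosen to make the
suite complete in minutes while keeping binomial bands meaningful: the
family-wise calibration uses 200 null datasets of n = 1,000 with B = 500;
the nine-cohort coverage experiment uses 100 master seeds at the full
default cohort sizes; the null-uniformity check uses 1,000 single-SNP scans
of n = 400; brute-force oracle comparisons cover all tie-free fixtures with
n ≤ 8. Each statement fixes its seeds, so outcomes are reproducible.

## Known limitations

No population-stratification adjustment, no X chromosome, no multi-allelic
sites (rejected, not split), no competing risks or cause-specific
mortality, no random-effects or sample-size-weighted meta-analysis, no
adaptive permutation stopping. The simulator's LD is first-order Markov;
statistics that depend on long-range LD patterns beyond adjacent-pair decay
are outside what passing tests demonstrate.
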