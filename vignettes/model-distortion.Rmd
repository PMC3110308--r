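---
title: "Disease model distortion under linkage disequilibrium: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease model distortion under linkage disequilibrium: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distortgwas)
```

## The problem

Genome-wide association studies detect disease loci indirectly: the SNP
that lights up in a scan is usually a *marker* in linkage disequilibrium
(LD) with the causal variant, not the causal variant itself.  The disease
model inferred at the marker is therefore a distorted image of the truth.
This package quantifies that distortion and its consequences for power,
and provides a simulation engine to study how it plays out in a realistic
scan–replication pipeline.

The headline structure is a pair of decay laws.  Writing $r$ for the
correlation between the allele indicators at the causal SNP $A$ and the
marker SNP $B$,

* the **additive** (per-allele, log-scale) effect observed at the marker
  decays *linearly* in $r$, so power to detect association decays with
  $r^2$ and a marker study needs roughly $N/r^2$ samples;
* the **dominance** effect (heterozygote-specific deviation from the
  multiplicative model) decays *quadratically* in $r$, so power to detect
  a departure from multiplicativity decays with $r^4$ and a marker study
  needs roughly $N/r^4$ samples;
* a **two-SNP interaction** effect observed at two tag SNPs decays as the
  product $r r'$ of the per-locus correlations: sample size $N/(rr')^2$.

Because dominance and interaction decay faster than the additive effect,
LD pushes every observed model toward the multiplicative one.

## Models and parameterization

**LD model.**  Two biallelic SNPs with allele-1 frequencies $f_A$, $f_B$
and allelic correlation $r$ fully determine the four haplotype
probabilities via $p_{11} = f_A f_B + r\sqrt{f_A(1-f_A)f_B(1-f_B)}$ and
the marginals.  The feasible range of $r$ (`r_bounds()`) follows from
$\max(0, f_A+f_B-1) \le p_{11} \le \min(f_A, f_B)$; $r = 1$ requires
$f_A = f_B$, and strong negative correlation requires both frequencies
large.  The conditional probabilities $q_1 = \Pr(A{=}1 \mid B{=}1)$ and
$q_0 = \Pr(A{=}1 \mid B{=}0)$ satisfy
$q_1 - q_0 = r\sqrt{f_A(1-f_A)/(f_B(1-f_B))}$; this difference
$c = q_1 - q_0$ (equal to $r$ when $f_A = f_B$) is the mixing factor in
every distortion result.  Diplotypes assume Hardy–Weinberg equilibrium
for haplotypes; the double heterozygote sums its two phase
configurations.

**Disease models.**  Single-SNP risks follow the log-risk regression
$\log p(G) = \mu + \beta G + \gamma\,1\{G=1\}$: $\gamma = 0$ is
multiplicative, $\gamma = \beta$ dominant, $\gamma = -\beta$ recessive.
Simulation scenarios are indexed by the homozygous relative risk, with
$\beta = \tfrac12\log(\mathrm{RR_{hom}})$.  The two-SNP interaction model
attaches $\exp(\mu + a\beta_1 + a'\beta_2 + aa'\tau)$ to a haplotype with
alleles $(a, a')$; $\tau$ is the single interaction parameter.  The
log-risk link is used for all penetrance algebra because a case-control
analysis with *cohort* (population) controls by logistic regression is
equivalent to fitting the log-risk model; the finite-sample tests
themselves use the logistic link, and at low prevalence the per-allele
odds ratio and relative risk agree within a couple of percent.  The
baseline $\mu$ is not identifiable from case-control data; it defaults to
$\log(0.01)$ purely so that penetrances are well defined, and every
quantity of interest is free of it.

**Distortion.**  Marker penetrances are the conditional mixture
$p_B(g) = \sum_{g_A} \Pr(G_A = g_A \mid G_B = g)\, p_A(g_A)$ — computed
at genotype level via the diplotype conditional law for single-SNP
models, and at haplotype level (a 2×2 two-sided mixture
$P_B = M^\top P_A M'$) for the interaction model, where the
multiplicative-across-haplotypes structure makes the haplotype setting
exact.  Two identities are exact at all effect sizes, not just
asymptotically:

* $p_{B2} - 2p_{B1} + p_{B0} = c^2 (p_{A2} - 2p_{A1} + p_{A0})$
  (second-difference law behind the quadratic dominance decay);
* $\det P_B = c\,c'\,\det P_A$ (determinant law behind the interaction
  decay).

Both are verified to $10^{-12}$ over 1,000 random scenarios in the test
suite.  The general model is saturated for a single SNP, so the exact
marker parameters are recovered by inversion:
$\mu_B = \log p_{B0}$, $\beta_B = \tfrac12\log(p_{B2}/p_{B0})$,
$\gamma_B = \log p_{B1} - \mu_B - \beta_B$.  The small-effect
approximations are $\beta_B \approx c\beta_A$ and
$\gamma_B \approx c^2\gamma_A$.  One caveat found while validating them:
the linear $\beta$ law is derived for multiplicative truths; under a
dominant/recessive truth the marker's additive parameter absorbs a
same-order dominance contribution, approximately
$c(1-q_0-q_1)\gamma_A$, so the naive $c\beta_A$ is a few percent off for
those models even at homozygous RR $1.1^2$.  Similarly, the $r^4$ ratio
of deviation-test noncentralities carries a first-order-in-effect
residual that grows as $r$ falls (≈3% at RR $1.05^2$, $r = 0.5$) and
vanishes as effects shrink; the tests check the laws at effect sizes
where each statement holds.

**Effective additive parameter $\beta'$.**  GWAS scans fit the
multiplicative model regardless of the truth.  The population-limit
additive coefficient of that misspecified fit is computed by weighted
logistic regression on the *theoretical* genotype frequencies treated as
fractional counts — cases $\propto \Pr(G)p(G)$, controls the cohort
frequencies, weighted $\phi : 1-\phi$ — maximizing the weighted
likelihood directly without integer rounding.  With cohort controls this
makes $\beta' = \beta$ *exact* for multiplicative truths at every risk
allele frequency (verified to $10^{-8}$ on a frequency grid), and for
dominant/recessive truths the frequency-extreme limits are zero effect
or double the matched multiplicative effect.

## Power theory

Each test (trend, deviation, interaction) is treated as a 1-df Wald test
in the corresponding logistic model, with noncentrality
$\eta = N\theta^2/v$: $\theta$ is the population-limit value of the
tested parameter (for the trend test under a non-multiplicative truth,
$\beta'$), and $v$ is the per-individual asymptotic variance of its
estimator, taken from the inverse expected Fisher information of the
logistic fit at the exact case/control cell frequencies with nuisance
parameters profiled out.  Case cells are $\propto \Pr(G)p(G)$; control
cells are cohort frequencies (consistent with the $\beta'$ convention).
For the interaction test the computation works per haplotype (risk
factorizes over an individual's two haplotypes, so case ascertainment
preserves haplotype independence), with $2N$ observations over the four
allele-pair classes.  Power is the noncentral $\chi^2$ tail above the
central quantile.  This construction is validated three ways in the test
suite: a Monte-Carlo oracle (mean Wald statistic ≈ df + NCP across a
grid of models and frequencies), recovery of the three sample-size laws
as log–log regression slopes ($2.00$, $4.00$, $-2.00$ within the stated
bands), and the simulation bridge described below.

Equal case/control numbers ($\phi = 0.5$) are the default throughout;
$\phi$ is exposed because varying it changes results only mildly
compared with allele frequency.

## The simulation engine

`run_study()` reproduces the ascertainment pipeline of a reported GWAS
association: scan 2,000 cases and 2,000 controls at all chip SNPs with
the trend test; take the *hit* SNP (smallest p-value; ties broken by
lowest index and flagged); require $p < 10^{-6}$; replicate at the hit
SNP only with a fresh 2,000 + 2,000 sample and require $p < 0.01$; then
apply the deviation test to the replication counts at level $0.05$.
Outcomes are three-way: undetected, association only, association plus
deviation.  Controls are haplotype pairs drawn uniformly without
replacement; case genotypes at the causal SNP are drawn with
probabilities $\propto (1-f)^2,\ 2f(1-f)\alpha_1,\ f^2\alpha_2$ and then
realized as uniform draws among consistent haplotype pairs.  A study
consumes panel haplotypes without reuse (cases first, then controls;
replication excludes the scan's draws); the panel is restored between
studies.  Replication tables where the general model is unfittable
(empty cells) count as showing no deviation and are flagged — no
continuity correction is applied, since any correction would change the
test's size.  `run_experiment()` presumes each allele of each SNP causal
in turn, derives per-study seeds reproducibly from one master seed, and
aggregates outcome percentages and the deviation rate among detected
associations, overall and within $r^2$ bins of width 0.1.

**Synthetic panels.**  `generate_panel()` draws haplotypes i.i.d. from a
first-order Markov chain across SNPs, with adjacent correlation targeted
at $e^{-d/\lambda}$ (inter-SNP distance $d$, decay scale $\lambda$,
default 50 kb) and clipped into the feasible range for the adjacent
frequencies; for binary Markov chains correlations multiply, so pairwise
LD decays approximately exponentially in distance.  Target minor allele
frequencies come from a rare-skewed Beta(0.35, 1) spectrum truncated at
0.01 and are organized into haplotype-block-like runs (a SNP continues
the previous target frequency with probability $e^{-d/\lambda}$) —
necessary because near-perfect LD is only feasible between
frequency-matched SNPs, exactly as in real panels.  A mosaic/copying
construction was considered instead, but with independently assigned
ancestral alleles segment sharing alone produces essentially no LD;
the Markov construction gives directly tunable, analytically transparent
decay and i.i.d. haplotypes, which keeps without-replacement sampling
clean.  The chip mask keeps SNPs with realized MAF ≥ 0.05 independently
with probability 0.5, emulating array thinning; whether the causal SNP
may sit on the chip is configurable per experiment
(`causal_on_chip`), since scans differ in whether the causal variant is
typed.  With the defaults (40,000 haplotypes, 250 SNPs per Mb), mean
pairwise $r^2$ runs ≈0.5–0.7 within 10 kb and reaches noise level past
100 kb.

**What the generator does and does not emulate.**  It reproduces a
rare-skewed frequency spectrum, distance-decaying LD with
near-perfect-LD blocks, and chip thinning — the features the pipeline's
behavior depends on.  It does not reproduce empirical human LD in
detail: no recombination hotspots, no mutation-age/frequency
correlation, no population structure, and haplotype blocks here are
first-order Markov rather than coalescent.  Consequently the absolute
outcome percentages of a full experiment (detection rates per
homozygous RR) are properties of these synthetic conditions, not
predictions for any real chip or population, and published
empirical-panel percentages are not comparable targets.  What *is*
expected to transfer, and what the tests assert, is the calibration and
shape of the results: the deviation rate among detected associations
sits at the nominal 5% under multiplicative truth (the ascertainment
cascade does not inflate the test), and under dominant truth the
deviation rate among detected associations falls as the hit-to-causal
$r^2$ falls.

## Numerical choices

* Probability cells within $10^{-12}$ of $[0, 1]$ are clamped;
  larger violations raise errors — infeasible LD is never silently
  clipped.
* Weighted logistic fits run to an IRLS tolerance of $10^{-14}$
  (population-limit quantities) or $10^{-12}$ (count-table fits);
  estimates with $|\hat\theta| > 30$ or non-converged fits raise a
  classed error (`distortgwas_fit_error`) so pipeline callers can treat
  a replicate as unfittable rather than absorb a spurious value.
* The trend test returns statistic 0 (p = 1) on tables with zero score
  variance: a monomorphic SNP carries no evidence either way.
* Monomorphic causal SNPs or exhausted haplotype classes raise a classed
  sampling error; `run_experiment()` records such studies as `failed`
  and excludes them from outcome denominators.
* P-values are upper chi-square tails throughout; the deviation and
  interaction tests are Wald by default with likelihood-ratio variants
  available as cross-checks (the two agree to $O(1/N)$).

## Problem sizes used in the checks

The shipped checks run at desk scale, chosen to keep Monte-Carlo
standard errors small relative to the bands they certify: the calibration
experiment uses one 40,000-haplotype, 800-SNP panel (1,600 studies,
giving ≥300 detected associations under multiplicative RR $1.4^2$); the
theory↔simulation bridge uses bespoke two-SNP panels of 200,000
haplotypes with 800–1,500 replicates per setting, including the $N/r^4$
equivalence at RR $1.1^2$, $r = 0.9$; identity checks use 1,000 random
scenarios each.

## Known limitations

* Allele frequencies must be strictly inside $(0, 1)$; fixation is not
  modeled.
* The interaction machinery covers the single-$\tau$ haplotype model
  only, and its finite-sample test uses the genotype product coding;
  general 3×3 epistasis is out of scope.
* No covariates, genotyping error, imputation dosages, or phase
  uncertainty.
* The trend-scan ascertainment is the only scan model; scanning with the
  2-df general test would change which loci are ascertained (it is
  available as `general_test()` for count tables, but the pipeline does
  not use it).
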