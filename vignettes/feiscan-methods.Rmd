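---
title: "Mixed-model analysis of baseline FVIII-inhibitor status: models and methods"
author: "feiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model analysis of baseline FVIII-inhibitor status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feiscan)
```

## The scientific problem

About 30% of severe hemophilia-A patients treated with therapeutic FVIII
develop neutralizing anti-FVIII alloantibodies ("inhibitors"). Genetic
analysis of inhibitor status in such cohorts faces two sources of
non-independence that ordinary regression ignores:

1. **Genetic relatedness.** Hemophilia cohorts recruited through treatment
   centers are enriched for relatives (brothers, cousins, uncle–nephew
   pairs); on the order of a third of subjects may have a close relative
   in-sample.
2. **Causative-mutation heterogeneity.** The F8 lesions causing the disease
   are highly heterogeneous (recurrent intron-22 inversions alongside dozens
   of distinct missense substitutions), and mutation type is itself a strong
   determinant of inhibitor risk. Subjects carrying the identical lesion
   share a risk component that is neither a fixed covariate nor ordinary
   polygenic background.

`feiscan` implements a binary linear mixed model with **two structured
random effects** that absorb both sources:

$$ y_i = a + b'x_i + g_i + m_i + e_i, $$

with $y_i$ the 0/1 baseline-inhibitor status, $x_i$ fixed covariates (race
by default), and

$$ g \sim N(0, \sigma^2_g K), \quad m \sim N(0, \sigma^2_m M), \quad
   e \sim N(0, \sigma^2_e I). $$

$K$ is an empirical genomic relationship matrix (GRM) or a pedigree-derived
additive relationship matrix; $M$ is the **shared-causative-mutation
matrix**, an indicator covariance with $M_{ij} = 1$ when subjects $i$ and
$j$ carry the same lesion.

## The structured covariances

**GRM.** `computeGRM()` uses the per-marker-standardized estimator
$K_{ij} = L^{-1}\sum_l (g_{il}-2p_l)(g_{jl}-2p_l) / (2p_l(1-p_l))$ over the
markers passing the configurable QC filters (default minimum MAF 0.01,
maximum missing rate 0.05; the exact QC of the motivating study is not
public, so the filters are exposed as parameters rather than fixed).
Missing dosages are mean-imputed to $2p_l$, which contributes exactly zero
to the centered cross-products. The estimator is invariant to swapping the
counted and other allele.

**Mutation sharing.** `mutationSharingMatrix()` offers two granularities.
The default is `allele` (identical lesion), because recurrent bi-allelic
intron-22 inversions and allelically diverse missense substitutions behave
very differently; `category` (same broad lesion class) is retained as an
option. Subjects whose lesion could not be identified are given per-subject
unique tokens at either granularity: their lesions are unknown and almost
surely distinct, so a shared "not identified" block would fabricate
covariance. $M$ is a union of disjoint blocks of ones, hence positive
semi-definite with eigenvalues equal to the block sizes.

**Pedigree kinship.** `pedigreeKinship()` implements the recursive tabular
method (entries are twice the kinship coefficient). It is the ground truth
for the simulator and the validation target for the empirical GRM: on
gene-dropped genotypes the GRM converges to it in mean absolute error as
the marker count grows.

## REML fitting and its numerical choices

`fitVC()` maximizes the restricted likelihood of
$V = \sigma^2_g K + \sigma^2_m M + \sigma^2_e I$ by L-BFGS-B over the
box-constrained components ($\sigma^2 \ge 0$; no negative-component
interior estimates), with analytic gradients and four deterministic
restarts from spread variance splits (equal split, residual-heavy,
first-component-heavy, balanced-heavy), converging at a relative
log-likelihood tolerance of 1e-8. The restricted log-likelihood follows
Harville's error-contrast form (including the $-\tfrac12\log|X'X|$
constant), so it agrees exactly with the likelihood of any orthonormal
error-contrast basis — the test suite exploits this with an independent
contrast-based oracle and a brute-force grid search. Fixed effects are GLS
estimates at the optimum. Degenerate inputs are refused early: non-PSD
components (minimum eigenvalue below $-10^{-6}$), rank-deficient covariates,
and proportional components (e.g. $K = M = I$, under which the variance
split is unidentifiable) all raise errors rather than returning arbitrary
splits.

Variance-component hypotheses sit on the boundary of the parameter space,
so `lrtVarComp()` refers $\Lambda = 2(\ell_{full}-\ell_{reduced})$, clipped
at zero, to the 50:50 mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$:
$p = \tfrac12\Pr(\chi^2_1 \ge \Lambda)$, so $\Lambda = 0$ gives $p = 0.5$
and $\Lambda = 2.706$ gives $p = 0.05$.

### The observed scale and the liability scale

The binary trait is fitted by Gaussian REML on the observed 0/1 scale.
This is deliberate: the exact binary-trait likelihood of pedigree packages
such as SOLAR is not publicly specified in enough detail to reproduce, the
observed-scale LMM is well-defined and testable, and it supports the same
variance partition. `heritabilityPartition()` labels the scale explicitly
and offers the Dempster–Lerner conversion
$h^2_{liab} = h^2_{obs}\, p(1-p)/z^2$ (`observedToLiability()`), with $p$
the prevalence and $z$ the standard-normal density at the threshold. The
mutation share of total heritability, $h^2_m / (h^2_m + h^2_g)$, is a ratio
and therefore scale-invariant; with components 0.08 and 0.47 it is 0.145,
i.e. ~15% at whole-percent rounding.

## The gene-centric association scan

`scanAssociation()` tests each QC-passed SNP as a fixed effect with the
covariates always included. The default mode holds $\hat V$ at the
null-model REML estimates and computes the GLS slope and Wald z per SNP
(the standard fast approximation in mixed-model association); `full_lrt`
refits per SNP by ML and uses $\chi^2_1$. The two agree asymptotically —
the suite checks 20% relative agreement for $|z| < 4$ at $n = 400$. The
counted allele is re-oriented to the combined-sample minor allele (per-race
MAFs are recorded, since ancestry-restricted variants can flip major and
minor allele between groups). Monomorphic and covariate-collinear markers
are skipped with logged reasons.

Thresholds follow `bonferroniNeglog10(alpha, n)` $= -\log_{10}(\alpha/n)$,
rounded half-up to two decimals for reporting: 6.44 chip-wide for 137,776
tests at $\alpha = 0.05$, and 3.76 / 3.75 / 3.86 for genes with 287 / 281 /
362 assigned SNPs. `flagSignificant()` uses strict inequality: a SNP sitting
exactly on a threshold is **not** significant (documented tie rule).

Calibration of the Wald scan is assessed on common variants
(permuted-phenotype nulls, rejection rate within the binomial 95% CI of
0.05). For rare variants with a handful of carriers the Wald test is
conservative at these sample sizes — a known small-sample property, left
uncorrected and documented here.

## Joint logistic models and model selection

`fitLogistic()` is maximum likelihood via IRLS with Wald 95% CIs
exponentiated to OR intervals; on a saturated 2×2 design it reproduces the
cross-product odds ratio exactly. Perfect separation is detected (diverging
estimates) and reported as an error naming the offending term rather than
returning meaningless CIs. "Bayesian model selection" over race×SNP
interactions is realized as exhaustive BIC comparison
($\mathrm{BIC} = -2\ell + k\ln n$, the standard Bayes-factor
approximation): all $2^k$ interaction subsets are fitted with main effects
always retained, and the minimum-BIC model is reported with the full table.
`fishersMethod()` combines $k$ p-values via $-2\sum\ln p_i \sim \chi^2_{2k}$.
On the pair (0.06, 0.14) the closed form gives 0.0485 — notably smaller
than either input, a combination the package reports as computed.

## What the synthetic cohorts emulate

`simulateCohort()` generates the study conditions the analysis assumes,
with defaults calibrated to the motivating cohort's published margins:

* 450 males in two ancestry groups (BA 206/450, WE 244/450), assigned per
  family;
* family units mixed so ~31% of subjects have a close relative in-sample
  (full-sib and avuncular pairs; the 31% figure comes from a comparable
  multi-center cohort and is used only as a default);
* founder allele frequencies drawn per ancestry from a Balding–Nichols
  model around a shared ancestral frequency (default $F_{st} = 0.1$), plus
  a 10% fraction of ancestry-restricted markers (common in one group, rare
  below 0.01 in the other); genotypes descend by Mendelian gene-dropping;
* causative-mutation categories drawn per family (relatives share the
  familial lesion): intron-22 inversions 0.416 sharing the single recurrent
  allele, missense 0.216 drawn from 61 distinct alleles, unidentified 0.098
  with subject-unique tokens, remaining mass uniform over the other
  categories (their exact published counts are not printed in text, so the
  uniform split is a documented calibration, not a reported spectrum);
* a liability $\ell = \beta_{race}\mathbb{1}(WE) + g + m + e$ with
  liability-scale components $\sigma^2_g = 0.47$, $\sigma^2_m = 0.08$,
  $\sigma^2_e = 0.45$ and $\beta_{race} = -0.21$ (the gap between per-race
  prevalences 21.5% and 15.9% in threshold units), thresholded at the
  upper-0.185 quantile of the theoretical marginal distribution (normal
  approximation including the between-race variance of the fixed part), so
  prevalence is matched in expectation — 0.185 is the pooled value implied
  by the per-race rates, since no overall rate is published;
* $m$ is built by drawing one $N(0, \sigma^2_m)$ effect per distinct allele
  and assigning it to carriers, so $\mathrm{cov}(m) = \sigma^2_m M$ holds
  exactly, and $g \sim N(0, \sigma^2_g K_{ped})$ by construction — both
  verified by Monte-Carlo covariance checks in the suite.

Everything is deterministic given `(params, seed)`.

The generator deliberately omits LD between markers, admixture/continuous
ancestry, genotyping error, and X-linked transmission of the marker panel
(the F8 lesion itself is X-linked, modeled only as "relatives share the
familial lesion"; markers are treated as autosomal-diploid, as on the
ImmunoChip autosomes). Passing tests therefore demonstrate statistical
correctness of the machinery under the stated generative model, not
robustness to those real-data features.

## Calibration scale of the recovery experiment

The headline recovery experiment (also recomputed by
`scripts/acceptance.R`) fits the two-component REML model on 40 replicate
default cohorts and averages the per-component heritabilities. The fit uses
the latent liability retained by the generator, because the generating
components (0.47 / 0.08 / 0.45) are liability-scale parameters: on that
scale the REML means are unbiased (measured 0.47 / 0.08 with per-replicate
SDs 0.22 / 0.06). Fitting the observed 0/1 trait instead and converting by
the Dempster–Lerner factor is supported, but at this design's information
content (~70 informative relative pairs per cohort) the per-replicate
liability-scale SD is ~0.5 and the non-negativity constraint truncates the
sampling distribution at zero, biasing the *mean* of converted estimates
upward by ~0.15; a mean-recovery criterion is not a fair test of that
chain, while per-replicate inference (the package's primary analysis path)
remains valid and is exercised throughout the suite.

Problem sizes used by the suite — 40 replicates at $n = 450$ for recovery,
$n = 200$ with 500 common SNPs for scan calibration, 120 subjects × 5,000
markers for GRM convergence, 2,000 Monte-Carlo draws for the covariance
identities — were chosen as the smallest designs at which the measured
Monte-Carlo error is comfortably inside each tolerance.

## Known limitations

* No generalized (probit/logit) random-effect integration; the binary trait
  is modeled on the observed scale with post-hoc conversion.
* At most two structured components plus residual are intended; the code
  accepts more but identifiability degrades quickly.
* Wald scan p-values are conservative for very rare variants.
* Whether the motivating study's mutation matrix encoded shared allele,
  shared category, or a graded similarity is not stated in its main text;
  both discrete options are implemented and neither is asserted as the
  original's.
* The BIC subset search enumerates at most $2^{12}$ models.
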