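---
title: "Allele-aware analysis of germline-targeting vaccine priming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-aware analysis of germline-targeting vaccine priming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleleprime)
library(dplyr)
```

## The scientific problem

Germline-targeting immunogens aim to activate the rare naive B cells whose
receptors can mature into broadly neutralizing antibodies. For VRC01-class
precursors the heavy chain must come from IGHV1-2 allele \*02 or \*04;
alleles \*05 and \*06 carry a tryptophan-to-arginine change at codon 50
that abolishes binding to the immunogen. Because \*02-derived precursors
are several-fold more frequent in the naive repertoire than \*04-derived
ones, the distribution of IGHV1-2 alleles across the arms of a
dose-escalation trial can confound an apparent dose effect: if the
high-dose arm happens to be enriched for \*02 carriers, its stronger
responses may reflect genotype, not dose.

`alleleprime` implements the full analysis chain needed to untangle this:

1. **Repertoire quantification** — per-allele mRNA usage and unique-HCDR3
   frequencies from UMI-tagged IgM libraries.
2. **Response modelling** — four competing quasi-Poisson models of
   VRC01-class B cell counts, ranked by QAICc.
3. **Allele inference for BCRs** — germline allele assignment with
   ambiguity-aware 0.5/0.5 counting.
4. **Association statistics** — Fisher exact allele-by-dose tests,
   Wilcoxon comparisons, heterozygote ratio intervals, bootstrap ratios of
   means, correlations, genotype ranking.
5. **Affinity comparisons** — random-intercept linear mixed models with
   Satterthwaite degrees of freedom.
6. **A synthetic-trial generator** that emulates the statistical structure
   of such a trial so every stage is testable without participant-level
   data.

## The count model

For participant $i$ at one timepoint, let $V_i$ be the number of
VRC01-class IgG B cells among $N_i$ sampled IgG B cells, $n02_i$ and
$n04_i$ the zygosity counts (0/1/2) of the \*02 and \*04 alleles, and
$D_i$ the high-dose indicator. The four mean structures are identity-link
and intercept-free, so every coefficient is a per-cell response frequency:

$$
\begin{aligned}
\text{Null:}   \quad E(V_i) &= \beta_{\mathrm{Intercept}} N_i \\
\text{Dose:}   \quad E(V_i) &= \beta_{\mathrm{low}} N_i +
                              \beta_{\Delta} D_i N_i \\
\text{Allele:} \quad E(V_i) &= \beta_{02}\, n02_i N_i +
                              \beta_{04}\, n04_i N_i \\
\text{Full:}   \quad E(V_i) &= \beta_{02}\, n02_i N_i +
                              \beta_{04}\, n04_i N_i + \beta_{\Delta} D_i N_i
\end{aligned}
$$

with quasi-Poisson variance $\mathrm{Var}(V_i) = \hat{c}\, E(V_i)$.
Additivity in allele copies is the key mechanistic assumption: each allele
contributes precursors independently, so a homozygote's expected response
is twice a heterozygote's. The identity link (covariates pre-multiplied by
$N$) follows directly from these expectation formulas; a log link with an
offset would instead model multiplicative effects, which is not the stated
biology.

`fit_quasipoisson()` solves the quasi-score equations
$\sum_i x_i (V_i - \mu_i)/\mu_i = 0$ by iteratively reweighted least
squares with step-halving so that fitted means of structurally non-zero
rows stay positive. Genotypes with no productive allele (\*05/\*06) have
$\mu = 0$ under the Allele model; such rows are retained with zero
likelihood contribution when $V = 0$ and are an infeasibility error when
$V > 0$. The dispersion $\hat c$ is the Pearson statistic over
positive-mean rows divided by their count minus the number of mean
parameters, and the coefficient covariance is
$\hat c\,(X^\top W X)^{-1}$ with $W = \mathrm{diag}(1/\hat\mu)$.
Coefficients are unconstrained apart from the positive-mean requirement —
in particular the dose delta may be negative, since near-zero dose effects
with intervals spanning zero are an expected outcome.

### Model ranking by QAICc

$$\mathrm{QAICc} = \frac{-2\ln L}{\hat c} + 2K + \frac{2K(K+1)}{n-K-1}$$

where $\ln L$ is the Poisson log-likelihood at the fitted means and $K$
counts the mean parameters **plus one** for the estimated dispersion (the
standard convention; it makes rankings comparable across candidates). Two
choices the literature leaves open are exposed as options of
`rank_models()`:

* `c_hat_policy = "full"` (default): $\hat c$ estimated from the most
  general candidate (Full) and shared across all four models — standard
  QAIC practice, since a common variance scale is what makes the
  criterion comparable;
* `"per-model"`: each candidate uses its own $\hat c$.

Exact QAICc ties break in favour of fewer parameters.

### Derived quantities

* `genotype_mean()` — linear combinations $n02\,\hat\beta_{02} +
  n04\,\hat\beta_{04}$ with quadratic-form variances and normal-theory
  intervals.
* `allele_ratio()` — $\hat\beta_{02}/\hat\beta_{04}$ with the delta-method
  variance (gradient $(1/\beta_{04},\ -\beta_{02}/\beta_{04}^2)$); the
  lower confidence bound is truncated at zero because the ratio of two
  non-negative response frequencies cannot be negative.
* `allele_difference()` — the $(1,-1)$ contrast with a two-sided p-value;
  differences can be significant where ratio intervals still cross 1,
  because the ratio's variance blows up as $\hat\beta_{04}$ gets small.

## Repertoire quantification

Only rearrangement records with **zero mismatches** to the personalized
germline set are counted (records with a missing mismatch annotation are
conservatively treated as mutated). A unique UMI is one mRNA molecule;
duplicate (allele, UMI) pairs collapse. The per-allele usage frequency
divides by all unique UMIs in the library — i.e. frequency in the full
naive repertoire across IGHV genes, not within IGHV1-2. Unique HCDR3s are
counted by exact amino-acid string equality (no clustering: the analysis
counts distinct clones, not clonal families), and the unique-HCDR3
denominator is likewise all distinct HCDR3s in the library; whether a
per-gene denominator is meant instead is not fully determined by the
source analyses, so the all-IGHV convention is the documented default and
either can be computed from the returned counts.

Each participant has two independent libraries (leader and 5'UTR primer
sets); `combine_primer_sets()` averages the two frequencies per allele,
and `collapse_s4953()` folds the silent \*02_S4953 variant into \*02 by
summing frequencies. These two operations commute.

The ratio of unique-HCDR3 count to mRNA count (`ratio_diagnostics()`)
estimates the reciprocal of BCR surface density per clone; similar ratios
for \*02 and \*04 mean that usage differences reflect precursor-frequency
differences rather than expression-per-cell differences.
`zygosity_stratified_means()` compares homozygote and heterozygote usage
(total per participant by default, per allele copy with
`per_allele = TRUE`) with t intervals and a Welch t-test of zero
difference.

## BCR allele assignment

Each read is compared to the germline templates of the participant's own
genotype over a fixed-length window; the call is the allele with the
fewest mismatches (Hamming distance). For equal-length ungapped candidates
this ordering coincides with ranking alignments by e-value, which is why a
full alignment engine is not needed here; indels are assumed corrected
upstream. Exact distance ties are reported as `"ambiguous"`; a tie between
the \*02 family and \*04 — one nucleotide from both templates — is
equiprobable for either allele and contributes 0.5 to each tally.
Ambiguity involving a non-productive allele stays in an "ambiguous-other"
bucket and is excluded from the \*02:\*04 ratio. Per-participant \*02:\*04
ratios of 0 or infinity (a zero tally on either side) are reported and
flagged but excluded from the t-based interval, which is defined only for
finite ratios.

## Affinity mixed models

Equilibrium dissociation constants span picomolar to micromolar, so
affinities are analysed on the $\log_{10} K_D$ scale by default (the raw
scale is exposed via `log10_scale = FALSE`; the choice matters and is
therefore prominent). Antibodies from the same participant are correlated,
hence a participant random intercept:

$$y_{ij} = x_{ij}^\top\beta + b_i + e_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2), \quad e_{ij} \sim N(0, \sigma_e^2).$$

The random-intercept structure gives closed-form per-participant blocks of
$V^{-1}$, so REML reduces to a one-dimensional profile over
$\lambda = \sigma_b^2/\sigma_e^2$, optimized by a log-spaced grid plus
golden-section refinement with the boundary $\lambda = 0$ checked
explicitly. Fixed-effect tests use Satterthwaite's degrees-of-freedom
approximation: the contrast variance $f(\theta)$ is differentiated
numerically in $\theta = (\sigma_b^2, \sigma_e^2)$ and
$\mathrm{df} = 2 f^2 / (g^\top A g)$ with $A$ the inverse REML
information (numeric Hessian). Degenerate designs collapse to the
classical answers: with one observation per participant the fit is
ordinary least squares and the between-group test is the pooled two-sample
t-test; the paired original-vs-variant analysis with one antibody per
participant is exactly the paired t-test.

Censored non-binders (no detectable binding at the highest analyte
concentration) are excluded from the mixed models; in medians they are
treated as right-censored, so a median that lands on a censored record is
reported at the censoring limit and flagged as a lower bound.

## The synthetic-trial generator

`trial_config()` fixes the study conditions; `simulate_trial()` draws a
complete trial. What it emulates, and the defaults:

| Parameter | Default | Meaning |
|---|---|---|
| `n_per_group` | 18/18/12 | low, high, placebo group sizes |
| `allele_freqs` | .25/.02/.55/.03/.15 | population frequencies of \*02, \*02_S4953, \*04, \*05, \*06 |
| `expr_rate_per_allele` | .031/.031/.009/.0009/.024 | mRNA usage per allele copy |
| `hcdr3_ratio` | 0.23 | unique-HCDR3 per mRNA (binomial thinning) |
| `beta_02`, `beta_04` | 8e-4, 2e-4 | per-allele VRC01-class response frequency |
| `dose_delta` | 0 | additive high-dose effect |
| `dispersion` | 2 | variance inflation $\varphi$ |
| `n_total_umis` | 30000 | unique UMIs per library |
| `n_igg_sampled` | 50000 | IgG B cells per response sample ($N$) |
| `mutation_rate` | 0.01 | per-base substitution rate for BCR reads |

Design choices, made once:

* **Genotypes are Hardy–Weinberg**: two independent draws from the allele
  pool. The source data report genotype counts but no sampling model;
  exchangeable HWE sampling is the simplest model adequate for parameter
  recovery. A fixed `genotype_table` mode reproduces any observed
  genotype-by-dose imbalance exactly (e.g. 13/18 vs 5/18 \*02 carriers)
  for confounding studies.
* **Allele frequencies** are calibrated to the reported qualitative
  ordering (\*04 most common, then \*02, \*06 intermediate, \*05 rare);
  exact population counts are not printed as text in the source, so these
  are fixed representative values.
* **Over-dispersion is NB1** (variance $\varphi\mu$; Poisson at
  $\varphi = 1$, zero counts surely at $\mu = 0$), because
  quasi-Poisson specifies only the first two moments and NB1 matches the
  fitted variance function exactly in expectation.
* **HCDR3 uniqueness is binomial thinning** of the UMI count at ratio
  0.23 rather than an explicit clone-size distribution: it reproduces the
  count-ratio statistic the analysis uses without modelling clonality.
* **Response betas** 8e-4 / 2e-4 encode the roughly four-fold \*02:\*04
  precursor-frequency advantage and give a heterozygote response
  frequency of 0.1%, in the range of reported memory-compartment medians.
  $N$ per sample is not reported in the source and is configurable.
* **BCR reads** are template copies with independent per-base
  substitution; origin is proportional to zygosity by default (an
  `origin_probs` argument allows, e.g., precursor-frequency-proportional
  origins). The synthetic germline templates are *not* real IGHV1-2
  sequences — they are a fixed synthetic scaffold carrying the structure
  that matters: a single diagnostic A/T difference between \*04 and \*02,
  a silent \*02_S4953 variant, and extra fixed differences for \*05/\*06.

What the generator does **not** emulate: somatic hypermutation and
class-switching, clone-size distributions, light chains, indels and
sequencing artefacts, participant-level covariates (age, sex, immune
history) that the real data's unexplained heterogeneity reflects, and any
true dose effect unless `dose_delta` is set. Passing recovery tests on
this generator therefore demonstrates correctness of the estimators under
the model's own assumptions — not robustness to the ways real repertoire
data violate them.

## Numerical choices

* IRLS: relative-change convergence at 1e-12, max 200 iterations,
  step-halving to keep $\mu > 0$, fitted means floored at 1e-8 inside the
  weights; a Moore–Penrose fallback handles near-singular steps.
* REML profile: grid $\{0\} \cup 10^{[-6,6]}$ (121 points) then
  `optimize()` in the bracketing interval; the boundary fit
  $\sigma_b^2 = 0$ wins whenever its criterion is no worse.
* Satterthwaite: central finite differences with steps
  $10^{-5}\,|\theta|$; if the information matrix is singular (boundary
  fits) the df fall back to the residual df, which is the exact answer in
  the collapse cases.
* Half-up rounding in `estimate_v()` (`floor(x + 0.5)`), not banker's
  rounding, so counts like 10.5 round to 11. The underlying definition of
  the estimated count is frequency × sampled IgG B cells.
* Exact Wilcoxon enumeration for combined $n \le 20$ without ties; tie
  correction in the normal approximation otherwise. Exact permutation
  correlations enumerate all $n!$ orderings for $n \le 8$ and use seeded
  random permutations with an add-one correction above that.
* The bootstrap p-value inverts the percentile interval:
  $p = 2\min(P(r^* \le 1), P(r^* \ge 1))$, capped at 1 — a documented
  convention, since only the interval construction is prescribed by the
  source analyses.

## Problem sizes used in validation

The test suite and acceptance script run: 500 simulated trials of
$n = 36$ vaccinees at dispersion 2 for coefficient recovery and interval
coverage; 200 replicates per size at $n = 36/360/3600$ for QAICc
selection consistency; 100,000 multivariate-normal coefficient draws for
the delta-method/bootstrap comparison; 10,000 reads for the assignment
oracle; and B = 2000–10,000 bootstrap resamples. These sizes give
Monte-Carlo errors comfortably below the tolerances being asserted.

## Known limitations

* The quasi-Poisson intervals are normal-theory; at very small $n$ with
  estimated dispersion they run a little below nominal (the recovery study
  observes ~94–95% for nominal 95%).
* The percentile bootstrap for ratios of means undercovers slightly at
  $n = 10$ per group (~92% for nominal 95%), a known small-sample
  property of percentile intervals rather than an implementation issue.
* The assignment surrogate scores substitutions only; reads with
  uncorrected indels would need realignment upstream.
* `wilcoxon_rank_sum()` falls back to the normal approximation whenever
  ties are present, including small samples where an exact conditional
  test exists.
* The LME assumes a single level of clustering (participant); antibody
  lineage effects within participant are not modelled.
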