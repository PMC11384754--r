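# alleleprime

Allele-aware analysis of germline-targeting vaccine priming.

## The problem

Germline-targeting immunogens are designed to activate the rare naive B
cells that can mature into broadly neutralizing antibodies. For the
VRC01 class of HIV bnAb precursors the heavy chain must use IGHV1-2
allele \*02 or \*04; alleles \*05/\*06 carry a codon-50 change (W50R)
that abolishes precursor binding. Since \*02-using precursors are roughly
four-fold more frequent in the naive repertoire than \*04-using ones, an
uneven distribution of IGHV1-2 alleles between the arms of a
dose-escalation trial can masquerade as a dose effect. Disentangling
genotype from dose requires per-participant repertoire quantification,
count models with additive allele effects, allele-resolved BCR analysis,
and repeated-measures affinity comparisons — the pipeline this package
provides, for statisticians and immunologists analysing
immunoglobulin-genotyped vaccine trials.

## The models at its core

**Response counts.** For a participant with `n02`/`n04` copies of the
\*02/\*04 alleles, `V` VRC01-class IgG B cells among `N` sampled, and
high-dose indicator `D`, four competing identity-link quasi-Poisson mean
structures are fitted per timepoint and ranked by QAICc:

    Null:    E(V) = b_Intercept * N
    Dose:    E(V) = b_low * N + b_delta * D * N
    Allele:  E(V) = b_02 * n02 * N + b_04 * n04 * N
    Full:    E(V) = b_02 * n02 * N + b_04 * n04 * N + b_delta * D * N

with Var(V) = c_hat * E(V), coefficients estimated by quasi-likelihood
(IRLS on the quasi-score), and

    QAICc = -2 lnL / c_hat + 2K + 2K(K+1)/(n - K - 1),

K counting the mean parameters plus one for the dispersion. Derived
quantities: genotype means (linear combinations with quadratic-form
variances), the \*02:\*04 per-allele ratio with a delta-method interval
truncated at zero, and the \*02 − \*04 difference.

**Repertoire usage.** Per-allele mRNA usage = unique UMIs with zero
germline mismatches for that allele / all unique UMIs in the library;
unique-HCDR3 frequencies analogously; two primer-set libraries averaged;
the silent \*02_S4953 variant folded into \*02.

**BCR allele assignment.** Minimal Hamming distance against the
participant's own germline alleles over a fixed window; exact ties are
"ambiguous" and \*02/\*04 ties count 0.5 to each.

**Affinities.** log10(K_D) compared between allele groups (or matched
original/variant antibody pairs) with a participant random intercept,
fitted by profile REML, tested with Satterthwaite degrees of freedom.

A synthetic-trial generator (`trial_config()` + `simulate_trial()`)
reproduces the statistical structure of a two-dose trial — Hardy-Weinberg
genotypes, zygosity-proportional allele usage, binomial HCDR3 thinning,
NB1 over-dispersed response counts, single-SNP-distinguished germline
templates — so the whole pipeline is testable end to end.

## Worked example

```r
library(alleleprime)
library(dplyr)

cfg   <- trial_config(n_per_group = c(18, 18, 12), seed = 42)
trial <- simulate_trial(cfg)

# per-allele naive-repertoire usage, homozygotes reported per allele copy
usage <- quantify_repertoires(trial$repertoire)
zygosity_stratified_means(usage, trial$participants, per_allele = TRUE) |>
  filter(allele %in% c("*02", "*04")) |>
  select(allele, group, n, mean, ci_lower, ci_upper)
#>   allele group            n    mean ci_lower ci_upper
#> 1 *02    heterozygous    23 0.0309   0.0306   0.0313
#> 2 *02    homozygous       2 0.0307   0.0272   0.0341
#> 3 *04    heterozygous    22 0.00907  0.00890  0.00924
#> 4 *04    homozygous      13 0.00897  0.00877  0.00918
```

Per-allele usage is ~3.1% for \*02 and ~0.9% for \*04 regardless of
zygosity — usage proportional to allele copies, \*02 about 3.4-fold above
\*04.

```r
m <- model_all_timepoints(trial$responses)
m$ranking |> filter(compartment == "MBC", week == 4)
#>   compartment  week model      K c_hat_used loglik QAICc delta_QAICc
#> 1 MBC             4 Allele     3       1.51  -113.  156.        0
#> 2 MBC             4 Full       4       1.51  -113.  158.        1.96
#> 3 MBC             4 Dose       3       1.51  -309.  414.      258.
#> 4 MBC             4 Null       2       1.51  -311.  415.      259.
```

The Allele model ranks first: allele content explains the counts, and
adding a dose term (Full) buys no fit. The per-allele contribution ratio:

```r
allele_ratio(m$fits[["MBC_wk4"]]$Allele)
#>   estimate    se conf.low conf.high truncated
#> 1     3.68 0.358     2.98      4.39 FALSE
```

i.e. each \*02 allele contributes ~3.7x the VRC01-class response
frequency of a \*04 allele (this trial was simulated with a four-fold
true ratio and no dose effect). `genotype_mean()`, `allele_difference()`,
`assign_allele()` / `tally_assignments()` / `per_participant_ratio()`,
`fisher_exact_2x2()`, `bootstrap_ratio_of_means()`,
`fit_between_group_lme()` and `fit_paired_variant_lme()` cover the rest
of the analysis; `plot_allele_usage()`, `plot_model_ranking()`,
`plot_genotype_means()` and `plot_affinities()` draw the standard
displays.

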