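---
title: "Models and methods behind lampreykin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lampreykin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lampreykin analyses the reproductive ecology of larval sea lamprey
(*Petromyzon marinus*) cohorts from RAD-capture SNP genotypes: who bred,
how unequally, how many effective breeders there were, and whether sibling
larvae cluster in space. This vignette explains the models, the defaults
and their units, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The breeding-matrix simulator

A spawning event is modelled as a females x males matrix of expected
offspring counts. For a pool of `n_parents` adults:

1. The males-per-female ratio is drawn uniform on [1, 2] and the pool is
   split with `n_females = round(n_parents / (1 + ratio))` (round-half-even,
   floor of one per sex). The rounding rule is a package choice; any
   deterministic rule preserving both sexes would do.
2. Each female draws a mate number from Poisson(lambda = 3), truncated
   below at 1 (an unmated female would simply not appear in the matrix)
   and above at the number of males (sampling mates without replacement
   requires it; this bites only in 10-parent pools). Mates are chosen
   uniformly without replacement.
3. Her fecundity is uniform on [25,000, 100,000] eggs and is allocated to
   her mates in the descending triangular proportions
   `n : n-1 : ... : 1` over `n(n+1)/2`. Which mate receives the largest
   share is randomised — the allocation schedule fixes the shares, not
   their recipients.
4. Males left without any mate then repeat the procedure in mirrored form
   (own fecundity, female partners), so the realised sex ratio of the
   matrix is exactly the drawn split.

Cell values stay real-valued; integerisation happens only when offspring
are sampled, multinomially with probabilities proportional to expected
counts. This preserves the triangular ratios exactly and avoids rounding
bias. Offspring names embed the true parent pair, so inferred
relationships can always be scored against truth.

One accounting subtlety: the calibration statistics "mates per female ~3,
mates per male ~2" refer to the primary mating round. Counting positive
cells of the final matrix instead would add the remated males' pairings
(about `3 e^{-3/r}` extra matings per capita at ratio `r`) and push both
means above those values; `mate_counts()` therefore reports the primary
round by default and offers `round = "realized"`.

## Pairwise dyad likelihood

Relationships are classified per unordered pair (dyad) of offspring as
full-sib (FS), half-sib (HS) or unrelated (U), the three relationships
being characterised by their Cotterman IBD coefficients
`(k0, k1, k2)`: FS `(1/4, 1/2, 1/4)`, HS `(1/2, 1/2, 0)`, U `(1, 0, 0)`.
At a biallelic locus with ALT frequency `p`, the joint probability of an
observed genotype pair is

```
P(g1, g2 | R) = k0 P0(g1, g2) + k1 P1(g1, g2) + k2 P2(g1, g2)
```

where `P0` is the product of Hardy-Weinberg genotype probabilities, `P2`
is the diagonal HWE table, and `P1` is the one-allele-shared table
(`q^3`, `q^2 p`, `pq`, `p^2 q`, `p^3` in its non-zero cells). Genotyping
error with rate `epsilon` enters as a contamination mixture — with
probability `epsilon` an observed genotype is an independent HWE draw —
which collapses to

```
P_obs = (1 - eps)^2 P(g1, g2 | R) + (1 - (1 - eps)^2) P_HWE(g1) P_HWE(g2)
```

because every IBD table has HWE marginals. Log-likelihoods sum over
jointly called loci; dyads sharing fewer than `min_shared_loci`
(default 100, the smallest panel size the power study evaluates) are left
uncalled. Classification is maximum likelihood with equal priors; exact
ties break toward the less related label (U over HS over FS), a
conservative choice against false kin. The unit tests verify the
implementation against brute-force enumeration over parental genotypes to
1e-12 relative error.

This pairwise composite likelihood deliberately replaces a joint
full-likelihood sibship partition (as in dedicated pedigree software):
the quantities of interest here — per-class dyad accuracy and
false-negative rate, family groups, parent counts — are all functions of
dyads, and a pairwise engine is transparent, fast and fully testable
in-package. It is a methodological substitute, not a re-implementation of
any external program.

## Families, parent slots and pedigree summaries

Full-sib families are connected components of FS calls, followed by a
transitivity repair: inside each component, every member's mean FS
support (`llFS - llU` against the other members) is computed, and
negative-support members are peeled off worst-first into singletons. The
repair is deterministic given the calls. Half-sib links between families
are declared when more than half of the cross-family dyads are called HS.

Each family owns two latent parent slots; each HS link merges one
still-free slot of each family (union-find). The number of contributing
adults is the count of distinct slot classes — hence 2 slots per
singleton, and `2F - merges` in general. A sib-free cohort of `n`
offspring therefore implies `2n` adults. Reproductive success tallies
family sizes per slot class: the mean is `2 n / N_s` by construction and
the variance is the sample variance of per-parent counts.

Group coancestry for a cohort of `n` is computed from its FS and HS dyad
counts with per-dyad coefficients 0.125 and 0.0625 over the `C(n, 2)`
distinct dyads (self-pairs excluded, unrelated dyads contributing zero).
This is the unique simple convention that reproduces all published
worked values from their printed dyad counts; if counts were given as
ordered pairs the equivalent kinship coefficients would be 0.25/0.125.
Dyad counts exceeding `C(n, 2)` are flagged with a warning but not
rejected, since printed counts are treated as opaque inputs.

## Effective number of breeders

**Sibship method.** From per-offspring parent assignments (true or
latent), `Q_mother` is the fraction of dyads sharing a mother and
`Q_father` likewise; effective parent counts are `1/Q` and
`N_b = 4 / (Q_m + Q_f)` (Wright's `4 N_f N_m / (N_f + N_m)` composition).
The 95% CI is a percentile bootstrap over offspring (500 resamples). The
estimator is exact on constructed pedigrees with equal parent shares and
recovers ideal populations of 50 breeders to within sampling error; it is
upward-noisy when offspring sampling is sparse relative to the parent
pool, which is why the `N_b <= N_s` pattern is asserted only in the
well-sampled regime the empirical cohorts occupy.

**LD method.** The squared Burrows composite correlation of ALT dosages
is averaged over eligible locus pairs — interscaffold-only by default, to
exclude physical linkage — after dropping loci with sample MAF below
`p_crit = 0.05`. The sampling bias is removed with
`r2' = r2 - (1/S + 3.19/S^2)` (valid for S >= 30; smaller samples are
rejected rather than silently using the small-S variant) and inverted
under random mating as `Nb = (1/3 + sqrt(1/9 - 2.76 r2')) / (2 r2')`.
Non-positive `r2'` censors the estimate at infinity; a negative
discriminant returns NA. The 95% CI is a delete-one jackknife over
individuals computed on the `1/Nb` scale (standard LD-method practice;
the scale is near-normal where `Nb` itself is heavy-tailed).

## Spatial randomization test

For a cohort with `N_gt` genotyped larvae, `Dyad_total = C(N_gt, 2)`
dyads and `N_RW` related dyads, the observed statistic is the proportion
of related dyads whose members share a sampling location. The null
assigns `N_RW` related labels uniformly without replacement among all
dyads (1,000 draws by default); a variant permuting location labels over
individuals is available (`permute = "locations"`) since the two nulls
have different variances and the original procedure is ambiguous between
them. The statistic is defined as within-location related dyads over
`N_RW`: the alternative reading (related dyads over all dyads) is
constant under the randomization and cannot yield a test.

The default p-value is the proportion of null draws strictly greater than
the observed value. For this discrete statistic the strict rule is
anti-conservative under ties (a constant null gives p = 0); the inclusive
rule (`strict = FALSE`), whose rejection region at 199 draws coincides
with the add-one permutation p-value, is the calibrated choice and is the
one the type-I-control tests exercise. Cohorts without related dyads have
no test (the statistic is 0/0) and error explicitly. Cross-cohort
comparisons are two-sided Fisher exact tests on the 2x2
within/between-by-cohort tables.

## Population-genomic summaries

* **Diversity** per locus x population: observed heterozygosity, unbiased
  expected heterozygosity `2 p q 2n/(2n - 1)`, `F_IS = 1 - Ho/He` (Nei
  convention, negative values retained, undefined at monomorphic cells),
  and MAF.
* **Differentiation**: Nei & Chesser sample-size-corrected `H_S`/`H_T`
  with `G_ST = (H_T - H_S)/H_T` per pair and globally; the multilocus
  value is a ratio of averages (sum of `H_T - H_S` over sum of `H_T`) for
  stability at small `H_T`, with the average-of-ratios alternative behind
  a flag. Small negative per-locus estimates are expected and kept.
* **Ordination**: per-locus mean imputation of missing dosages, PCA, then
  LDA on a user-chosen number of retained components (`n_pcs` has no
  claimed default: the retention criterion used in the original survey is
  not recoverable). Discriminant loadings are back-projected to loci,
  summarised as the sum of squared loadings across axes and reported as
  percentile ranks; tied minima (e.g. monomorphic loci) anchor the scale
  at 0 via minimum-rank ties. Everything is deterministic.
* **Outlier scan**: the neutral F_ST distribution is fitted to the
  trimmed core (5% from each tail by default) of the per-locus values by
  maximum likelihood under a scaled chi-square model
  `Fst df / Fst_bar ~ chisq(df)` *doubly truncated at the trim bounds* —
  fitting the untruncated model to trimmed data would bias `df` upward.
  The optimiser works on log parameters (Nelder-Mead, method-of-moments
  start `df = 2 mean^2 / var`); right-tail p-values for all loci are
  BH-adjusted and flagged at FDR 0.10. The uncorrected per-locus
  statistic drives the fit, mirroring the two-statistic design of
  trimmed-likelihood outlier scans. Loci with non-positive F_ST receive
  p = 1 and never enter the fit.
* **HDplot**: per locus, summed REF and ALT reads over heterozygous calls
  give `D = (n_A - n_B)/sqrt(n_A + n_B)`; together with the heterozygote
  fraction `H`, loci with `H > 0.60` or `|D| > 7` are flagged as putative
  collapsed paralogs. Allele balance is the mean heterozygote REF-read
  fraction per SNP with a [0.3, 0.7] acceptance band.

## Genotype filtering and panel selection

Filters run in a fixed order, because order changes survivor counts:
genotype-level GQ masking (GQ < 10), individual removal (> 75% missing;
a 50% threshold is conventional for the population-genetic subset), site
removal by mean depth (< 10x) then by missingness (> 30%). The report
counts removals per stage and is additive by construction.

The independent pedigree panel keeps, per scaffold, a greedy
left-to-right selection of loci genotyped in > 80% of individuals and at
least 2 Mb apart. Greedy earliest-position selection is optimal in locus
count for a minimum-gap constraint (verified against brute force in the
tests); an optional mode prefers the highest-MAF eligible locus within
each spacing window instead of the left-most.

## Ageing from body lengths

Larval ages (0, 1, 2, 3+) come from a four-component Gaussian mixture of
body lengths fitted by EM: tolerance 1e-8 on relative log-likelihood
change, at most 500 iterations, variance floor 1e-4 mm^2 (hitting the
floor flags the fit as degenerate rather than failing, so an
all-identical input is handled). Two deterministic starts are run —
component means at the `(2k-1)/2K` sample quantiles, and at the same
levels of the data range — and the higher final log-likelihood wins; a
single quantile start can stall in a local optimum that splits the
youngest, most abundant age class when mixing weights are uneven.
Components map to ages in ascending-mean order, which is biologically
forced for length-at-age. Assignment is by maximum posterior.

## The synthetic-data generator

Defaults are the study conditions wherever those are stated, and
field-realistic choices elsewhere:

* allele frequencies: truncated Beta(0.7, 0.7) on [0.05, 0.95] — a
  U-shaped spectrum typical of RAD SNP ascertainment with a mean MAF near
  0.25; the discovery spectrum itself is not published, only per-stream
  mean MAFs around 0.15-0.17, so the generator is calibrated loosely;
* read depth: negative binomial with mean 30 and dispersion 5, matching a
  >= 10x mean-depth filtering regime without claiming the real depth
  distribution; heterozygote allele depths are Binomial(depth, 0.5);
* genotyping error: with probability `error_rate` a call is replaced by
  an independent HWE draw — the same model the classifier assumes, which
  keeps likelihoods proper but also means error-model misspecification is
  *not* exercised by the tests;
* population structure: Balding-Nichols Beta draws around ancestral
  frequencies at a target F (default survey regime 0.01, within the
  published 0.000-0.018 range);
* lengths: Gaussian mixture with means 30/70/110/150 mm, SDs 8-15 mm and
  weights 0.35/0.30/0.20/0.15 — a plausible larval length-frequency
  shape with abundance declining in age.

What the generator does not emulate: linked loci within scaffolds (locus
coordinates are spaced >= 2 Mb by construction), null alleles and
allele-specific capture bias, family-correlated missingness, age-length
overlap beyond Gaussian tails, and real paralogs (HDplot fixtures are
constructed directly). Passing tests therefore demonstrate correctness of
the estimators under their stated models and calibration on idealised
data — not robustness to every artefact of a real RAD-capture panel.

## Problem sizes in the shipped tests and scripts

The test suite runs the power study at reduced replication (5 replicates
per design cell over the full 3 x 3 grid; the analysis script uses 10)
and simulation-based checks at 10-20 replicates, sizes chosen so the
whole suite completes in well under a minute of compute per file while
keeping Monte-Carlo acceptance bands at 3-sigma width. The full published
design (100 replicates per cell, 900 datasets) is a single argument
change in `run_power_study()` or `analysis/02_power_study.R`.
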