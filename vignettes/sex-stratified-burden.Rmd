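---
title: "Sex-stratified rare-variant burden and penetrance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-stratified rare-variant burden and penetrance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcmburden)
```

This vignette documents the statistical model behind `dcmburden`, the
conventions and thresholds it fixes, the design decisions taken where more
than one defensible choice existed, and what its simulation-based validation
does and does not demonstrate.

## The question and the model

Most definitive dilated-cardiomyopathy (DCM) genes are autosomal, so rare
qualifying variants are carried at equal rates by men and women in the
population. Among *diagnosed cases*, however, the proportion of carriers of
gene *g* depends on how penetrant that gene's variants are in each sex: if a
variant class causes disease more readily in women, female cases are
enriched for its carriers. Writing $q_g$ for the population carrier
frequency, $\pi_{g,s}$ for the penetrance in sex $s$ and $b$ for the disease
risk in non-carriers, the probability that a case of sex $s$ carries gene
$g$ is

$$
P(G_g \mid D, s) \;=\; \frac{q_g\,\pi_{g,s}}
     {\sum_h q_h \pi_{h,s} + \bigl(1 - \sum_h q_h\bigr)\, b},
$$

whose denominator is the sex-specific prevalence. Comparing carrier counts
between female and male cases therefore tests $\pi_{g,f} = \pi_{g,m}$
without needing population controls. This conditional model is exactly what
the synthetic-cohort generator simulates, which is why the pipeline's
behaviour on generated data has analytic expectations.

## Variant qualification

A variant qualifies for a gene when it passes four gates, applied in a fixed
order so that every exclusion carries a single deterministic reason
(`low_call_rate`, `low_qual_by_depth`, `hwe_violation`, `common_af`,
`class_mismatch`, `ttn_non_constitutive`):

1. **Variant QC.** Genotyping call rate ≥ 0.90 and QualByDepth ≥ 6, both
   passing on equality, and an exact Hardy–Weinberg p-value ≥ $10^{-6}$.
   The HWE test is the Levene–Haldane exact test: conditional on the
   observed allele counts, the heterozygote count has distribution
   $P(n_{AB}) \propto 2^{n_{AB}} / (n_{AA}!\,n_{AB}!\,n_{BB}!)$ over counts
   of the right parity, and the p-value sums all outcomes no more probable
   than the observed one. Monomorphic sites return 1. The test is computed
   on all genotyped samples of the analysed cohort; computing it within
   ancestry strata would also be defensible, but with the cohort's limited
   admixture a pooled test was chosen for simplicity and power.
2. **Rarity.** The allele frequency must be strictly below 0.01%
   ($10^{-4}$) in *every* reference population supplied, i.e. the popmax
   frequency is the binding constraint. A frequency of exactly $10^{-4}$
   fails (the rarity bound is strict; the QC bounds are not). Populations
   from which the variant is absent contribute zero, and a variant with no
   frequency annotation at all is treated as unobserved, hence rare.
3. **Mechanism class.** Consequence terms on the MANE transcript map to
   predicted loss-of-function (stop gained, frameshift, essential splice
   site), missense (missense, in-frame indel) — with pLoF taking precedence
   when both appear — or `none`. The protein-altering class (PAV) is
   exactly the union of the first two. Each gene is tested only on the
   class consistent with its disease mechanism: truncating for *TTN*,
   *FLNC*, *BAG3*; missense for *DES*, *MYH7*, *TNNC1*, *TNNT2*;
   protein-altering for *DSP*, *LMNA*, *RBM20*, *SCN5A*, *PLN*.
4. **TTN exons.** Titin truncating variants only cause DCM when they hit
   exons constitutively included in the cardiac transcript. There is no
   canonical percent-spliced-in cut-off for "constitutive"; the package
   defaults to PSI ≥ 0.90, configurable in `filter_config()`. A TTN variant
   with *missing* PSI is conservatively excluded — silently admitting
   unannotated exons would dilute the tested class.

Sample-level QC (excess heterozygosity, sex checks, relatedness pruning) is
**deliberately not implemented**: the sample sheet is assumed to describe
unrelated, QC-passing individuals. Feeding related samples in will
overstate carrier counts.

## The exact burden test

Carriers are collapsed per gene — at least one alternate allele at at least
one qualifying variant makes a carrier, counted once — into the 2×2 table of
sex by carrier status, with females as the first row so an odds ratio above
one means female enrichment. A missing genotype counts as non-carrier: after
the ≥ 90% call-rate filter at most a small fraction of calls can be missing,
and keeping fixed per-sex denominators makes the table honest about its
sampling frame; per-gene denominator adjustment was rejected as needless
complexity at this missingness level.

Conditional on both margins the carrier cell follows the noncentral
hypergeometric distribution with odds ratio $\psi$. The package reports:

* the two-sided exact p-value: the sum of probabilities, under $\psi = 1$,
  of all tables no more probable than the observed one (the "minimum
  likelihood" convention; other two-sided conventions exist and give
  different numbers, so the choice is fixed and documented);
* the conditional MLE $\hat\psi$ solving $E_\psi[X] = x$, plus the sample
  odds ratio $ad/bc$ for transparency (they differ noticeably only in
  sparse tables);
* the central exact conditional 95% interval, each tail at 2.5%, with
  one-sided intervals (lower 0, upper $\infty$) when the observed cell sits
  at the edge of its conditional support.

The root solves run on the log-odds scale with symmetric bracket expansion
and `uniroot` at tolerance $10^{-12}$, so estimates and interval ends are
reproducible to well below $10^{-6}$; the test suite checks them against
brute-force enumeration and golden-section likelihood maximisation over
every 2×2 table with total ≤ 60, and against `stats::fisher.test` (whose
own roots stop near $10^{-4}$) at a correspondingly looser tolerance.

Genes with fewer than five combined carriers are excluded before testing —
a sex comparison on four carriers can never reach informative significance,
and excluding such genes keeps the multiplicity family small. The boundary
is strict: exactly five carriers are tested. Benjamini–Hochberg adjustment
(step-up, via `stats::p.adjust`) runs over the *tested* genes only, since
excluded genes contribute no p-value. Adjusted values therefore depend on
both the p-value convention and the family definition; the package reports
raw p alongside adjusted so either can be recomputed.

Because the exact conditional test is discrete, it is conservative: the
replicated null study (`null_calibration_study()`, 500 equal-penetrance
cohorts of 274 female / 556 male cases at cohort-like carrier frequencies)
yields per-gene rejection fractions at $\alpha = 0.05$ of roughly 0.03–0.05
— at or *below* the nominal level, occasionally dipping under the two-sided
99% binomial band around 0.05. That is the expected behaviour of exact
tests on tables with tens of carriers, not miscalibration; the upper bound
is what matters for error control and is respected.

## Cross-sectional penetrance

Bayes' rule gives $P(D \mid G) = P(G \mid D)\,P(D)/P(G)$, estimated as
`prevalence * f_case / f_pop` and clamped to $[0, 1]$. Frequencies are
computed on carrier counts; for variants at popmax < 0.01% essentially all
carriers are heterozygous, so allele- and carrier-based ratios coincide (an
`allele_counts` switch divides by $2n$ instead for callers whose counts are
alleles).

Design choices:

* **Prevalence is a required input with no default.** Penetrance scales
  linearly in it, and no single value is right across populations, sexes or
  diagnostic definitions; a silent default would be the most dangerous knob
  in the package. Supply the stratum-appropriate value (and optionally a
  95% interval, propagated log-normally).
* **Intervals by Monte Carlo.** Both frequencies are drawn from Jeffreys
  Beta posteriors ($k + \tfrac12$, $n - k + \tfrac12$); the clamped ratio is
  formed per draw and the 2.5/97.5 percentiles reported. Default
  $10^5$ draws, default seed 20250423; identical inputs and seed give
  bit-identical intervals, and the caller's RNG state is restored. Clamped
  draws are counted and reported (`n_clamped`), since heavy clamping
  signals that the point estimate is pressed against 1.
* **Boundaries.** Zero case carriers give point 0 with an upper bound from
  the posterior; zero *population* carriers make the ratio undefined and
  raise an error rather than returning infinity.

The estimator is validated by parameter recovery
(`penetrance_recovery_study()`): 500 replicates at 274/556 cases and
biobank-scale population denominators (91,751 female / 75,727 male), with
true penetrance 0.11/0.02 (female/male) for *DSP* and 0.06/0.18 for *TTN*.
Coverage of the 95% interval is 0.93–0.97 in all four gene–sex cells. The
*median* relative bias is within a few percent wherever expected carrier
counts are moderate, but in the male-*DSP* cell — about two expected case
carriers — the binomial median is lumpy (1 vs 2 carriers) and the plug-in
median lands 15–25% below truth. That is count discreteness, not estimator
drift: the mean is on target, and the interval covers. Penetrance point
estimates built on single-digit carrier counts should be read with their
intervals, not alone.

## The synthetic-cohort generator

`simulate_population()` draws, per individual: sex (Bernoulli, default
0.5), a carried gene (multinomial over carrier frequencies — each
individual carries qualifying variants in *at most one* gene, which keeps
per-gene expectations analytic and is a documented simplification), and
disease (sex-specific penetrance for carriers, background risk 0.0028
otherwise). Every carrier then receives a private heterozygous qualifying
variant with realistic annotations, and decoy variants exercising every
exclusion reason (common frequency, synonymous consequence, low
QualByDepth, low call rate, Hardy–Weinberg violation, non-constitutive or
unannotated TTN exon, wrong class, unlisted gene) are interleaved.
`ascertain_cases()` samples diagnosed individuals at a requested sex split;
`simulate_case_cohort()` instead draws cases directly from the conditional
carrier distribution above — statistically identical because individuals
are independent, and the route used for 500-replicate studies. Default
per-gene carrier frequencies are round values in the rare-variant regime
chosen to reproduce cohort-like carrier counts at 274/556 cases (e.g.
$3\times10^{-3}$ for *TTN*, $5\times10^{-4}$ for *DSP*, giving about 6
female and 2 male truncating *DSP* carriers per cohort); *DSP* and *TTN*
carry the sex-asymmetric penetrance under study and the other genes are
sex-neutral at 0.05.

What the generator does **not** emulate: linkage disequilibrium and
haplotypes, relatedness, ancestry structure and stratified allele
frequencies, X-chromosome dosage (all twelve genes are autosomal), variable
sequencing depth, or multi-gene carriers. Passing tests on generated data
therefore demonstrate that the statistics are computed correctly under the
stated model — they do not certify robustness to population structure or
cryptic relatedness in real cohorts, which must be handled upstream.

Separately, `table1_cohort()` is a deterministic, seed-free fixture whose
qualifying-carrier counts encode a reference burden table exactly (spread
over records of at most five heterozygotes, so every record is rare and in
equilibrium), with one decoy per exclusion reason and a manifest of expected
verdicts; `ukb_cohort()` does the same for a 1,304-case population-biobank
validation comparison.

## Numerical conventions and degenerate inputs

* Probability ties in both exact tests use a $1 + 10^{-7}$ relative slack,
  so equal-probability outcomes lost to floating point still count as ties.
* Displayed odds ratios round half-up at two decimals (so the *LMNA*
  conditional MLE 1.7945 prints 1.79 while a sample OR of 1.796 would print
  1.80); adjusted p-values display at two significant figures. Full
  precision is always available in the machine-readable report.
* Monomorphic sites: HWE p = 1. Empty table margins: error ("untestable
  gene") rather than NA. Genes with no qualifying variants appear with
  zero-carrier tables and are excluded by the minimum-carrier rule.
* Replicate seeds are derived from the user seed by fixed affine maps
  modulo $2^{31} - 1$, so every study is reproducible from one integer.

## Problem sizes used in validation

The shipped studies use 500 replicates each (calibration and recovery),
$4{,}000$ Monte-Carlo draws per recovery interval against $10^5$ for
production estimates, exhaustive oracle scans over all 628,055 2×2 tables
with total ≤ 60 and all 1,373,700 genotype triples with total ≤ 200, and a
$10^5$-individual population for the law-of-large-numbers check. These
sizes give Monte-Carlo error well inside the tolerances they are checked
against while keeping a full validation run in the minutes range on a
single core.

## Known limitations

* FDR-adjusted values are convention-dependent (p-value sidedness, family
  definition); this package fixes two-sided exact p over tested genes and
  reports raw p so alternatives can be recomputed, but numbers produced
  under other conventions will differ.
* The penetrance point estimate is median-biased at very small carrier
  counts (see above); intervals remain calibrated.
* The exact burden test is conservative on sparse tables; with carrier
  counts below ~10 per gene its power is limited and the minimum-carrier
  rule already removes the worst cases.
* Binary sex, single-gene attribution, and pre-cleaned samples are modelling
  assumptions of both the analysis and the generator.
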