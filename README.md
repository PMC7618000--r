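# dcmburden

Sex-stratified rare-variant burden and penetrance analysis for dilated
cardiomyopathy (DCM).

DCM is diagnosed roughly twice as often in males as in females, yet most of
its definitive disease genes are autosomal, so qualifying variants should be
carried equally often by both sexes. If a gene accounts for a different
*proportion of cases* in women than in men, its variants must differ in
penetrance between the sexes. `dcmburden` operationalises that comparison
for people working on cardiomyopathy genetics: it qualifies candidate
variants with mechanism-aware filters, compares per-gene carrier counts
between female and male cases with an exact conditional test, and estimates
sex-stratified penetrance cross-sectionally from case versus population
carrier frequencies. A synthetic-cohort generator with known carrier
frequencies and sex-specific penetrance makes the whole pipeline testable
without access to patient-level data.

## The statistics

**Variant qualification.** A variant qualifies for gene *g* if it passes
variant QC (genotyping call rate ≥ 0.90, QualByDepth ≥ 6, exact
Hardy–Weinberg p ≥ 10⁻⁶ by the Levene–Haldane conditional test), is rare in
every reference population (popmax allele frequency < 0.01%), and its
consequence class on the MANE transcript matches the gene's disease
mechanism — truncating (pLoF), missense, or protein-altering (either) — with
*TTN* truncating variants further restricted to constitutively expressed
cardiac exons (exon inclusion proportion PSI ≥ 0.90).

**Burden test.** Carriers are collapsed per gene (≥ 1 qualifying variant ⇒
carrier, counted once) into the 2×2 table of sex × carrier status. With both
margins fixed, the first cell follows the noncentral hypergeometric law with
odds ratio ψ; the package reports the two-sided exact p (sum of table
probabilities ≤ the observed one under ψ = 1), the conditional maximum
likelihood estimate of ψ solving E<sub>ψ</sub>[X] = x, and the central exact
95% CI (each tail 2.5%). Genes with fewer than five combined carriers are
excluded; the remaining p-values are Benjamini–Hochberg adjusted over the
tested genes.

**Penetrance.** By Bayes' rule, P(D | G) = P(G | D) · P(D) / P(G), estimated
as prevalence × f<sub>case</sub>/f<sub>pop</sub> and clamped to [0, 1], per
sex stratum. Intervals propagate counting noise by Monte Carlo from Jeffreys
Beta posteriors on both frequencies.

## Worked example

The bundled fixture is an 830-case cohort (274 female, 556 male) whose
qualifying-carrier counts per gene and sex encode a reference burden table,
decoy variants included:

```r
library(dcmburden)
fit <- dcm_burden(table1_cohort())
fit
```

```
Sex-stratified rare-variant burden (274 female, 556 male)

Gene    class     N_f    %_f  N_m    %_m  OR [95% CI]            p          p_FDR
TTN     pLoF       37  13.50  105  18.88  0.67 [0.43 - 1.02]     0.062      0.25
FLNC    pLoF        2   0.73    4   0.72  1.01 [0.09 - 7.13]     1          1
DES     missense    2   0.73    6   1.08  0.67 [0.07 - 3.80]     1          1
MYH7    missense   10   3.65   12   2.16  1.72 [0.65 - 4.40]     0.25       0.55
DSP     PAV        20   7.30   14   2.52  3.04 [1.44 - 6.63]     0.0023     0.018
LMNA    PAV         7   2.55    8   1.44  1.79 [0.55 - 5.73]     0.27       0.55
RBM20   PAV         5   1.82    7   1.26  1.46 [0.36 - 5.39]     0.54       0.73
SCN5A   PAV         6   2.19    8   1.44  1.53 [0.43 - 5.10]     0.41       0.65

Excluded genes:
  BAG3    fewer than 5 carriers (2)
  TNNC1   fewer than 5 carriers (1)
  TNNT2   fewer than 5 carriers (4)
  PLN     fewer than 5 carriers (3)
```

Desmoplakin (*DSP*) protein-altering variants are carried by 7.3% of female
but only 2.5% of male cases — a conditional-MLE odds ratio of 3.04 (female
vs male enrichment) with exact 95% CI 1.44–6.63 and raw two-sided exact
p = 0.0023 (BH-adjusted 0.018 over the eight testable genes). Four genes
have fewer than five carriers in total and are not testable. `coef(fit)`
returns the odds ratios, `summary(fit)` adds the variant-level filter log,
and `plot(fit)` draws a forest plot.

Sex-stratified penetrance of *DSP* truncating variants, from carrier counts
in cases (6/274 female, 2/556 male) against a population reference, with
sex-specific DCM prevalence supplied explicitly:

```r
sex_stratified_penetrance("DSP",
  case_counts = list(female = c(6, 274),   male = c(2, 556)),
  pop_counts  = list(female = c(46, 91751), male = c(38, 75727)),
  prevalence  = c(female = 0.0026, male = 0.0034))
```

```
Cross-sectional penetrance estimates
  DSP      female  0.11 [0.05 - 0.25]
  DSP      male    0.02 [0.00 - 0.08]
```

With these inputs, penetrance in female carriers (0.11) is roughly five
times that in male carriers (0.02): the same variant class carries very
different disease risk by sex.

End-to-end runs from files (VCF + annotation TSV + sample sheet, or a YAML
configuration) go through `run_pipeline()`; `write_fixture_table1()`
materialises the fixtures as plain-text files for that path.

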