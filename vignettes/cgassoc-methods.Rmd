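---
title: "Candidate-gene case-control association analysis with cgassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene case-control association analysis with cgassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgassoc)
library(tibble)
```

## Scope and model

`cgassoc` implements the statistical workflow of a candidate-gene
case-control association study of biallelic SNPs: panel-level quality
control, single-SNP logistic association under the five standard genetic
inheritance codings, linkage-disequilibrium and haplotype assessment,
exhaustive multivariate model selection with gene-environment
interactions, and ROC-based comparison of the resulting risk-prediction
models. The outcome throughout is a binary disease label (in the motivating
application, prevalent chronic kidney disease), and every model is a
logistic regression

$$\operatorname{logit} \Pr(Y_i = 1) = \beta_0 + \mathbf{x}_i^\top
\boldsymbol\beta,$$

fit by iteratively reweighted least squares. The genetic design columns are
derived from the effect-allele dosage $d \in \{0, 1, 2\}$:
dominant $\mathbb{1}[d \ge 1]$, recessive $\mathbb{1}[d = 2]$,
overdominant $\mathbb{1}[d = 1]$, additive $d$, and codominant
($\mathbb{1}[d = 1], \mathbb{1}[d = 2]$, 2 df). Missing genotypes are never
imputed: each analysis is complete-case on the variables it uses.

## Quality control

Variants and samples are filtered in a fixed, logged order: samples above a
missingness threshold, variants with no genotyped control (a panel may
simply never have been run on the control arm), variants above a
missingness threshold, and variants out of Hardy-Weinberg equilibrium.
Defaults are deliberately permissive (`max_variant_missing = 0.5`), because
candidate panels routinely retain informative SNPs with up to ~46% missing
calls; the threshold is a configuration value, not a scientific claim.

HWE is tested two ways on the pooled case-control sample: a 1-df
chi-squared goodness-of-fit test without continuity correction, and the
conditional exact test, which enumerates every heterozygote count
compatible with the observed allele totals and sums the probabilities of
configurations no more probable than the observed one. A SNP is treated as
in HWE unless *either* test rejects; the uncorrected chi-squared matches
the companion exact test more closely at these sample sizes than the
Yates-corrected version would. A controls-only HWE mode exists but is off
by default, matching the pooled-assessment convention of prevalence
studies whose case arm dominates the cohort.

## Single-SNP association

For each SNP all five codings are fitted with the adjusting covariates
(default: sex, age, Caucasian yes/no) on the identical complete-case
subject set, and the minimum-AIC model is selected. When only two genotype
classes are observed, several codings collapse to the same design column;
ties are broken by the fixed order dominant < recessive < overdominant <
additive < codominant. The reported p-value is a likelihood-ratio test of
the SNP terms against the covariates-only model on the same subjects. The
odds ratio is the Wald estimate under the chosen coding with
$z = 1.959964$ intervals; for codominant fits the summary row carries the
term with the larger $|\log \mathrm{OR}|$ and the detail output retains
both.

Significant SNPs additionally receive a permutation p-value. The statistic
is the unadjusted likelihood ratio $LR = 2(\ell_{\mathrm{SNP}} -
\ell_0)$; case/control labels are permuted uniformly and
$p = (1 + \#\{LR^* \ge LR\})/(B + 1)$, which avoids exact-zero p-values
and differs from the plug-in proportion by less than reporting precision at
the study-scale $B = 20{,}000$. Permuting outcome labels destroys the
covariate-outcome association, so a covariate-adjusted permuted LR would
not be exchangeable; the package therefore pairs the unadjusted permutation
p with the separately adjusted LRT p, and offers a covariate-respecting
variant (`method = "covariate"`, permuting the genotype vector against the
intact covariate-outcome data) for sensitivity analysis.

Because the encoded genotype takes at most three values, a label
permutation only changes the case count in each genotype class. The
implementation exploits this: each permutation is a multivariate
hypergeometric draw of per-class case counts, and the LR is recomputed by
weighted IRLS on the aggregated (at most 3-row) table. This is
mathematically identical to permuting labels subject-by-subject and makes
large calibration studies cheap.

No multiple-testing correction is applied across SNPs (the workflow this
package mirrors reports per-SNP $\alpha = 0.05$); users scanning large
panels should treat the significant set as hypothesis-generating.

## Linkage disequilibrium and haplotypes

Two-locus haplotype frequencies are estimated from unphased genotypes by
EM: every genotype combination except the double heterozygote contributes
known haplotype counts, and the double heterozygote splits between the
*cis* and *trans* phases in proportion to the current frequency estimates.
Initialization is at linkage equilibrium, iteration stops when the largest
frequency change is below `tol` (default 1e-8, cap 1000 iterations), and
the observed-data log-likelihood is checked to be non-decreasing. From the
frequencies the package reports $D$, $D'$ (normalized by its
frequency-determined bound) and $r^2 = D^2 / (p_A p_a p_B p_b)$, with the
LD test statistic $\chi^2 = 2 n r^2$ on 1 df. A table consisting entirely
of double heterozygotes has a bimodal likelihood and is flagged
`phase_indeterminate` rather than resolved arbitrarily.

Qualitative "haplotype structure supported" calls have no single standard
criterion; the package uses an explicit operational rule — LD test
significant at $\alpha$ and $|D'| \ge 0.7$ — and labels it as its own
convention in the output.

## Multivariate model search

The SNPs significant in the single-SNP stage enter an exhaustive best-subset
search: all $2^m - 1$ non-empty subsets, each coded per its selected
inheritance model and adjusted for the forced covariates, are fitted **on
one fixed complete-case subject set** (subjects with data for all $m$
SNPs). AICs are only comparable on a common likelihood sample, which is why
the subject set is not allowed to vary with the subset. Perfectly collinear
SNP terms (aliasing — e.g. two SNPs whose risk-carrier indicators coincide
subject-for-subject) are detected first; within any subset only the first
member of an aliased group enters the design, so subsets differing only in
which member they carry tie to machine precision. All subsets within
`aic_tie_tol = 1e-6` of the minimum are reported; the tie-break keeps the
smallest subset with the lowest panel indices, mirroring the convention of
retaining the first-listed SNP.

The chosen subset then seeds a bidirectional stepwise search by AIC whose
candidate terms are the SNP main effects, the clinical risk factors
(diabetes, hypertension), and all SNP x clinical and SNP x SNP
interactions, under the marginality hierarchy: an interaction may enter
only while both parents are present, and a parent cannot leave while its
interaction remains. Adjusting covariates are never dropped. A
p-value-driven backward mode (`criterion = "pvalue"`) is available, since
stepwise conventions differ between groups. AIC is a liberal gatekeeper: a
null 1-df interaction enters with probability $\Pr(\chi^2_1 > 2) \approx
0.16$, so occasional spurious interactions in the final model are expected
behaviour, not a defect; the p-value mode is stricter.

Predicted odds-ratio profiles (`profile_odds_ratios()`) contrast arbitrary
covariate/genotype profiles against a reference profile through the fitted
linear predictor, with delta-method Wald intervals on the contrast. When a
figure fixes age, the package follows the convention of using the sample
median age.

## Risk-model discrimination

Model discrimination is evaluated in-sample (apparent AUC), matching the
workflow this package mirrors; no held-out set is constructed, and the
documentation flags the optimism this implies. The AUC is the Mann-Whitney
estimator (ties counted one half), pairwise model comparisons use the
DeLong placement-value test, and per-model uncertainty comes from a
stratified bootstrap that **refits the model on every resample** (1,000 by
default) and reports the mean and 2.5/97.5 percentile interval. The
optimal operating point maximizes Youden's index (equivalently, distance
to the chance diagonal), with ties resolved toward higher specificity;
sensitivity, specificity, PPV and NPV at that point carry Wilson 95%
intervals (chosen for small-sample behaviour; the CI method in published
tables of this kind is rarely stated), with predictive values computed at
the sample case fraction.

## The synthetic-cohort generator

Because genotype-level data of the motivating study are not deposited, the
package ships a generator that reproduces the statistical structure the
analysis assumes, so that every stage is testable end to end:

* genotypes drawn under HWE (`rbinom(n, 2, p)`), linked pairs from a
  four-haplotype pool with configurable frequencies;
* covariates drawn at the cohort-level marginal prevalences of a large
  renal case-control study (60.1% male, age 57.3 (12.6), 3.1%
  non-Caucasian, 22.6% diabetes, 80.7% hypertension, smoking
  43.1/36.9/19.9%);
* a logistic liability combining covariate effects (set to the log crude
  odds ratios of the emulated baseline table: hypertension ln 18.63,
  diabetes ln 2.83, female ln 0.71, non-Caucasian ln 1.95), per-SNP effects
  under their inheritance codings, and optional interaction terms, with the
  intercept solved numerically so the realized case fraction hits its
  target (81.4% in the template);
* missingness applied afterwards: per-SNP random rates, a shared "block"
  of subjects missing a SNP group (emulating two SNPs ~46% missing
  jointly, as happens when part of a cohort is never run on a later assay),
  and SNPs fully missing in one arm (13 such SNPs in the template,
  reproducing a panel never genotyped in controls).

The template (`study_template_config()`) plants 12 effect SNPs with odds
ratios 1.22-1.74 under mixed inheritance models, three linked pairs at
$D' = 0.8$, and one SNP x hypertension interaction at OR 2.68. The SNP
minor allele frequencies are synthetic stand-ins fixed once at plausible
candidate-gene values (0.2-0.45); the emulated study does not publish
them. Two deliberate simplifications: covariates are generated
independently of each other (real risk factors co-occur), and the marginal
crude odds ratios realized by the liability model are mildly attenuated
relative to their conditional coefficients (non-collapsibility of the
odds ratio), so template-level checks of crude effects use wide bands. A
passing test suite therefore demonstrates correct statistics under the
generator's assumptions — HWE, logistic effects, monotone missingness —
not robustness to population structure, batch effects or differential
genotyping error, none of which are simulated.

## Numerical choices

* Logistic fits: IRLS via `stats::glm`, `epsilon = 1e-10`, 100 iterations;
  rank-deficient designs are an error naming the aliased columns; complete
  separation (diverging coefficients with fitted probabilities at the
  boundary) is flagged with a warning, not corrected — no Firth penalty.
* Permutation p-values use $(r + 1)/(B + 1)$; bootstrap intervals are
  percentile (type-7 quantiles).
* The EM tolerance (1e-8 on frequencies) is far below the statistical
  noise at any realistic sample size.
* Effect alleles default to the minor allele computed on the full sample,
  so reported ORs refer to the rarer allele; a per-SNP override exists
  because the risk-allele convention of a published table may differ.
* All randomness flows from user-supplied integer seeds; reruns are
  bit-identical.

## Problem sizes used in the shipped checks

The package's own test suite runs its simulation checks at reduced but
statistically meaningful sizes chosen by us: permutation calibration at
1,000 replicates of $n = 600$ with 199 permutations; OR recovery at 500
replicates of $n = 3{,}004$; interaction retention at 200 replicates of
$n = 3{,}000$; EM consistency at $n$ up to 50,000. The acceptance script
scales the replicate counts further down (500/200/60) while keeping the
cohort sizes; all sizes are stated in the script.

## Known limitations

* No genotype imputation, no indels or multiallelic sites, no sex-
  chromosome dosage rules, no phased input.
* No relatedness, population-stratification or batch-effect modelling.
* No penalized or cross-validated model selection; the search is AIC
  enumeration plus stepwise, with its known liberality.
* Discrimination is apparent (in-sample); external validation is the
  user's responsibility.
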