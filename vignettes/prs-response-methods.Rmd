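---
title: "Methods: polygenic scores and antipsychotic treatment response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scores and antipsychotic treatment response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsresponse)
```

## The scientific problem

Response to antipsychotic medication varies widely between patients, and part
of that variability is heritable. A polygenic risk score (PRS) aggregates many
small allelic effects into one per-subject number: given a panel of variants
with effect alleles and weights, the score is

$$\mathrm{PRS}_i = \sum_j \beta_j \, d_{ij},$$

where $d_{ij} \in [0,2]$ is subject $i$'s dosage of the effect allele at
variant $j$. The packaged default panel contains eleven SNPs previously
associated with antipsychotic response at genome-wide significance; because
published per-SNP effect sizes on response are not available, the panel uses
unit weights ("dummy beta"), making the score a plain risk-allele count in
$[0, 22]$. Odds-ratio-weighted panels (with $\beta_j = \ln \mathrm{OR}_j$) use
the same machinery.

The package implements the full analysis chain around that score —
variant-level quality control with ancestry principal components, linkage
disequilibrium (LD) clumping, score construction, a rule engine deriving a
binary responder label from longitudinal Clinical Global Impressions (CGI)
records, covariate-adjusted logistic association, and Youden-index diagnostic
evaluation — plus a seeded synthetic-cohort generator, because individual-level
clinical-genetic cohorts of this kind are not publicly deposited. Every stage
is therefore exercisable and testable end-to-end with known ground truth.

## Quality control

Variants are excluded when any of the following fails (defaults in
parentheses, all configurable and echoed in reports):

* call rate below a threshold (retain iff $\geq$ 0.99; the exclusion condition
  is read strictly, "below 99 percent");
* Hardy-Weinberg equilibrium: one-degree-of-freedom Pearson chi-square of the
  observed genotype counts against $p^2, 2pq, q^2$ expectations at the sample
  allele frequency, without continuity correction (exclude iff
  $p < 10^{-6}$). An exact HWE test is deliberately out of scope — the
  chi-square is the documented choice;
* minor allele frequency below 0.05.

The HWE statistic is exactly $n$ for a complete heterozygote deficit
($F = 1$) and exactly 0 when observed counts equal their expectations; both
identities are asserted in the tests. Monomorphic variants return statistic 0
and are flagged rather than tested. Subjects are never removed by variant QC.

Ancestry principal components are computed EIGENSTRAT-style: missing dosages
are mean-imputed per variant, columns are centered by $2f$ and scaled by
$\sqrt{2f(1-f)}$, and the top-$k$ (default 5) left singular vectors are
returned as unit-norm subject coordinates with the sign fixed so each
component's largest-magnitude entry is positive. Ancestry subsetting by PC
thresholds is exposed as a configurable filter (`pc_subset()`); the particular
thresholds any one cohort used are cohort-specific and never hard-coded.

## LD clumping

Greedy index selection in the PLINK/PRSice tradition: sort by ascending
p-value (ties broken by chromosome, position, then id — determinism matters
more than the arbitrary choice); take the best unassigned variant as index and
remove all unassigned variants on the same chromosome within a window
(default 250 kb measured from the index position, both directions) whose
in-sample squared dosage correlation with the index is at or above the
threshold (default 0.1, so strictly-below-0.1 pairs are considered
independent). The default index-eligibility p-value threshold of 1 makes every
variant eligible. Missing dosages use pairwise-complete deletion in $r^2$; a
constant dosage vector yields $r^2 = 0$ with a flag. LD is computed in-sample
(no external reference panel). A zero-width window disables clumping entirely,
including co-located variants. The greedy output is verified against an
independent exhaustive oracle on randomized instances.

## Score construction and allele alignment

Score files carry effect/other alleles on an arbitrary strand and the genotype
file orders REF/ALT arbitrarily, so each panel entry is aligned before
scoring: direct match (use ALT dosage), swapped match (use $2 - d$),
complement-strand match (flip then align), otherwise drop with a reason.
Strand-palindromic variants (A/T and C/G pairs) are dropped by default because
their strand cannot be resolved without reference frequencies; the
`allow_palindromic` flag trusts the strand, which is appropriate when score
file and genotypes share provenance — the pipeline does exactly that for its
own simulated cohorts, two of whose default panel variants are palindromic.

Missing dosages follow a policy: `mean` (default) imputes $2f$ with $f$ the
in-sample effect-allele frequency, matching common PRS-software behaviour and
producing fractional scores; `omit` scores subjects over their non-missing
variants; `fail` refuses. The score is the raw weighted sum, not an average
per allele — with an 11-variant unit-weight panel the observed scale
(roughly 0-12 about a mean near 6 at realistic frequencies) only makes sense
on the sum scale.

## Response classification

The rule engine reads a subject's CGI-S/CGI-I observations and treatment
events inside a window (default 365 days) after the course start. Response
signals: R1, a CGI-S decrease of at least 2 points between observations at
least 30 days apart (improvement means a lower score; the spacing applies to
this pair only); R2, any CGI-S of 1; R3, any CGI-I of at most 2. Stability
conditions: R4, treatment duration at least 90 days; R5, no antipsychotic or
mood-stabilizer add-on; R6, no dose increase after day 90. A responder must
satisfy (R1 or R2 or R3) and R4 and R5 and R6 — the signals are alternatives,
the stability conditions necessary; this conjunction/disjunction structure is
the only reading under which "all other cases are unknown" is coherent, and it
is asserted prominently in the tests.

Non-response is never defined symmetrically in this literature, so the package
documents explicit rules: N1, an add-on, a switch, or a post-90-day dose
increase inside the window; N2, discontinuation attributed to inefficacy at
any time; N3, at least 180 days of CGI-S observation with two or more values,
duration at least 90 days, and no response signal ever. Everything else —
including discontinuation for side effects, whose efficacy information is
nil — is `unknown` and excluded from association analyses, with the exclusion
count reported. R1 comparisons default to "any earlier visit"; a
`baseline_only` switch restricts them to the first observation.

## Association and diagnostics

Per-variant tables cross-tabulate hard-call genotypes against responder
status; the Cochran-Armitage trend test (via `stats::prop.trend.test`) is used
when all cells are adequately filled, the genotypic Fisher exact test (via
`stats::fisher.test`, checked in the test suite against a complete enumeration
oracle) otherwise. The per-variant odds ratio is the allelic contrast
(2 x hom + het per group) with a Woolf interval and the Haldane-Anscombe 0.5
correction for empty cells, flagged when applied; group-swap maps the log odds
ratio to its exact negation. No multiplicity correction is applied to the
primary per-SNP report (a handful of pre-specified variants, nominally
reported), but a Bonferroni column is emitted for transparency.

The primary model is maximum-likelihood logistic regression of responder
status on the score, age (years) and PC1-PC5, with Wald standard errors, 95
percent Wald intervals and two-sided p-values. Perfect separation is detected
(fitted probabilities saturated concordantly with the outcome) and raised as
an error rather than reported as a huge coefficient. A univariate screen
(linear-probability and logistic fits per candidate) flags covariates at
p $\leq$ 0.05 for inclusion. Subgroup analyses are driven by ICD-10 prefix
lists (schizophrenia; plus schizoaffective; plus bipolar; all; complement),
each stratum fitted independently.

ROC curves place cutoffs at midpoints between distinct scores with infinite
sentinels; prediction is score $\geq$ cutoff (higher score predicts response
by default, a direction flag exists). The AUC is the Mann-Whitney probability
with ties counted half, identical to the trapezoidal area. The reported
operating point maximizes the Youden index $J = \mathrm{sens} +
\mathrm{spec} - 1$ by exhaustive search; ties break toward the smallest
cutoff. PPV and NPV are computed at the cohort's own prevalence; when a cutoff
predicts no positives (or negatives) the corresponding value is flagged
undefined rather than propagated as NaN.

## The synthetic cohort generator

The generator's defaults describe the study conditions the package is built
around: 460 subjects, the packaged 11-SNP panel with effect-allele frequencies
on a European-ancestry scale, a responder fraction near 0.54
(intercept $= \mathrm{logit}(249/460)$), a per-PRS-unit odds ratio of 1.14, an
age effect of $-0.02$ log-odds per year (older patients respond less often),
ages uniform on 18-80, and per-entry genotype missingness of 0.002. With those
frequencies the implied score distribution (mean $\approx 5.95$,
SD $\approx 1.96$) closely matches the scale reported for real cohorts scored
on this panel — a consistency check on the frequency choices, not a fitted
quantity.

Structure and LD are deliberately simple. Population structure follows a
Balding-Nichols model: subpopulation-specific allele frequencies drawn from a
Beta distribution around the ancestral frequency with drift parameter
`fst` (default 0.02 across two equal subpopulations), optionally with a
subpopulation log-odds shift on response so that ancestry confounding is
recoverable through PCs. LD blocks are induced by copy-with-resample — a block
member matches its anchor with probability $\sqrt{r^2}$ — which reproduces any
target pairwise $r^2$ among equal-frequency variants; only pairwise $r^2$
matters to clumping, so no haplotype model is attempted. Unequal frequencies
within a block are rejected as incompatible rather than silently approximated.

Responder status is drawn from the logistic model on the true
(complete-genotype) score and age, both centered, so the intercept controls
the responder fraction. Clinical trajectories are then constructed to be
recoverable by the rule engine: responders receive one of the three response
signals and no disqualifier (one in five also receives a harmless pre-day-90
dose increase, exercising the R6 boundary); non-responders receive one of five
mechanisms (add-on, post-90-day dose increase, switch, discontinuation for
inefficacy, or a flat CGI course spanning at least 190 days), with CGI values
constrained never to improve by two points or reach 1. A `label_fidelity`
parameter (default 1) sets the fraction of subjects whose trajectory agrees
with their latent status. Visit schedules are not modeled realistically — the
number and spacing of visits is whatever the chosen mechanism needs, and is
documented as a construction, not an inference.

What passing tests therefore show: the pipeline's stages are correct against
their definitions and calibrated under the generator's assumptions
(independent subjects, hard-call binomial genotypes, logistic outcome,
recoverable trajectories). What they do not show: performance under realistic
haplotype structure, imputation dosage error, visit-schedule informativeness,
diagnosis-dependent effect sizes, or any reproduction of a particular cohort's
printed estimates — those require the original individual-level data.

## Numerical and design choices

* Determinism: every stochastic function is driven by a single integer seed;
  identical configurations produce byte-identical cohorts. Phenotype
  generation offsets the seed by a fixed constant so genotypes and phenotypes
  are independently reproducible.
* PCA rank deficiency returns zero-filled trailing components with a
  degenerate flag; an all-identical cohort yields all-zero components rather
  than an error.
* Dosages are validated into $[0,2]$; hard calls for HWE and contingency
  tables are obtained by rounding (round-half-even, irrelevant for integer
  calls).
* The demonstration problem sizes — 460 subjects for the end-to-end run, 500
  replicates of n = 1000 for parameter recovery, 2000 null tables for
  trend-test calibration, 100 random instances for clumping oracle
  equivalence — were chosen as the package's own standard study conditions and
  are stated in the tests that use them.
* Parameter-recovery acceptance uses a "combined" standard error for the
  replicate mean, $\sqrt{\mathrm{sd}(\hat\beta)^2 +
  \overline{\mathrm{se}^2}}/\sqrt{R}$: maximum-likelihood logistic estimates
  carry a first-order bias of order $\beta(p+2)/n$ that is real, small and
  expected, and a band blind to estimation uncertainty would reject a correct
  implementation.
* The per-variant odds-ratio contrast in published per-SNP tables of this
  design is often undefined; the allelic contrast is this package's documented
  default, and an adjusted per-SNP logistic fit is available through
  `fit_logistic()` on a single-variant design.

## Worked example

```{r example, eval = FALSE}
library(prsresponse)
report <- run_pipeline(default_config(n_subjects = 460, seed = 1))
print(report)
report$association[, c("stratum", "n", "or", "ci_low", "ci_high", "p")]
```

## Known limitations

Only autosomal biallelic variants are modeled; there is no X/Y handling,
sex-mismatch or relatedness QC, imputation, phasing or liftover. The Fisher
exact test delegates to the standard network algorithm and is limited by table
size (a Monte-Carlo mode exists). Small strata (a few dozen subjects) fit the
full covariate model and can be unstable; failed stratum fits are flagged
rather than dropped. The generator's clinical trajectories guarantee
recoverability by construction and must not be mistaken for a model of real
visit dynamics.
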