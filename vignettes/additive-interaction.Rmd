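---
title: "Additive gene-environment interaction in matched case-control data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive gene-environment interaction in matched case-control data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reriscan)
```

## The model

`reriscan` analyses individually matched case-control data in which each
case is matched to 1-3 controls on age band, sex and recruitment center.
For one SNP and one binary drug exposure, every subject falls into one of
four joint categories: (unexposed, wild-type) — the reference — plus
exposed-only, carrier-only, and both. "Carrier" uses the dominant
genetic model: carriage of at least one variant allele. The package fits

$$\mathrm{logit}\,P(\text{case}) = \beta_{10}\,\mathbb{1}[\text{exp only}]
 + \beta_{01}\,\mathbb{1}[\text{carrier only}] + \beta_{11}\,\mathbb{1}[\text{both}]
 + \gamma' z$$

by the matched-set conditional likelihood: conditioning on each stratum
containing exactly one case,

$$\ell(\beta) = \sum_s \left[ x_{\text{case}(s)}'\beta -
  \log \sum_{j \in s} \exp(x_j'\beta) \right].$$

This was a deliberate design decision. Multicenter matched studies are
sometimes analysed with multi-level mixed logistic models (subjects
within strata within centers within periods); but when controls are
matched within center, and enrolment period is shared by a case and its
controls, both center and period are constant within every matched set
and are *absorbed* by the conditional likelihood. The conditional
estimator therefore targets the same within-stratum odds ratios with an
explicit, fully testable likelihood — value, gradient and Hessian are
exact closed forms, verified in the test suite against a plain-loop
enumeration oracle and against `survival::clogit`. The cost of this
choice is that exact numerical agreement with a random-effects fit of the
same data is not guaranteed (nor required): the two estimators coincide
asymptotically under the matched design but differ in finite samples.

Interaction on the additive scale is summarised by

$$\mathrm{RERI} = \mathrm{OR}_{11} - \mathrm{OR}_{10} - \mathrm{OR}_{01} + 1,
\qquad
S = \frac{\mathrm{OR}_{11} - 1}{(\mathrm{OR}_{10} - 1) + (\mathrm{OR}_{01} - 1)},$$

with $\mathrm{OR}_{\cdot} = e^{\beta_\cdot}$ taken from the joint model.
A useful property worth keeping in mind (and enforced as a test): under a
*multiplicative* null $\mathrm{OR}_{11} = \mathrm{OR}_{10}\mathrm{OR}_{01}$
with both single-factor ORs above 1, RERI equals
$(\mathrm{OR}_{10}-1)(\mathrm{OR}_{01}-1) > 0$ — additive and
multiplicative no-interaction hypotheses are different claims.

## Confidence intervals

The default RERI interval is the multivariate delta method: with
$g = (-e^{\beta_{10}}, -e^{\beta_{01}}, e^{\beta_{11}})$ and $V$ the
3×3 coefficient covariance, $\mathrm{se} = \sqrt{g'Vg}$ and the interval
is the symmetric Wald band. The $S$ interval is a delta interval on
$\ln S$, back-transformed; it exists only when $\mathrm{OR}_{11} > 1$ and
the excess-odds denominator is positive — otherwise the package reports
the $S$ interval as undefined while keeping the RERI interval, rather
than printing a meaningless band. The regression-coefficient delta
method is the standard closed-form realisation of CI methods for
interaction contrasts; because the exact published formulation it stands
in for is not spelled out anywhere we could verify, a stratum-resampling
bootstrap (percentile intervals, seeded) is implemented as the
independent arbiter: the acceptance suite requires delta and 2,000-rep
bootstrap endpoints to agree within 10% of the interval width on a large
simulated cohort.

Within-stratum ("re-referenced") odds ratios — e.g. the OR of exposure
among carriers — are reported in two modes. `joint-model` forms them as
exact coefficient contrasts ($\mathrm{OR}_{11}/\mathrm{OR}_{01}$, CI from
the contrast variance); `stratified-refit` refits the conditional model
inside each genotype (or exposure) stratum, letting covariate effects
differ by stratum. The default is `stratified-refit` because published
within-stratum ORs in this literature are generally not equal to the
joint-model ratios, indicating refitting; both modes are available and
agree within Monte-Carlo error on large simulated cohorts (tested). A
refit whose subset is separable (common in sparse exposed-carrier
strata) returns `NA` rather than a divergent estimate.

## Exposure, genotype and QC conventions

* **Etiological window.** Exposure is 1 iff at least one event of the
  drug of interest falls in the *closed* interval
  `[index_date − window_days, index_date]`, default 7 days. The endpoint
  convention is not universal, so it is configurable; events after the
  index date are never exposure. Exposure is monotone in the window
  length by construction (a property test).
* **Dominant coding.** Genotype calls are unordered allele pairs; the
  carrier indicator is 0 only for the homozygous reference genotype, and
  missing calls propagate (a missing genotype is never recoded as
  wild-type). Codominant (0/1/2) coding is available as an option.
* **HWE QC.** Hardy-Weinberg equilibrium is tested in controls
  (deviation there suggests selection bias or genotyping error). Default
  is the 1-df Pearson chi-square at the estimated allele frequency; a
  full-enumeration exact test is provided for small counts and verified
  against direct factorial arithmetic. SNPs with HWE p below `alpha`
  (default 0.001) or call rate below 0.98 are *flagged, never dropped
  automatically* — the conventional direction of the p-threshold is easy
  to invert in prose, so the pipeline leaves the decision to the analyst.
* **Sparse cells.** Any SNP with fewer than 5 cases or 5 controls in an
  analysis cell is routed to a separate "inconclusive" table rather than
  interpreted.

## Covariate selection

The implemented procedure mirrors common epidemiological practice:
candidates pass a bivariate matched screen at Wald p < 0.2; backward
elimination from the full model then repeatedly tries to drop the
candidate with the largest Wald p, accepting the drop only when **(i)**
no exposure-term coefficient changes by more than 10% and **(ii)** the
BIC, $-2\ell + k\log(\text{strata})$, improves. The change-in-estimate
comparison is made on the log-odds scale by default (the OR scale is a
config option) because the coefficient scale is the one on which the
model is linear; whether published 10%-change rules mean coefficients or
ORs is usually unstated, so both are offered. With `cie = 0` nothing can
be dropped unless the exposure coefficients are exactly unchanged — a
limit behaviour covered by a test.

## The synthetic-data generator

`simulate_cohort()` exists so that every downstream stage has a known
truth. It generates an explicit source population — genotypes under HWE
at the configured minor-allele frequency, binary confounders, exposure
with confounder-dependent odds, disease by Bernoulli draws whose odds are
`base_odds` times the four-cell multiplier times confounder effects —
then samples cases and matches controls from the non-cases on center,
sex and 5-year age band. Sampling from an explicit population makes the
built-in odds ratios exact by construction (no rare-disease
approximation: odds, not risks, are multiplied), which is what a
parameter-recovery oracle needs. The "both"-cell OR is derived from the
target RERI as $\mathrm{OR}_{11} = \mathrm{OR}_{10} + \mathrm{OR}_{01} - 1
+ \mathrm{RERI}$, so `truth$true_reri` is exact by definition.

Defaults mirror the motivating study design: 326 case strata matched
1:3, four centers, two enrolment periods, ~73% male, aspirin exposure
prevalence 2.5% among controls, minor-allele frequency 0.30, and the
four-cell pattern (3.42, 0.85, 8.22) of a strong positive modifier.
Covariate marginals (BMI class, H. pylori, arthrosis, interview
reliability, and so on) are drawn to resemble the study population's
one-way distributions.

What the generator does **not** emulate: linkage disequilibrium between
SNPs (each SNP is independent), the joint distribution of covariates
beyond their margins, genotyping error, recall bias in drug histories,
or dates with seasonal structure. Passing the recovery and calibration
tests therefore shows the estimator chain is correct under a faithful
matched design with exact odds structure — it does not certify behaviour
under misspecified real-world data.

## Numerical choices

* Newton-Raphson with step-halving; convergence when the score's maximum
  absolute entry falls below `1e-8` or the relative log-likelihood change
  below `1e-10`; at most 100 iterations (exceeding them is an error
  carrying the trace, not a silent return).
* Within-stratum log-sum-exp is max-shifted for stability.
* Coefficients beyond ±15 log-odds are reported as (quasi-)complete
  separation via a warning; no penalised correction is applied.
* Stratum-constant design columns are removed before fitting (they are
  unidentified in the conditional likelihood) with a message.
* Display rounding (2 dp, matching the field's tables) happens only at
  render time; all stored values keep full precision, and a test checks
  that RERI recomputed from stored ORs matches the stored RERI to 1e-12.

## Problem sizes used by the verification suite

The stochastic checks run at sizes chosen to make their asymptotic
claims meaningful while staying desk-scale: end-to-end RERI recovery
uses 3,000 strata (12,000 subjects) against a 3-standard-error band;
null calibration uses 500 replicates of 250 strata with exposure
prevalence 0.25 (so the exposed cells are populated under the null) and
checks delta-interval coverage of 0 against binomial 99% bounds around
0.95; delta-vs-bootstrap agreement uses one cohort of 2,000 strata and
2,000 bootstrap replicates. The null-calibration exposure prevalence is
deliberately higher than the study-like default: coverage of a Wald-type
interval is an asymptotic property and is not expected to hold with
near-empty cells, which the "inconclusive" gating exists to intercept.

## Known limitations

* No random-effects (integral-approximation) GLMM solver, by design; see
  above for why the conditional likelihood replaces it under this
  matched design.
* No Firth-type correction for separation — separation is reported, and
  sparse-cell SNPs are gated out of the main table instead.
* No multiple-testing correction across SNPs is applied by default (the
  per-SNP tables are exploratory, as in the motivating literature); any
  correction can be applied downstream to the stored p-values.
* The delta interval for S is undefined when the single-factor excess
  odds sum to zero or the joint OR is below 1; the bootstrap can still
  produce an interval there, but its interpretation is doubtful and the
  package does not pretend otherwise.
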