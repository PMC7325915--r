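# reriscan

Additive-scale gene–environment interaction analysis for individually
matched (1:m) case–control studies, with a focus on SNP × drug-exposure
effects on a binary outcome such as upper gastrointestinal hemorrhage
(UGIH) in aspirin users.

## The scientific problem

Case-only and exposed-only designs cannot separate the risk contributed by
a drug, by a genetic variant, or by their joint presence. A *full*
case–control design classifies every subject into four categories by
exposure E and dominant carrier status G —

| category | exposure | genotype |
|---|---|---|
| reference | E− | wild-type |
| exp-only | E+ | wild-type |
| carrier-only | E− | variant carrier |
| both | E+ | variant carrier |

— and estimates the adjusted odds ratio of each category against the
reference. Interaction on the **additive** scale (the scale relevant for
public-health excess risk) is then measured by the *Relative Excess Risk
due to Interaction* and the *synergism index*:

```
RERI = OR11 − OR10 − OR01 + 1
S    = (OR11 − 1) / ((OR10 − 1) + (OR01 − 1))
```

where OR11 is the "both" cell, OR10 the exposed wild-type cell and OR01
the unexposed carrier cell. RERI = 0 (S = 1) means the joint excess odds
is exactly the sum of the single-factor excesses; RERI > 0 flags positive
effect modification.

Because each case is matched to up to three controls on age band, sex and
center, the package estimates the cell ORs with the **matched-set
conditional logistic likelihood**

```
l(β) = Σ_strata [ x_case'β − log Σ_{j ∈ stratum} exp(x_j'β) ]
```

maximized by an exact Newton–Raphson solver (analytic gradient and
Hessian, step-halving, separation diagnostics). Conditioning on the
matched set absorbs every stratum-constant covariate, including the
matching variables, recruitment center and enrolment period. Confidence
intervals for RERI and S come from the multivariate delta method on the
coefficient covariance, with a stratum-resampling bootstrap as an
independent check.

The package also provides:

* cohort I/O for delimited subject tables (genotypes as `A/G` pairs,
  dated drug events, covariates), with typed validation and an exclusion
  log;
* derivation of binary exposure from a 7-day etiological window before
  the index date (events after the index date never count);
* per-SNP QC: genotype counts in controls, call rate, minor-allele
  frequency, chi-square and exact Hardy–Weinberg equilibrium tests;
* the conventional covariate workflow: bivariate screening at p < 0.2,
  then backward elimination accepting a drop only when no exposure
  coefficient moves by more than 10% and the BIC improves;
* presentation tables following the reporting recommendations for
  interaction analyses, with SNPs segregated as *inconclusive* when any
  analysis cell holds fewer than 5 cases or controls;
* a seeded matched-cohort simulator whose four-cell odds structure (and
  hence true RERI and S) is set by configuration, used throughout the
  test suite for parameter-recovery and calibration checks.

## Worked example

Simulate a matched cohort whose generator builds in the four-cell odds
pattern (1, 3.42, 0.85, 8.22) — a known true RERI of 4.95 — and run the
full pipeline:

```r
library(reriscan)
cfg <- sim_config(n_strata = 1500, seed = 2026)
sim <- simulate_cohort(cfg)
run <- run_pipeline(sim$cohort, rereference_mode = "joint-model")
run$results$rs689466$stratum_ors
#> Joint-classification odds ratios (reference = unexposed wild-type):
#>          cell n_cases n_controls     or  lower   upper
#>           ref     700       2041 1.0000     NA      NA
#>      exp_only      50         29 4.8995 3.0551  7.8574
#>  carrier_only     621       2141 0.8423 0.7426  0.9553
#>          both     129         40 9.7517 6.6348 14.3329
run$results$rs689466$interaction
#> RERI = 5.01 (95% CI 0.69 to 9.33) [delta]
#> S    = 2.34 (95% CI 1.12 to 4.90)
#> AP   = 0.51
```

The estimated RERI of 5.01 recovers the generator's truth of 4.95 well
within its confidence interval; the interval excludes 0, as it should for
a strong built-in positive modifier at this sample size. The per-SNP QC
table confirms the simulated controls sit at Hardy–Weinberg equilibrium:

```r
run$hwe
#>     snp_id n_AA n_Aa n_aa       maf call_rate      chi2   p_value flags
#> 1 rs689466 2070 1776  405 0.3041637         1 0.7208768 0.3958565
```

A thin command-line front end is included at `inst/cli/reriscan.R`
(`simulate`, `hwe` and `run` subcommands over YAML configs).

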