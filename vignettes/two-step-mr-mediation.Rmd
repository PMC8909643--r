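---
title: "Two-step MR mediation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step MR mediation: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

The package implements a two-step, two-sample Mendelian randomization
(MR) mediation analysis. The structural picture is

```
          alpha              beta_m
exposure ------> mediator(s) ------> outcome
    \_________________________________/
                  beta_d
```

Genetic variants instrument the exposure; the *total* causal effect of the
exposure on the outcome is `beta_d + sum(alpha_m * beta_m[m])`. Step 1
estimates each `alpha_m` by univariable MR of the exposure on the mediator.
Step 2 estimates each `beta_m[m]` — the mediator's *direct* effect on the
outcome conditional on the exposure — by multivariable MR (MVMR). The
mediated (indirect) effect of mediator m is the product `alpha_m * beta_m[m]`,
and the proportion mediated divides it by the total effect. A combined
mediation over all mediators uses the *difference* method instead: total
effect minus the exposure's direct effect adjusted for all mediators
jointly, divided by the total effect.

All binary-trait effects are carried internally on the natural-log-odds
scale; odds ratios are presentation-layer `exp(beta)`. Continuous traits
are in SD units, so `alpha` is SD per log-odds and `beta_m` is log-odds per
SD.

### Identifying assumptions

Each estimator inherits the usual instrumental-variable assumptions
(relevance, independence from confounders, exclusion restriction), plus:

* **IVW** assumes all instruments valid; the multiplicative
  random-effects variant (the default) only inflates the SE by
  `sqrt(max(1, Q/(J-1)))` and never tightens it below the fixed-effect SE.
* **MR-Egger** relaxes exclusion to the InSIDE condition (pleiotropic
  effects independent of instrument strength) and estimates the average
  directional pleiotropy as an intercept.
* **Weighted median** is consistent while less than half the total weight
  sits on invalid instruments.
* **MR-PRESSO** detects individual pleiotropic outliers through their
  contribution to the residual sum of squares around the leave-one-out
  IVW fit.
* **Mediation calculus** additionally assumes the step-1 and step-2
  estimates are independent (reasonable in the two-sample setting, where
  they come from non-overlapping datasets) and that indirect and total
  effects may be treated as independent in the quotient SE. The shipped
  propagation rules are first-order (delta method) with no covariance
  terms; this is a documented limitation, not an oversight — shared
  instruments induce some correlation that the CIs ignore.

## Estimators and their numerical conventions

* **Wald ratio**: `by/bx` with first-order SE `sy/|bx|`; exposure-side
  uncertainty is ignored (NOME). This is the standard summary-data default
  when instruments are strong; the instrument module enforces/flags
  F = (β/σ)² > 10 precisely so this approximation is tenable.
* **IVW**: `β̂ = Σ bx·by/sy² / Σ bx²/sy²`, fixed SE `sqrt(1/Σ bx²/sy²)`.
  Cochran's Q is computed as `Σ (by − β̂·bx)²/sy²`, algebraically the
  weighted squared deviation of Wald ratios from β̂ but stable at
  `bx = 0`. Default model is multiplicative random effects: with
  100+ instruments some heterogeneity is the norm, and `max(1, ·)` makes
  it never anti-conservative relative to fixed effects. P-values are
  two-sided normal.
* **MR-Egger**: weighted least squares *with* intercept after orienting
  every SNP so `bx ≥ 0` (Egger is not orientation-invariant; a fixed
  convention is required for reproducibility). SEs carry
  `max(1, RSS/(J−2))` dispersion; inference uses the t distribution with
  J−2 df, the small-sample convention for Egger.
* **Medians**: the estimate interpolates the cumulative standardized
  weight `p_j = (cumsum(w) − w/2)/sum(w)` over ascending ratios at 0.5.
  SEs come from a seeded parametric bootstrap (default 1000 draws)
  resampling both `bx` and `by` from their sampling distributions,
  mirroring the originating median-estimator literature. The bootstrap
  runs in a private RNG scope: it never perturbs the caller's stream.
* **MVMR**: weighted least squares of `by` on the J×K matrix of exposure
  effects, no intercept, weights `1/sy²`; dispersion `max(1, RSS/(J−K))`,
  normal p-values. `J ≤ K` raises an insufficient-instruments error (the
  pipeline records such pairs as failures rather than aborting); a
  rank-deficient design names the offending exposures. With K = 1 the
  point estimate reproduces univariable fixed-effect IVW exactly, and the
  SE matches the random-effects IVW because J−K = J−1.
* **MR-PRESSO**: observed statistic
  `RSS = Σ (by_j − β̂(−j)·bx_j)²/sy_j²` with leave-one-out IVW
  expectations; the null distribution comes from `nsim` parametric
  redraws `by* ~ N(β̂(−j)·bx, sy²)` with the statistic recomputed
  identically, so empirical p-values carry add-one smoothing and are
  bounded below by `1/(nsim+1)` — with the default `nsim = 1000` and J
  instruments, a per-SNP Bonferroni-adjusted outlier p-value can reach
  significance only when `J/(nsim+1) < 0.05`; raise `nsim` for large J.
  The distortion test re-assigns the outlier labels to randomly chosen
  *non-flagged* SNPs: the null then describes removing unremarkable SNPs
  of the same count, so a heavy outlier's removal registers as
  significant while a negligible-weight outlier's does not.

### Eligibility gates and multiplicity

The pipeline applies two suggestive gates at p < 0.05: a mediator must be
causally shifted by the exposure (step 1) and must causally shift the
outcome conditional on the exposure (step 2); failures are flagged
`excluded_step1` / `excluded_step2` and excluded from mediation rows and
from the combined adjustment set. Bonferroni thresholds (0.05 / family
size, e.g. 0.025 for a 2-trait family) are *annotated* per mediator family
but do not gate eligibility: families are a reporting construct for
mediators drawn from shared data sources, supplied explicitly as
configuration.

### Harmonization

All tables are aligned to the first exposure's effect allele: identical
alleles pass; swapped alleles negate the effect and reflect the frequency;
strand complements map through A↔T / C↔G first. Palindromic (A/T, C/G)
SNPs are unresolvable from alleles alone; the default policy drops them
when either side's effect-allele frequency is missing or within
(0.42, 0.58) and otherwise aligns by frequency — the conservative
convention, configurable to always-drop. Duplicate variant rows keep the
smallest p-value; every drop is logged with a reason. Harmonization of
already-aligned inputs is a no-op.

## The synthetic-data generator

`simulate_mediation_sumstats()` emulates the two-sample summary-statistic
setting directly: no individual genotypes, observed effects are
truth + Normal(0, se²), SEs are supplied scales standing in for 1/√N, and
the LD matrix is identity (instruments post-clumping are approximately
independent). Defaults are sized to a modern consortium-scale design:

* 143 exposure instruments (the scale of a current type 2 diabetes
  instrument set), per-SNP effects |N(0, 0.04²)| on the log-odds scale
  with exposure SE 0.004, giving typical F-statistics in the 25–100
  range;
* effect alleles labeled exposure-increasing — the convention of
  published instrument tables — which is what gives *directional*
  pleiotropy a well-defined sign;
* 50 instruments per mediator with effects N(0, 0.03²) and mediator SE
  1/√450000 ≈ 0.0015, matching the sample size written into the tables
  (an SE inconsistent with N would silently attenuate MVMR through
  design-matrix measurement error);
* outcome SE 0.01 (a six-figure case-control GWAS);
* structural defaults `alpha = 0.5`, `beta_m = 0.4`, `beta_d = 0.1`:
  total effect 0.3 with two thirds mediated;
* horizontal pleiotropy off by default; `invalid_fraction`,
  `pleiotropy_mean`, `pleiotropy_sd` switch on balanced or directional
  violations for diagnostic testing.

What the generator does **not** emulate: LD between instruments, liability
-scale subtleties of binary outcomes, winner's-curse-inducing overlap
between discovery and analysis samples, allele-frequency-dependent effect
sizes, and population stratification. Passing tests therefore demonstrate
estimator correctness and calibration under the stated model, not
robustness to every failure mode of real consortium data.

## Verification choices

* Estimators are checked against independent closed-form oracles (IVW as
  the weighted mean of Wald ratios; Egger against textbook weighted
  regression algebra; MVMR against exact linear solves).
* Parameter recovery runs the realistic route — genome-wide selection at
  5×10⁻⁸, then estimation — over 200 seeded replicates at the default
  truth; at consortium-scale SEs winner's curse is negligible and
  coverage sits at the nominal 95%.
* Calibration of the Egger intercept and PRESSO global tests is evaluated
  under the diagnostics' own null: valid instruments with *fixed*
  exposure effects, matching the first-order (NOME) convention the tests
  are defined under. With per-SNP exposure-side noise included instead,
  residuals inflate by ≈ `(β·se_x/sy)²` and the PRESSO global test
  rejects slightly above nominal (≈0.08 at J=143 in our measurements) —
  a known property of the NOME approximation worth remembering when
  interpreting borderline global p-values on real data.
* Problem sizes in the test-suite simulations (200–500 replicates,
  `nsim = 200` for PRESSO calibration, J = 50–150) were chosen to keep
  the default test run fast while leaving Monte-Carlo error well inside
  the asserted bands.

## Known limitations

* No covariance terms in the delta-method SEs (shared instruments across
  steps induce correlation the CIs ignore).
* NOME throughout: exposure-side uncertainty is not propagated into Wald,
  IVW, Egger or PRESSO (median bootstraps do resample it).
* LD clumping requires an explicit r² matrix; there is no reference-panel
  computation or positional windowing.
* MVMR reports no conditional F-statistics; a marginal weak-instrument
  warning is the only gate.
* The worked-example reproduction is bounded by the rounding of published
  inputs: two-decimal odds ratios limit agreement to roughly one
  percentage point, and pairs whose published proportions came from
  unrounded internal values (e.g. an MI/SBP row) can deviate by two.
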