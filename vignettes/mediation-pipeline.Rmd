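---
title: "Methods: genotype-brain-behavior mediation with neuromediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-brain-behavior mediation with neuromediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromediate)
```

## The model

`neuromediate` implements a three-stage inference chain for candidate-gene
imaging-genetics cohorts. The causal variable X is a two-level
minor-allele-carrier coding of a biallelic marker (1 = at least one minor
allele). The candidate mediator M is a normalized regional morphometry
measure, and the outcome Y a behavioral score (here an attention-problems
T score averaged over assessment waves). All three stages adjust for age
and gender.

The mediation stage fits the covariate-adjusted single-mediator model.
After Z-scoring X, M and Y:

* `M ~ X + age + gender` gives the path **a**,
* `Y ~ X + age + gender` gives the total effect **c**,
* `Y ~ X + M + age + gender` gives the direct effect **c′** and the path
  **b**,

and the indirect effect is **ab = a·b**. Because the same covariates
enter all three ordinary-least-squares regressions, the decomposition
`c = c′ + a·b` is an exact algebraic identity, which the test suite
asserts to 1e-10 on every dataset it touches. The proportion mediated is
`100·ab/c`, reported only when `ab` and `c` agree in sign — when they
disagree ("inconsistent mediation") the ratio misrepresents the
mechanism, so it is flagged instead.

Standardizing a binary X is an affine map, so it changes no t-statistic
or p-value; it is done anyway so that every coefficient is reported on
the same standardized scale.

## Inference: bootstrap BCa, gating, permutation

Primary inference is a case-resampling bootstrap: subjects are drawn with
replacement (whole rows — X, M, Y and covariates together) and all paths
are refit per resample; 5000 resamples by default, always seeded.
Standardization is performed once on the observed data and resamples
reuse the standardized rows; re-standardizing inside each resample would
distort the bias-correction term. Resamples in which X happens to be
constant cannot be fit and are redrawn (their count is reported; more
than 10% is an error, signalling a sample too small for resampling
inference). Within each resample the total effect is obtained through the
identity `c = c′ + a·b` rather than a third regression; the identity is
verified independently on the observed-data route, where c is fit by its
own regression.

Confidence intervals use the bias-corrected and accelerated (BCa)
construction: the bias term `z0` is the normal quantile of the fraction
of resamples below the point estimate, the acceleration is the jackknife
skewness of leave-one-out estimates, and the corrected levels are applied
to type-6 (Hazen-interpolated) quantiles of the resample distribution —
the quantile convention is fixed so that endpoints are reproducible
bit-for-bit given a seed. Because the BCa literature defines intervals,
not p-values, the p-value is defined by interval inversion: the smallest
two-sided level at which the BCa interval excludes zero, found by
bisection to 1e-4. When even the widest resolvable interval excludes zero
the p-value is reported as the bound `2/n_resamples` and flagged.

Mediation prerequisites are enforced as gating: the indirect effect `ab`
and the direct effect `c′` are evaluated only when a, b and c are all
significant at the chosen level; otherwise they are reported as "n.e."
(not evaluated), mirroring how such analyses are reported when a
prerequisite path is absent. When the prerequisites hold, the result is
labeled *partial mediation* if `c′` remains significant and
*indirect-dominant* otherwise.

A Freedman–Lane permutation test is available as a clearly-labeled
secondary p-value for every path: the residuals of the reduced model (the
model without the tested predictor) are permuted while the covariate
structure is preserved. For the composite `ab`, the covariate-residualized
X is permuted, breaking the X→M and X→Y links jointly under the null of
no genotype effect. The two inference routes (bootstrap BCa and
permutation) agree in accept/reject on the large majority of
moderately-powered synthetic datasets, which the suite checks.

## Genotype QC choices

* **HWE test.** The default is the exact test conditional on observed
  allele counts — appropriate at n = 58, where genotype counts are small —
  computed by the numerically stable ratio recurrence over heterozygote
  counts; a chi-square (1 df) variant is available. The exact two-sided
  convention sums the probabilities of all heterozygote configurations no
  more probable than the observed one. Note that the exact convention
  orders outcomes by conditional probability while the chi-square orders
  by the statistic, so their p-values typically agree at large n but can
  differ by a few hundredths in individual draws, most visibly at low
  minor-allele frequency; the suite therefore checks median agreement
  over replicates.
* **LD r².** Unphased genotypes are phased only implicitly, through a
  two-locus EM over the four haplotype frequencies (the double
  heterozygote being the only ambiguous configuration), with at most 1000
  iterations and a 1e-10 convergence tolerance — the same estimator the
  standard haplotype-browser tooling uses. r² is undefined (and flagged,
  not zeroed) when a marker is monomorphic.
* **Carrier coding.** Heterozygotes and minor homozygotes code 1, major
  homozygotes 0, missing propagates. At a frequency tie (MAF = 0.5) the
  lexicographically smaller allele label is "minor", so results are
  deterministic. Allele labels are opaque strings, so a deletion allele
  written "-" needs no special treatment.
* **Missingness** is handled by pairwise-complete deletion per
  computation, with the excluded counts always reported.

## Screening choices

Each screening model is a four-column OLS design (intercept, gender, age,
predictor), so 58 complete cases give 54 error degrees of freedom.
Volume outcomes are divided by total intracranial volume and surface-area
outcomes by total cortical surface area before fitting — a ratio
normalization, the minimal reading of a "normalization factor"; thickness
enters raw. The multiple-comparison correction for the large SNP →
morphometry design is Bonferroni with a configurable divisor, default 31
(one hemisphere's region count), which reproduces the conventional
corrected threshold 0.05/31 ≈ 0.0016 at α = 0.05. The divisor is printed
with every report because reasonable alternatives (number of regions ×
features × markers) differ and published thresholds are not always
arithmetically consistent with the stated family size. Triads are passed
to mediation only when all three designs agree: the marker affects the
outcome (uncorrected), the marker affects the ROI feature (corrected),
and the ROI feature affects the outcome (uncorrected). Each selected
triad is mediated independently; no joint multi-mediator model is fit.

The default region list contains 31 of the 34 Desikan-Killiany regions
per hemisphere (62 ROIs, hence 62 × 3 features × 6 markers = 1116 models
in the first design). Which three regions a given study excluded is often
unstated; the default drops the banks of the superior temporal sulcus and
the frontal and temporal poles — the smallest and least reliably measured
parcels — and every function accepts an explicit region list, so the
choice is overridable and documented as a choice, not a fact.

## The synthetic-cohort generator

The generator exists so the chain can be validated end to end without
subject data. Its defaults mirror the target study design: n = 58,
six markers at minor-allele frequencies (0.29, 0.34, 0.27, 0.26, 0.16,
0.22), 62 ROIs × 3 features, age ~ U(6, 17) years, 42/58 male fraction.
Genotypes are independent HWE draws; marker pairs can instead be drawn
from two-locus haplotypes whose frequencies imply a target r² (positive-D
construction).

Planted effects are defined on the standardized population scale so that
fitted standardized coefficients are directly comparable to generating
values: the carrier code is standardized by its population moments, each
planted mediator is `M = a·X + 0.1·age + 0.1·gender + noise` and the
outcome `Y = c′·X + Σ bᵢ·Mᵢ + 0.1·age + 0.1·gender + noise`, with
residual variances chosen analytically so every generated variable has
unit population variance (a specification with implied |c| ≥ 1 is
rejected as unidentifiable). The small covariate effects exist so that
covariate adjustment is actually exercised rather than vacuous. Several
planted triads must share one causal marker and the one outcome, the
configuration that mirrors a study mediating one SNP through several
regions.

Morphometry is written back on a realistic positive scale: planted and
noise ROIs get a normalized-scale value (e.g. volume/ICV ≈ 0.0035 ±
0.00035) multiplied by the subject's own global (ICV ~ N(1.45·10⁶,
1.2·10⁵) mm³, total surface ~ N(1.7·10⁵, 1.5·10⁴) mm²), so the pipeline's
ratio normalization recovers the planted structure exactly; the location
and spread constants are arbitrary plausible magnitudes and documented as
such. The outcome is written as T-score-like `60 + 8·Y`. What the
generator does **not** emulate: realistic cortical covariance between
regions (unplanted ROIs are independent noise), longitudinal wave
dynamics of the behavioral score, genotyping error, or population
structure — so passing tests demonstrate correctness and calibration of
the statistical machinery under the assumed linear model, not robustness
to those real-data complications.

## Numerical and validation notes

* Simulation problem sizes used by the suite: parameter recovery uses
  1000 cohorts of n = 58 (observed absolute bias of a, b, c well under
  0.02); BCa coverage for path a uses 1000 cohorts × 1000 resamples
  (coverage ≈ 0.97); the type-I error of the indirect-effect test uses
  500 datasets × 1000 resamples under a = 0 with b and c′ at their study
  values (rejection ≈ 0.03, within the binomial 99% band around 0.05).
  Product-of-coefficients tests are intrinsically conservative when the
  non-null path is itself weakly determined; with a strong b the
  rejection rate moves to the nominal level, which is why the
  calibration is read against a band rather than a point.
* The exact HWE p-value is discrete and conservative by construction, so
  its null distribution is only approximately uniform; validity
  (P(p ≤ α) ≤ α, up to simulation error) is the property the suite
  asserts.
* Published mediation tables sometimes print confidence intervals that
  cannot bracket their own estimates (e.g. an estimate of −0.45 against
  an interval [−0.26, 0.26]); such intervals look null-referenced rather
  than estimate-centered. `neuromediate` reports estimate-centered BCa
  intervals and makes no attempt to reproduce interval values of that
  form.
* Degenerate inputs fail loudly and early: constant predictors, collinear
  designs (|r| > 0.999 between X and M), non-positive globals, duplicate
  subjects or result rows, half-missing genotype calls, and bootstrap
  distributions entirely on one side of the estimate all raise errors
  naming the offending column or subject.

## Limitations

Single mediator per model, two-locus LD only, no imputation or
population-structure modeling, no FDR-style alternatives beyond the
Bonferroni divisor, no moderated or longitudinal mediation, and no
causal-sensitivity analysis (sequential ignorability is assumed, as in
any observational mediation analysis). At n = 58 the screening designs
have modest power at the corrected threshold; a planted standardized
effect of 0.5 is detected in roughly 85% of replicates, so null screening
results on cohorts of this size are weak evidence of absence.
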