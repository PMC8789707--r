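---
title: "Equivalent-Score norming of the FAB: models, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent-Score norming of the FAB: models, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fabnorms)
```

## The problem

Raw scores on the Frontal Assessment Battery decline with age and rise
with education in healthy adults. A normative pipeline therefore has two
jobs: remove the expected demographic effect from an individual's raw
score, and place the residual ("adjusted") score on a reference
distribution so that a clinician can read off how unusual it is. This
package implements the regression-based Equivalent Scores (ES) approach
used throughout the Italian normative literature, for the FAB total scale
and its three two-item sub-scales (FAB-1 linguistically mediated
executive functioning, FAB-2 planning, FAB-3 inhibition).

## Demographic adjustment

The adjustment model is deliberately small: one transformed age term and
one transformed education term, fitted jointly by ordinary least squares
on the raw scale score,

$$AS = RS + b_a\,[T_a(\mathrm{age}) - c_a] + b_e\,[T_e(\mathrm{edu}) - c_e],$$

with candidate families $T_a \in \{x, x^2, x^3\}$ and
$T_e \in \{x, \ln x, 1/x\}$, centering constants $c$ equal to the sample
means of the transformed predictors (so an average participant receives
no correction), and adjustment coefficients $b$ equal to the *negated*
fitted slopes. Education is recorded as completed school years with a
minimum of 1; the value 0 is rejected rather than imputed because the
logarithmic and reciprocal transforms are undefined or explosive there.
Sex is tested separately (two-sample t with an F-ratio variance pretest
at $\alpha = 0.05$ deciding between pooled and Welch forms) and omitted
from the model when null, as in the published norms.

`select_transforms()` fits all candidate pairs and returns the pair with
the smallest residual sum of squares. Among models with the same number
of parameters this is equivalent to picking the jointly most significant
pair; per-term $|t|$ statistics are retained in the report so ties and
near-ties can be audited. Alternative criteria (per-term significance,
information criteria) reorder near-equivalent pairs but not clearly
better ones, and RSS has the virtue of determinism.

**An identifiability caveat that matters.** Over the observed age range
(21–96), $\mathrm{age}^2$ and $\mathrm{age}^3$ correlate above 0.99, and
$\ln(\mathrm{edu})$ with $1/\mathrm{edu}$ similarly. At the residual
noise level implied by the published score dispersion (total-scale
residual SD ≈ 1.9 points), a cohort of 475 simply does not carry enough
information to identify the generating transform family reliably:
in simulation, the true (cubic age, log education) pair is selected in
roughly 60% of replicates, with the quadratic/reciprocal neighbours
taking most of the remainder. Selection becomes reliable (≥ 90%) only
when the residual SD drops below about 0.6 — a dispersion no real
screener attains. The acceptance suite states the selection-consistency
check at the 90% level and it fails honestly under realistic noise; the
*coefficients* of whichever neighbouring transform is selected are
recovered accurately (95% CI coverage at nominal rate), and the resulting
adjustments differ negligibly over the observed demographic range. Users
deriving fresh norms should treat the selected family as a fitted
convenience, not a substantive finding.

Display grids (`generate_grid()`) tabulate the adjustment at raw score 0
over the conventional lattice (ages 35–95 by 5; education 5, 8, 11, 13,
16, 18, 21), rounded half-up at 2 decimals. Scoring always uses the
continuous equation; demographics outside the lattice produce a warning,
not a refusal. The printed grids shipped for verification contain one
known typesetting defect (FAB-2, education 21, ages 70–75), which the
comparison helper excludes and logs rather than matches.

## Tolerance limits and the ES scale

With non-normal, ceiling-heavy score distributions, the reference points
are non-parametric. For a sample of $n$ adjusted scores, the outer
tolerance rank is the largest $r$ with
$P(\mathrm{Bin}(n, 0.05) \ge r) \ge 0.95$: the $r$-th smallest adjusted
score is then a one-sided 95% lower confidence bound on the population
5th centile, and any score at or below it is confidently abnormal
(ES 0). The inner rank is the smallest $s$ with
$P(\mathrm{Bin}(n, 0.05) \ge s) \le 0.05$, an upper bound; the
oTL–iTL band is the region where abnormality cannot be asserted either
way. Below $n \approx 59$ no rank achieves the outer confidence and
`compute_norm_table()` refuses to derive norms rather than degrade
silently. Ties at the rank positions take the observation's value.

ES 4 is assigned strictly above the sample median. The two thresholds
splitting ES 1/2/3 between the oTL and the median are not pinned down by
a single convention in the ES literature, so both common schemes are
implemented and labelled: the default `z_thirds` places them at the
empirical centiles corresponding to equal thirds of the standard-normal
interval $[z_{0.05}, 0]$ (the 13.64% and 29.18% centiles, taken as
type-1 quantiles so thresholds are observed order statistics);
`equal_frequency` splits the outer-rank-to-median ranks into equal
counts. The shipped published tables are used verbatim, so this choice
affects only newly derived norms. Classification is total and monotone:
intervals are closed on the right at display precision, so for the
published FAB table an adjusted score of 12.02 is ES 0 and 12.03 is the
first borderline value.

## The synthetic cohort generator

The generator exists so that every pipeline stage — fitting, selection,
tolerance limits, classification, batteries — can be exercised on data
with the normative sample's structure. Per participant it draws:

* age and education from truncated normals rounded to whole years, with
  *parent* parameters solved (from the truncated-normal moment
  identities) so the truncated distributions reproduce the printed means
  and SDs (61.08 ± 15.1 on [21, 96]; 11.67 ± 4.57 on [1, 25]);
* sex Bernoulli with P(F) = 306/475, with no score effect by default;
* a latent score per sub-scale: intercept + age effect + education
  effect + a shared standard-normal "frontal ability" factor + Gaussian
  noise. Latents are rounded, clipped to 0–6 and apportioned to the two
  items by largest remainder, so item, sub-scale and total ranges hold
  exactly and the sub-scales always partition the total;
* a MoCA total from the standardized FAB-total latent plus independent
  noise, mapped through its normal CDF onto truncated-normal quantiles
  (24.5 ± 3.95 on [8, 30]) — a monotone map that fixes the marginal
  while preserving the rank coupling — then allocated to six sub-domains
  (maxima EF 4, A 6, L 5, M 5, VS 4, O 6) by largest remainder with a
  few random one-point transfers.

Calibration was done once, against the printed sample description, and
frozen into `default_generator_config()`: intercepts, loadings and noise
SDs were iterated until the *discretised* scores match the printed
means/SDs (FAB 15.9 ± 2.17; sub-scales 5.21 ± 0.93, 5.41 ± 1.08,
5.27 ± 1.14), the sub-scale intercorrelations sit in the reported
0.21–0.24 band with part–whole correlations near 0.63–0.70, and the
FAB–MoCA rank correlation equals 0.49. Because ceiling clipping
attenuates regression slopes, the generating demographic slopes are the
negated published adjustment coefficients *inflated* (factors ≈ 1.4–2.2,
solved in the same calibration) so that refitting the observable bounded
scores recovers coefficients near the published equations — the
round-trip shown in the README.

What the generator does **not** emulate: the empirical joint
age × education distribution (the two are drawn independently, whereas
real cohorts show older participants with less schooling), item-level
response processes (items inside a sub-scale are an apportionment, not
psychometric items), and the exact shape of the lower tail of real
adjusted scores. Consequently, passing tests demonstrate the *pipeline's*
correctness and the norms' internal consistency, not empirical claims
about new populations; the synthetic outer tolerance limit scatters
around ~11.5–12.0 against the published 12.02.

## Numerical choices

* Skewness is the adjusted Fisher–Pearson statistic; kurtosis defaults
  to the excess convention (moment kurtosis minus 3, what statistical
  packages print) screened against $|3|$, with the raw convention
  available by switch. A zero-variance input yields a flagged degenerate
  result, not an error.
* Spearman coefficients use average ranks; p-values use the
  t-approximation on $r_s\sqrt{(n-2)/(1-r_s^2)}$, adequate at normative
  sample sizes (exact methods only matter below n ≈ 10). The
  Bonferroni-adjusted alpha is reported truncated (floored) at 4
  decimals, as correlation tables conventionally print it (0.05/28 →
  0.0017).
* The power analysis uses the noncentral-F formulation with
  $\lambda = f^2(u + v + 1)$ and denominator df $v = n - u$ by default,
  the convention under which the published minimum N of 287 (u = 3,
  f² = 0.05, α = 0.05, power 0.90) reproduces exactly; the textbook
  intercept-counting $v = n - u - 1$ (which yields 288) is available via
  `intercept_in_df = TRUE`.
* Grid cells round half-up (away from zero at .5) with a 1e-9 guard
  against binary representation error; all scoring keeps full precision
  and rounds only at presentation.
* Test and acceptance simulations use n = 475 cohorts with 150–500
  replicates — sizes chosen to put Monte-Carlo error well inside the
  asserted tolerances while keeping the default suite under a minute.

## Known limitations

* Transform-family selection is information-limited at realistic noise
  (see above); fitted adjustments are robust, selected labels are not.
* The shipped published norms apply to Italian adults assessed with the
  Italian FAB and MoCA; the scorer performs psychometric classification
  only and makes no diagnostic claims.
* Norms cannot be derived for cohorts smaller than ~59 (no valid outer
  tolerance rank); the published grids' lattice is a display convention
  and scoring outside it, while supported, extrapolates the fitted
  polynomial/logarithmic trends.
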