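---
title: "Linking the 4- and 5-item SWLS by proration: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking the 4- and 5-item SWLS by proration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swlslink)
```

## The linking model

The Satisfaction With Life Scale (SWLS) totals five 7-point items into a
5–35 score. When only the first four items are administered — the modified
form preferred in traumatic-injury populations, where the fifth item
functions poorly — the 5-item total is estimated by proration: the missing
item is imputed with the mean of the four observed items,

$$\hat{T}_5 = S_4 + \tfrac{S_4}{4} = 1.25\,S_4, \qquad S_4 = \sum_{j=1}^4 x_j .$$

The estimator is linear in $S_4$, so it commutes with averaging: a group's
prorated mean is $1.25 \times \overline{S_4}$, identical to the mean of the
individual prorated scores. Its assumptions are those of any
mean-imputation proration: a high proportion of items observed (4 of 5),
similar item–total correlations, and high internal consistency. It also
guarantees, by construction, that every prorated score falls inside the
real range of the scale — unlike regression or normality-based linking.
Alternatives such as multiple imputation or full-information maximum
likelihood can reduce bias but need modelling software; proration is the
deliberately simple estimator this package implements, and no
regression-based or IRT-based linking is attempted.

Two exactness properties anchor the test suite:

* $\hat{T}_5 = 1.25\,S_4$ holds exactly for all $7^4 = 2401$ response
  patterns; prorated scores live on a quarter-point grid, which double
  precision represents exactly. Rounding (half away from zero, one decimal
  for scores, two for correlations) is applied only at display time and
  never feeds back into computation.
* For any sample, $\overline{d} = \overline{x_5} - \overline{S_4}/4$
  exactly, where $d = \text{direct} - \text{prorated}$. With the published
  overall item means (3.76, 3.80, 4.32, 4.53, 3.72) this identity gives
  $3.72 - 16.41/4 = -0.3825$, matching the reported $-0.39$ within the
  rounding of the printed means.

## The agreement battery

Validity of the link is assessed on respondents with all five items, by
comparing the direct total $b$ with the prorated estimate $c$ computed
from their first four items (the fifth item is never peeked at when
prorating, mirroring a true 4-item administration).

**Differences.** $d_i = b_i - c_i$; means and sample ($n-1$) SDs of $d$
and $|d|$. The $n-1$ convention is the standard one for Bland–Altman
limits; at the sample sizes involved the distinction is immaterial, so the
convention is safe.

**Limits of agreement.** $\bar{d} \pm 1.96\,s_d$. Under approximate
normality of $d$ about 95% of individual differences fall inside; a
simulation-based test checks this coverage to ±0.01 at $n = 10{,}000$.

**Correlation.** Pearson product–moment $r$, with $r > 0.9$ labelled "very
high". A constant vector leaves $r$ undefined and it is reported as `NA`,
never coerced to 0.

**ICC.** From the two-way crossed ANOVA (subjects × 2 measures, no
replication) with mean squares $MS_R$ (subjects), $MS_C$ (measures),
$MS_E$ (residual):

$$\mathrm{ICC}(C,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E}, \qquad
\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E +
\frac{k}{n}(MS_C - MS_E)},$$

with $k = 2$. The consistency form is blind to a constant offset between
the measures; the absolute-agreement form penalises it. The conventional
"(3,1)" label for the two-way mixed single-measure ICC is ambiguous
between the two when a report's words say "absolute agreement", so
`icc_pair()` always computes and labels **both**, and the headline report
field defaults to absolute agreement per the verbal definition. Confidence
intervals use exact $F$ bounds for $(C,1)$ and the
Satterthwaite-degrees-of-freedom approximation (McGraw–Wong) for $(A,1)$,
at fixed $\alpha = 0.05$. Estimates carry the usual qualitative bands:
poor $< 0.5$, moderate $0.5$–$0.75$, good $0.75$–$0.9$, excellent
$> 0.9$. When every mean square is zero the ICC is undefined and reported
as such. Both variants are verified against a brute-force
variance-components oracle and an external reference implementation in the
tests; only the two single-measure forms are provided (no average-measure
ICC, no Lin's concordance).

**Thresholds.** Fractions of respondents with $|d| < 2, 3, 4$ points.
The inequality is strict, following the benchmark definitions.

**Category concordance.** Scores are classified with the published
interpretive benchmarks: 31–35 extremely satisfied, 26–30 satisfied, 20–25
neutral or slightly satisfied, 15–19 slightly dissatisfied, 10–14
dissatisfied, 5–9 extremely dissatisfied. These integer bands leave gaps
for fractional prorated scores, and published category cross-tabulations
do not state how fractions were assigned. This package adopts the
half-open interval extension $[5,10), [10,15), [15,20), [20,26), [26,31),
[31,35]$: every integer keeps its published band, the bands partition the
whole 5–35 range, and classification is total and monotone. (The
alternative — rounding to an integer first — would move e.g. 25.5 into
"satisfied"; the interval rule keeps it in the band whose printed range
contains the scores just below it, and is the choice we consider least
surprising because it never reclassifies through rounding.)

**Normality.** Screened visually only: the Bland–Altman plot (and any
histogram the user draws) — no formal normality test gates any statistic.

## The synthetic-data generator

The validation sample behind the published link (Model Systems databases,
$n = 17{,}897$) is not redistributable, so the pipeline is exercised on
synthetic data. The generator draws a latent multivariate normal with an
exchangeable (or user-supplied) correlation, then discretises each value
by rounding to the nearest integer and clipping to $[1, 7]$.

Rounding and clipping bias the discretised mean away from the latent mean,
so latent means are *calibrated*: for each item the exact marginal of the
round-and-clip transform,
$E = \sum_{k=1}^{7} k\,p_k(\mu, \sigma)$ with the $p_k$ given by Gaussian
CDF differences at the half-integer cutpoints, is inverted by 1-D
root-finding. The calibration is therefore analytic and fully
deterministic — no Monte-Carlo calibration sample or internal calibration
seed is needed; Monte-Carlo checks appear only in the tests, where
empirical means at $n = 100{,}000$ recover the targets within ±0.05.
Calibration is declared to fail when a target is outside $(1, 7)$ or when
realising it would pile more than 90% of the mass on a boundary response
(e.g. a target mean of 6.99 with SD 2.5): such targets are effectively
degenerate on the grid.

Defaults state the world being emulated:

* target means 3.76, 3.80, 4.32, 4.53, 3.72 and SDs 2.07, 2.04, 2.07,
  2.00, 2.18 — the published overall item-level moments;
* $n = 17{,}897$ — the published pooled sample size;
* exchangeable latent correlation $\rho = 0.65$ — **not** a published
  value. The inter-item covariance of the original sample is not
  recoverable from printed results, so $\rho$ is a documented assumption,
  chosen to put internal consistency in the high range asserted for the
  scale (Cronbach's alpha ≈ 0.90 at $\rho = 0.65$ for five items), and
  overridable.

Targets are asymmetric on purpose: means are calibrated hard; SDs are used
as the latent scale and only loosely realised (round-and-clip compresses
them to ≈1.8 from targets ≈2.0–2.2), with achieved SDs reported. The
analytic acceptance checks depend on means only, so forcing SDs would add
complexity without sharpening any validated quantity.

What a green synthetic run does and does not establish: the generator
reproduces the marginal means, the sign and approximate size of the mean
direct-prorated difference (an algebraic function of those means), and the
qualitative high-agreement pattern (r and ICC > 0.9, category shifts of at
most about one band). It does **not** reproduce the exact published
$r = \mathrm{ICC} = 0.97$, the limits $-4.3$ to $3.5$, the 67/83/93%
threshold percentages, or the 71/8/20% concordance split — those depend on
the true inter-item covariance and on distributional shape beyond a
Gaussian copula (no IRT-style generative model is attempted), and they
require the restricted individual-level data. The tests treat them as
qualitative patterns, never as numeric targets.

## Numerical and interface choices

* Differences are `direct − prorated`, matching the sign convention of the
  published agreement table (negative overall mean).
* The limits-of-agreement multiplier is exactly 1.96, and the published
  overall limits (−4.3 to 3.5) are *not* exactly reconstructible from the
  published rounded mean (−0.39) and SD (1.95), which give −4.21 to 3.43;
  the original authors evidently used unrounded internals. The package
  computes from unrounded values and does not force agreement with the
  printed bounds.
* Proration requires all four items; there is no 3-of-4 fallback, which
  would be a different, unvalidated estimator. Input rows with missing,
  non-integer, or out-of-range responses are rejected with their location;
  dropping them requires an explicit `skip_invalid`, because silent drops
  bias complete-case agreement statistics.
* Report JSON is written with unrounded numbers and is byte-identical
  across reruns of the same input; the CSV report is the display-precision
  view (scores 1 dp, correlations/ICC 2 dp, half-away-from-zero).
* The generator saves and restores the caller's RNG state, so a simulation
  never perturbs the enclosing script's random stream.

## Known limitations

* Agreement statistics need $n \ge 2$ (ICC, SD) and $n \ge 3$ (Pearson);
  singleton groups are rejected rather than reported with undefined
  entries.
* The Gaussian-copula generator cannot match arbitrary SD targets on a
  7-point grid and does not emulate injury-group-specific distributions
  (group-level item moments were never published).
* The half-open category intervals are one defensible convention for
  fractional scores; analyses hinging on respondents within 0.75 point of
  a cutoff should check sensitivity to the alternative rounding rule.
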