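---
title: "Graded-response scoring and population reference values for PROMIS Global Health"
author: "promisref authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded-response scoring and population reference values for PROMIS Global Health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promisref)
```

## The problem this package addresses

Generic health-related quality of life is routinely measured with the 10-item
PROMIS Global Health scale (PROMIS-GH, also called PROMIS-10).  Its two
4-item subscales — Global Mental Health (GMH: quality of life, mental health,
social satisfaction, emotional problems) and Global Physical Health (GPH:
physical health, physical function, pain, fatigue) — are scored with an item
response theory model and reported on the T metric, which has mean 50 and
standard deviation 10 in the US calibration population.  Interpreting a
T-score requires two further ingredients that this package provides
machinery for:

1. **Reference values** — subgroup tables (total, gender, age bands) of mean
   T-scores in a general population, against which individual or
   patient-group scores can be placed.  The Dutch 2016 general-population
   tables are shipped as plain-text data and every derived quantity in them
   (weighted means, differences from the US mean, short-form gaps) is
   recomputed by code rather than trusted.
2. **Interpretability thresholds** — integer cut points on the T metric
   separating poor / fair / good / very good / excellent health, derived
   from the sample itself by an anchor-based procedure.

Because the underlying respondent-level panel data are not publicly
deposited, the package also contains a first-class synthetic-population
generator with the same statistical structure, so that the entire pipeline
is exercised end to end by tests.

## The measurement model

Each item has ordered response categories `1..K` (after recoding, higher =
better health).  Under the graded response model an item with discrimination
$a$ and thresholds $b_1 < \dots < b_{K-1}$ has cumulative curves

$$P^*_k(\theta) = \frac{1}{1 + e^{-a(\theta - b_{k-1})}},\qquad
P^*_1 \equiv 1,\; P^*_{K+1} \equiv 0,$$

and category probabilities $P(k\mid\theta) = P^*_k(\theta) -
P^*_{k+1}(\theta)$.  T-scores are the affine map $T = 50 + 10\,\theta$.

**Response-pattern EAP scoring.**  A respondent's trait estimate is the
posterior mean of $\theta$ under a standard-normal prior, with the
likelihood the product of category probabilities over *answered* items only.
Missing items contribute no factor, so any subset of items yields a score;
a pattern with no answered items returns the prior (T = 50, SE = 10) and is
flagged rather than dropped — whether to drop such respondents is a
pipeline-level policy, not an engine decision.  The posterior standard
deviation is reported as the standard error.

**Summed-score conversion tables.**  For complete responses, scoring-manual
style tables map each attainable raw sum to a T-score.  The likelihood of
each sum is accumulated with the Lord–Wingersky recursion (no enumeration of
the $K^J$ patterns), and the row's T-score is the EAP of $\theta$ given that
summed-score likelihood.  Tests verify the recursion against full pattern
enumeration to 1e-10, and the resulting T column is non-decreasing in the
sum.

Pattern scoring and table lookup are different estimators.  On simulated
complete-response populations they correlate above 0.99 and agree within 3
T-points for the large majority of respondents, but *discordant* patterns
(a very high response on a discriminating item together with a very low one
elsewhere, e.g. 5,5,1,1) can differ from their sum's table value by 10 or
more T-points.  This is intrinsic to any parameter set whose
discriminations differ across items — including the official calibration —
and is why pattern scoring is the accurate method.

## Recoding rules

Items are stored in the direction of administration.  Two items (fatigue,
emotional problems) run "higher = worse" and are reverse-coded at scoring
time.  The pain-intensity item is administered on a 0–10 numeric rating
scale and banded onto five categories; the band map (0→5, 1–3→4, 4–6→3,
7–9→2, 10→1) follows the official scoring convention but is shipped as
configuration, not code, because other instrument versions may band
differently.  Two further items — general self-rated health (the anchor) and
usual activities — belong to no subscale.

## Item parameters

The official US calibration parameters are distributed through the
HealthMeasures scoring channels and are not redistributed here.  The package
ships a clearly labelled **synthetic** default set
(`item_parameters_synthetic.csv`): discriminations between 1.7 and 3.2, and
thresholds placed with a logistic–normal approximation so that, at trait
levels typical of a general population scoring about half an SD below the
calibration centre, the implied category frequencies resemble the published
Dutch response distributions.  Users with access to the official file supply
it through `read_item_parameters()`; everything downstream is unchanged.

## Numerical choices

* **Quadrature.**  EAP integrals use 161 equally spaced nodes with
  normalized standard-normal weights on $[-8, 8]$.  The wide range matters:
  truncating at $\pm 4$ leaves relative posterior tail mass of order
  $10^{-3}$ for extreme all-highest patterns (the likelihood is ~1 where the
  prior still has $3\times10^{-5}$ mass beyond 4), which biases the
  posterior mean by up to $5\times10^{-3}$ on the $\theta$ scale.  On
  $[-8, 8]$ the truncated mass is below $10^{-15}$ and, because the
  integrand decays to zero at the end points, the equally spaced rule
  converges spectrally: agreement with a 10,001-point dense reference
  integration is at the $10^{-12}$ level, comfortably inside the 1e-6
  guarantee the tests enforce for every complete and incomplete 4-item
  pattern.
* **Rounding.**  All published-table arithmetic uses half-up rounding
  (`round_half_up()`), not IEEE round-half-even: the threshold worked
  example (means 47 and 54, midpoint 50.5, threshold 51) is only consistent
  with half-up.  T-scores are reported to 1 decimal, thresholds as integers,
  percentages to 1 decimal; internal computation is unrounded.
* **Classification.**  Threshold bands are defined on integer T-scores, so
  `classify_tscore()` rounds half-up to an integer before lookup; 37.9
  therefore falls in a band starting at 38.
* **Degenerate inputs.**  Empty anchor groups abort threshold derivation
  (naming the empty category); non-monotone anchor-group means yield a
  warning and a flag but no isotonic correction, since the published
  procedure defines none; empty reference subgroups are emitted with n = 0
  and missing statistics.

## The anchor-based threshold procedure

Respondents are grouped by their answer to the general self-rated-health
anchor item (poor … excellent); the unweighted mean subscale T-score is
computed per group; each threshold is the half-up-rounded midpoint of two
adjacent means.  The four midpoints tile the integer T axis into five bands.
Published Dutch and US band tables ship with the package
(`reference_bands()`) for side-by-side comparison.  Shift equivariance
(adding a constant to all T-scores shifts unrounded midpoints by that
constant) and determinism under sample reordering are enforced by tests.

## Representativeness checking

Sample margins for age (coarse census bins 18–39 / 40–65 / >65, both closed
bins including their end points), gender, education, region and ethnicity
are compared with census margins category by category; the deviation is the
absolute difference in percentage points and the sample passes when the
maximum deviation is strictly below the criterion (2.5 points by default).
`Unknown` buckets are reported but excluded.  Margin files whose printed
integer percentages sum to 101 (the shipped census age margins do, from
rounding) are accepted within a ±1.5 tolerance around 100.  The shipped
study sample margins deviate from the census by at most 2.0 points — the
check recomputes this from the category tables rather than asserting it.

## The synthetic-population generator

`generate_population()` emulates the structure the analysis assumes:

* **Strata.**  Gender × six age bands; default proportions are the products
  of the published gender and age margins, and default cell latent means are
  an additive gender + age decomposition of the published subgroup mean
  T-scores mapped to the latent metric (population mean ≈ −0.53 for the
  mental and −0.48 for the physical trait).  Stratum SDs default to 1.
* **Ages.**  The published tables pin the age structure down twice (fine
  reference bands with exact n's; coarse census margins), and uniform ages
  within fine bands cannot satisfy both.  Default within-band weights are
  therefore calibrated from the two published tables: the 35–44 band is
  split at 40 (share 0.73 below) and the 65–74 band places 0.18 at exactly
  65, uniform elsewhere.
* **Traits.**  Bivariate normal per stratum with correlation ρ = 0.6 — a
  placeholder, since the true mental–physical correlation in the source
  data is unpublished; all tests are written to be insensitive to ρ.
* **Responses.**  Every item is drawn from its graded-response
  probabilities at the respondent's trait; the two standalone items load on
  a standardized equal-weight composite of both traits (weight
  configurable — the instrument itself treats the anchor as standalone, so
  the 0.5/0.5 loading is a modelling choice, not doctrine).  Raw codes are
  written in administration direction; the pain item's scored category is
  banded back onto 0–10 with a uniform draw inside the band.
* **Missingness** is completely at random and defaults to 0: the source
  survey did not allow skipping items, and non-zero rates exist only to
  exercise the missing-data path of pattern scoring.
* **Determinism.**  One seed governs a fixed draw order (strata and
  demographics → latent traits → items → masks); identical seeds give
  byte-identical populations, and the caller's RNG stream is untouched.

### What passing tests do and do not show

The generator reproduces the *marginal and subgroup structure* of a
general-population survey under the scoring model's own assumptions.  It
does not emulate panel-recruitment bias, differential item functioning
between languages, local dependence, or exact copula matching of the
published item marginals.  Tests that pass on synthetic data therefore
validate the pipeline's arithmetic and its statistical behaviour under the
model, not the substantive claim that any real population has these score
levels.

Two quantitative caveats are worth stating because they are visible in test
tolerances:

* **Double shrinkage.**  Published subgroup means are themselves EAP means
  of real respondents.  The generator uses them as *latent* means, and EAP
  scoring shrinks a non-central population toward 50 by roughly
  $(1-\lambda)$ of its offset, with $\lambda \approx 0.85$ for the default
  4-item sets.  A subgroup configured at T = 43.4 is therefore *expected*
  to score back around 44.3–44.6.  The recovery tests compare against the
  configured latent targets with a shrinkage-aware tolerance of 1.5
  T-points at n = 5,000, and this bound is tight by design: the expected
  maximum subgroup gap is about 1.3.
* **Margins at the criterion.**  The study sample's own maximum deviation
  from the census was 2.0 points against a 2.5 criterion.  A simulated
  sample of n = 4,370 adds multinomial noise of ±0.7 points or so on top of
  the structural ~1-point age gap, so individual draws occasionally exceed
  2.5 — as a real recruitment round occasionally would.  The
  representativeness *code* is tested on fixed margin tables; the simulated
  population's pass/fail is reported, not asserted.

## Problem sizes used by the test suite

The suite enumerates all $5^4 = 625$ complete 4-item patterns for the
oracle-agreement, recursion and monotonicity checks; recovery and
subgroup-mean tests simulate n = 5,000; pipeline and consistency tests use
n = 400–1,500.  The acceptance script simulates one population of n = 4,370
(the published sample size).  The full suite runs in well under a minute on
one core.

## Known limitations

* The shipped parameter set is synthetic; absolute T-scores computed with it
  are internally consistent but not comparable to scores from the official
  calibration.  The published tables shipped with the package *are* on the
  official metric.
* The published Global10 distribution row is internally inconsistent by one
  printed unit (its percentages imply a mean of 3.6 against a printed 3.7);
  the regression test documents this rather than hiding it.
* The confidence interval in `compare_to_reference()` is a one-sample
  normal interval around the sample mean against a fixed constant; the
  source publication does not state its interval method, so published CI
  end points are displayed but not treated as reproduction targets — only
  the differences are.
* Age-band conventions are declared, not inferred: reference bands are
  closed integer ranges with 75+ open-ended; census bins 18–39 and 40–65
  include both end points.  The printed coarse labels ("40–65", "> 65")
  overlap at 65 under some readings; the declared convention places 65 in
  40–65.
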