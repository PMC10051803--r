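---
title: "Predicting gross motor function from assistive-device use: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gross motor function from assistive-device use: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdscalc)
```

`mdscalc` estimates the GMFM-66 gross-motor score of children and
adolescents with cerebral palsy from the assistive devices they use, their
age and their CP subtype, and quantifies what that *Medical Device Score*
(MDS) is good for: group comparison and sample-size planning, not
individual assessment. This vignette explains the models, the calibration
of the synthetic cohort generator, the numerical decisions, and what the
package's passing tests do and do not establish about real data.

## 1. The synthetic cohort generator

Clinical registry cohorts of this kind cannot be redistributed, so the
package ships a generator whose *joint* structure mirrors the causal chain
the analysis assumes:

GMFCS severity level → GMFM-66 score → device usage.

Per patient:

1. **GMFCS level** I–V ~ categorical. Default probabilities are the
   published cohort composition 118/289/592/470/112 of 1581 (levels I and V
   underrepresented, as typical for intensive rehabilitation programs).
2. **GMFM-66 | level** ~ Normal(mean_level, SD) truncated to [0, 100].
   Published sources report per-level score *ranges* only, not means, so
   the defaults — means 85/65/50/35/15 for levels I–V with common SD 8 —
   are assumptions of this package, chosen so adjacent level distributions
   overlap moderately (as per-level box plots of such cohorts imply). They
   are plainly flagged as assumptions and fully configurable.
3. **Subtype | level** ~ categorical with the published level-conditional
   mix (bilateral spastic 75.6% overall; unilateral spastic concentrated at
   level I, dyskinetic at level V). One published row sums to 99.9% after
   rounding; rows are renormalized proportionally so each sums to 1.
4. **Age** ~ Normal(8.1, 4.3) years truncated to [2.2, 25.5], independent
   of level: the published per-level age means vary little (7.2–9.0), so
   the simplification costs realism only in the second decimal.
5. **Devices**: each catalog device d is used independently with
   probability `base_rate_d · exp(−(score − center_d)² / (2 width_d²))` — a
   Gaussian "bump" peaking at the motor level the device is prescribed for.
   Empty device sets are possible and retained (clinically plausible at
   level I, and required for a meaningful floor/ceiling analysis).

### Device catalog calibration

Published anchors pin down nine of twelve profiles: five devices by usage
frequency (transtibial orthoses 13.2%, active wheelchair 12.8%, posterior
walker 9.5%, standing frame 7.6%, night splints 6.6%) and four by
device-user mean score (therapy bike 71.19 GMFM-66 points, shoe inserts
61.06, roller board 30.29, passive wheelchair 26.20). The four user-mean
anchors set the profile centers; base rates were solved numerically so the
expected usage frequency under the default score mixture is proportional to
the published frequencies. Three further profiles (seating shell, forearm
crutches, hand orthosis) are clinically standard devices with interpolated
values. The *orderings* — not the exact values — are the reproduction
targets, and both survive any common scaling of base rates.

Two deliberate choices:

- **Device-load factor 2.5.** The published percentages are read as
  relative frequency shares; all base rates carry a common factor 2.5,
  which sets the mean device count to about two per patient. A real
  inventory lists far more than twelve devices, so per-patient loads near
  one would be unrealistically sparse and would leave the device pattern
  too uninformative to support the strong-concordance prediction accuracy
  this kind of cohort exhibits. The factor changes neither the frequency
  ordering nor the user-mean ordering (conditional user means are invariant
  to base-rate scaling).
- **Independent Bernoulli usage.** No co-occurrence data are published;
  independence given the score is the neutral default. Real device sets are
  positively and negatively correlated (a passive wheelchair user rarely
  also uses a therapy bike); the simulator's independence makes the feature
  matrix slightly *more* informative than reality at equal load.

**Determinism.** One integer seed governs the whole cohort: the seed is set
once and the stages draw from a single RNG stream in fixed order, so
`generate_cohort` is reproducible bit for bit, and truncated normals are
sampled by quantile inversion (exactly one uniform per draw, so no
rejection-sampling drift in the stream).

## 2. Data handling

- **Min-count filter**: devices used by fewer than 5 patients cohort-wide
  are dropped from the catalog and from every record ("minimum count of
  n = 5" read inclusively: count ≥ 5 is kept). Records are never dropped;
  the operation is idempotent.
- **Device grouping** (raw inventory → analysis categories) is an input
  mapping file applied before filtering, identity by default — no grouping
  taxonomy is imposed.
- **Features**: one indicator per retained device (lexicographic), age,
  and all five subtype one-hot columns, in a fixed order. The GMFCS level
  is excluded by construction — the predictor must work from payer data,
  which has no clinical GMFCS grading — and a debug-only flag re-admits it
  for leakage audits (on the simulator, where GMFCS drives the score,
  re-admitting it must and does raise holdout concordance). Height, weight
  and sex are carried in the data model but excluded from the default
  feature set, mirroring the devices + age + subtype protocol.
- **70/30 split**: `round(0.7 N)` training patients with half-up rounding
  (1107/474 at N = 1581; the protocol source is silent on rounding).

## 3. The prediction harness

Four families — random forest (`randomForest`), radial-kernel
eps-regression SVM (`e1071`), single-hidden-layer feed-forward net
(`nnet`), gradient boosting (`xgboost`) — all trained on the identical
feature matrix. No tuning protocol is published, so library defaults are
used and recorded in each model handle. The two harness-set values are the
FNN topology (hidden size = number of features capped at 32, weight decay
0.1, 500 iterations, standardized inputs, fixed-seed initialization; the
original network topology is unstated) and the XGBoost round count
(`nrounds = 100`, which the library does not default).

Predictions are clipped to [0, 100] (the GMFM-66 range) and clipped pairs
flagged. A zero-variance training outcome returns a constant predictor with
a warning rather than an error, so degenerate strata do not abort batch
runs. The random forest is the production family (lowest MAE/RMSE in the
published comparison and in this package's simulator runs); the others run
in compare mode.

**Cross-fitting.** The power analysis needs an MDS for every patient.
In-sample predictions would be optimistic (a random forest nearly
interpolates its training data), so `crossfit_mds` produces out-of-fold
predictions: 5 folds by default, each patient predicted by a model that
never saw it. Whether the original analysis used in-sample or out-of-sample
MDS values is unstated; cross-fitted is the defensible default, and
in-sample predictions remain available by training and predicting manually.

## 4. Agreement statistics

Lin's CCC is computed with n-divisor moments (Lin's original definition;
the divisor visibly changes small-sample values, so it is fixed and
documented). Degenerate inputs are resolved explicitly: both vectors
constant with equal means → error (0/0); otherwise a constant vector gives
CCC = 0. Key properties (|CCC| ≤ |Pearson r|, symmetry, invariance to a
common shift, strict decrease when the location gap widens) are enforced by
randomized property tests.

Confidence intervals are percentile bootstrap over whole patient pairs,
2000 replicates by default; the interval method of the original analysis is
unstated, so no numerical match with published CIs is claimed. Resamples on
which a metric is undefined (constant resample for CCC) are redrawn and
counted. The percentile method can rarely exclude the point estimate; the
result flags when it does. Bootstrap-quantile Monte-Carlo error scales as
~2.7·SE(metric)/√reps, which sets the stability tolerances used in the
tests.

The GMFCS-stratified bias table (per-level signed error MDS − GMFM, MAE,
and quartiles of both scores) is the tabular analogue of per-level box and
scatter plots. On the simulator it reproduces the floor/ceiling direction:
negative signed error at level I, positive at level V. That is a structural
property of predicting a bounded outcome from features that saturate at the
extremes, so observing it on synthetic data says the machinery is correct,
not that real cohorts show the same magnitudes.

## 5. The power procedure

To ask "how large must two groups be for a comparison based on the MDS to
detect a true GMFM-66 difference of d points?", the package:

1. partitions the cohort into two groups of ⌊N/2⌋ (790 + 790 at N = 1581,
   one patient left out per candidate) uniformly at random, k times
   (default 10,000);
2. selects the candidate whose group-mean difference on the **true**
   GMFM-66 scale is closest to the target d (the engineered difference is
   defined on the measured scale, never on predictions);
3. **refines** the selected split by greedy patient swaps — each swap of
   one A-patient with one B-patient changes the mean difference by
   2(score_b − score_a)/790, and the swap landing closest to the remaining
   gap is taken until no swap improves it;
4. for each subsample size n, draws n patients per group without
   replacement, tests at α = 0.05, and repeats (default 10,000 reps). Per
   repetition the *same* drawn patients are tested twice — once on their
   GMFM-66 values, once on their MDS values — so the two power columns are
   directly comparable cell by cell.

**Why the refinement step exists.** The mean difference of a uniformly
random halving has SD ≈ 2σ/√N — about 0.94 GMFM-66 points at N = 1581,
σ ≈ 19. The most extreme of 10,000 candidates therefore differs by only
≈ 3.7 points: selection alone cannot build groups 5 or 10 points apart, the
achieved difference saturates, and the grid loses its meaning for larger
targets. Swap refinement constructs divisions that genuinely "differ most
precisely by" every target in 3–10 while preserving group sizes and the
random starting point. Successive targets are chained (each split refined
from the previous one) so the family of engineered differences is nested
and internally consistent; selection-only behavior remains available via
`refine = FALSE`.

Other decisions: Welch's t is the default test (the comparison test is not
named in the protocol; Student's t and Mann–Whitney are selectable);
subsamples are drawn without replacement within each repetition and
repetitions are independent; group A is always the higher-mean group, so
achieved differences are non-negative; one split is reused across all
sample sizes for a given d (the closest reading of the protocol).

**Type-I calibration and the finite-population caveat.** Drawing both
samples from one *small* finite group makes the t-test conservative: the
test estimates the population variance but without-replacement means are
less variable by the factor (N − n)/(N − 1), so at n = 250 from a
790-patient group the null rejection rate falls to roughly 3%. The
calibration check therefore draws from one large simulated group
(N = 10,000), where the correction is negligible and the empirical type-I
error sits at 5% as it should. Users subsampling large fractions of small
groups should expect conservative tests; this is a property of the
procedure, not a bug. The Welch/Student rejection decisions are computed
vectorized from column moments for speed and are verified against
`stats::t.test` column by column in the test suite; empirical power is
verified against the closed-form noncentral-t power on normal populations.

## 6. Problem sizes used by the tests

The shipped test suite runs the full pipeline at the study scale
(N = 1581 cohorts, 70/30 splits, 5-fold cross-fitting, the complete
8 × 8 (n, d) grid) with 500–10,000 Monte-Carlo repetitions per check,
chosen so each comparison's Monte-Carlo standard error is small against the
tolerance it is tested at (e.g. reps = 1000 gives ≤ 1.6 percentage points
2-SE on a power cell). Replicate-averaged calibration checks use 5 cohorts:
a single multinomial draw of 1581 patients puts ~1.2 percentage points of
SD on the largest level proportion, so single-cohort checks against a ±2
point band would fail by chance alone a sizable fraction of the time;
averaging 5 replicates makes the check sharp.

## 7. Limitations

- The conditional GMFM-66 means/SD per GMFCS level are assumptions; any
  analysis sensitive to them should vary the configuration.
- Device usage is conditionally independent given the score; real
  co-occurrence structure (substitutes, bundles) is not modeled.
- The simulator is cross-sectional; no longitudinal trajectories, no
  item-level GMFM-66 administration, no interval-scale conversion of raw
  item scores.
- Passing tests on the simulator establish correctness of the machinery
  and the *directions* of the scientific effects (attenuated power,
  floor/ceiling bias); they do not certify the magnitudes on any real
  cohort — published headline values (CCC 0.75, MAE 7.74 on 1581 clinical
  patients) came from data that are not redistributable, so no numeric
  reproduction of them is claimed.
- The MDS is a group-level research instrument. A mean absolute error
  around 8 GMFM-66 points makes individual clinical assessment unsuitable
  by a wide margin.
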