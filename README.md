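# mdscalc — Medical Device Score Calculator for cerebral palsy cohorts

Routine healthcare databases (health insurers, care providers) record which
assistive medical devices a child with cerebral palsy (CP) uses — walkers,
wheelchairs, orthoses — but almost never contain a measured motor-function
score such as the Gross Motor Function Measure (GMFM-66, 0–100, higher =
more able). Since device supply mirrors motor impairment like a negative
image, the GMFM-66 can be *predicted* from the device pattern plus age and
CP subtype. `mdscalc` implements that idea end to end: the predicted value
is the **Medical Device Score (MDS)**, and the package quantifies exactly
how far an MDS can substitute for a measured GMFM-66 in group-level
research.

The package is for biostatisticians and rehabilitation researchers who want
to (a) evaluate device-based score prediction on their own cohort tables,
or (b) plan sample sizes for group comparisons that will use the MDS
instead of a measured score.

## What it computes

**Agreement.** Predicted and measured scores are compared with Lin's
concordance correlation coefficient

CCC = 2·s_xy / (s_x² + s_y² + (x̄ − ȳ)²)

(n-divisor moments), plus MAE and RMSE, each with percentile-bootstrap 95%
CIs over patient pairs, and with GMFCS-stratified signed-error tables that
expose the floor/ceiling effect of a bounded predicted score
(underestimation at GMFCS level I, overestimation at level V).

**Prediction harness.** Four model families trained on identical,
GMFCS-free feature matrices (device indicators + age + one-hot CP subtype):
random forest, SVM, feed-forward neural net, XGBoost. Out-of-fold
cross-fitting provides an MDS for *every* patient without in-sample
optimism. Predictions are clipped to [0, 100].

**Power planning.** From one cohort, two groups with an engineered GMFM-66
mean difference d are built by split selection (best of k random halvings,
polished by patient swaps until the target is met). Empirical power is then
estimated by repeatedly subsampling n patients per group and testing
(Welch's t by default, α = 0.05) — once with the true GMFM-66 values and
once with the MDS of the *same* drawn patients. The resulting grid shows
how much larger n must be when the predicted score replaces the measured
one.

**Simulator.** Because clinical registry data cannot be redistributed, the
package ships a calibrated synthetic cohort generator
(GMFCS level → GMFM-66 → device usage; published GMFCS/subtype/age
marginals; device profiles anchored to published usage frequencies and
device-user mean scores). All tests and examples run on it.

## Worked example

```r
library(mdscalc)

coh <- generate_cohort(default_sim_config(n_patients = 1581, seed = 1))
res <- evaluate_families(coh, families = "RF", split_seed = 2,
                         train_seed = 2, reps = 2000)
print(res$report, digits = 3)
#>   family metric estimate     lo     hi   n reps
#> 1     RF    ccc    0.734  0.687  0.777 474 2000
#> 2     RF    mae    8.840  8.060  9.579 474 2000
#> 3     RF   rmse   12.124 10.959 13.229 474 2000
```

On the 474 held-out patients the random-forest MDS agrees strongly with the
true score (CCC 0.73, "strong concordance" band 0.61–0.80) but errs by
about 8.8 GMFM-66 points per patient on average — accurate enough for group
comparisons, far too coarse for individual assessment.

```r
pred <- crossfit_mds(coh, family = "RF", seed = 3)
stratified_bias(pred$gmfm_true, pred$mds, pred$gmfcs)[, 1:4]
#>   gmfcs   n mean_signed_error mean_abs_error
#> 1     I 113           -18.366          18.80
#> 2    II 294            -4.732           8.49
#> 3   III 597            -0.385           6.82
#> 4    IV 455             2.924           6.70
#> 5     V 122            19.520          19.84
```

The signed error (MDS − GMFM) shows the floor/ceiling effect: mildly
affected patients (level I) are underestimated, severely affected ones
(level V) overestimated — the bounded device pattern carries little
information at the extremes.

```r
grid <- power_table(coh, pred, d_list = c(5, 8), n_list = c(50, 100, 250),
                    k_splits = 2000, reps = 2000, seed = 4)
grid[grid$target_d == 5, ]
#>     n target_d achieved_d source power_pct reps seed
#> 1  50        5          5   GMFM      26.9 2000    4
#> 2  50        5          5    MDS      13.7 2000    4
#> 3 100        5          5   GMFM      46.6 2000    4
#> 4 100        5          5    MDS      20.9 2000    4
#> 5 250        5          5   GMFM      89.0 2000    4
#> 6 250        5          5    MDS      49.9 2000    4
required_n(grid, d = 8, source = "MDS", target_power = 80)
#> [1] 250
```

To detect a true 5-point GMFM-66 difference, using the MDS instead of the
measured score costs substantial power at every group size — the price of
predicting the outcome rather than measuring it.

## Command line

A thin dispatcher wraps the same functions
(`inst/cli/mdscalc.R`): `simulate`, `evaluate` and `power` subcommands,
each writing its CSV output plus a JSON run manifest (seeds, effective
config, library versions, output digests) so every artifact is reproducible
from its manifest.

```sh
Rscript inst/cli/mdscalc.R simulate --out cohort.csv --seed 1
Rscript inst/cli/mdscalc.R evaluate --cohort cohort.csv --out report.csv --family all
Rscript inst/cli/mdscalc.R power --cohort cohort.csv --out grid.csv --mds auto
```

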