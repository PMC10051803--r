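# Prediction harness: the four model families, clipping, cross-fitting.

make_xy <- function(n = 40, seed = 1) {
  set.seed(seed)
  x <- cbind(dev_a = rbinom(n, 1, 0.5), dev_b = rbinom(n, 1, 0.4),
             age = runif(n, 3, 15))
  y <- 80 - 50 * x[, "dev_a"] + rnorm(n, 0, 2)
  list(x = x, y = y)
}

test_that("constant outcome yields a warning and a constant predictor", {
  d <- make_xy()
  for (fam in c("RF", "SVM", "FNN", "XGBoost")) {
    expect_warning(m <- train_predictor(d$x, rep(50, nrow(d$x)), fam),
                   "zero variance")
    pred <- predict_mds(m, d$x)
    expect_true(all(pred$mds == 50))
  }
})

test_that("RF recovers a perfectly separable device rule", {
  # deterministic rule: wheelchair users score 20, bike users score 80;
  # the insole is uninformative noise, as are age and subtype
  set.seed(7)
  n <- 60
  low <- rep(c(TRUE, FALSE), each = n / 2)
  devs <- lapply(low, function(h) {
    base <- if (h) "wheelchair" else "bike"
    if (runif(1) < 0.5) c(base, "insole") else base
  })
  coh <- toy_cohort(gmfm = ifelse(low, 20, 80), devices = devs,
                    age = runif(n, 3, 15),
                    subtype = sample(c("bilateral_spastic",
                                       "unilateral_spastic", "dyskinetic",
                                       "ataxic", "mixed"), n, TRUE))
  fm <- encode_features(min_count_filter(coh, 1))
  test <- c(1:9, (n / 2 + 1):(n / 2 + 9))
  m <- suppressWarnings(train_predictor(fm$x[-test, ], fm$y[-test],
                                        "RF", seed = 1))
  pred <- predict_mds(m, fm$x[test, ], ids = fm$ids[test],
                      gmfm_true = fm$y[test])
  expect_lt(mae(pred$gmfm_true, pred$mds), 5)
})

test_that("training is deterministic given the seed", {
  d <- make_xy(60)
  for (fam in c("RF", "FNN", "XGBoost")) {
    m1 <- train_predictor(d$x, d$y, fam, seed = 42)
    m2 <- train_predictor(d$x, d$y, fam, seed = 42)
    expect_identical(predict_mds(m1, d$x)$mds, predict_mds(m2, d$x)$mds,
                     label = fam)
  }
})

test_that("predict_mds clips out-of-range values and flags them", {
  fake <- structure(list(family = "RF", feature_names = c("a", "b"),
                         constant = 103.2, hyperparameters = list()),
                    class = "mds_model")
  x <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "b")))
  pred <- predict_mds(fake, x)
  expect_equal(pred$mds, c(100, 100))
  expect_true(all(pred$clipped))
  # empty test set
  empty <- predict_mds(fake, x[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  # column mismatch names the differing columns
  bad <- matrix(0, 2, 2, dimnames = list(NULL, c("a", "c")))
  expect_error(predict_mds(fake, bad), "missing: b.*unexpected: c")
})

test_that("cross-fitting covers every patient exactly once, out of fold", {
  coh <- generate_cohort(default_sim_config(n_patients = 10, seed = 13))
  pr <- crossfit_mds(coh, "RF", n_folds = 10, seed = 1, min_n = 1)
  expect_setequal(pr$patient_id, coh$patient_id)
  expect_equal(nrow(pr), 10)
  expect_error(crossfit_mds(coh, "RF", n_folds = 11), "exceeds")
  expect_error(crossfit_mds(coh, "RF", n_folds = 1), ">= 2")
  coh2 <- generate_cohort(default_sim_config(n_patients = 57, seed = 14))
  pr2 <- crossfit_mds(coh2, "RF", n_folds = 4, seed = 2, min_n = 1)
  expect_setequal(pr2$patient_id, coh2$patient_id)
  expect_false(anyDuplicated(pr2$patient_id) > 0)
})

test_that("cross-fitted agreement does not exceed in-sample agreement", {
  # optimism property, averaged over seeds
  diffs <- vapply(1:5, function(s) {
    coh <- min_count_filter(generate_cohort(default_sim_config(400, seed = s)))
    fm <- encode_features(coh)
    m <- train_predictor(fm$x, fm$y, "RF", seed = s)
    insample <- lin_ccc(fm$y, predict_mds(m, fm$x)$mds)
    cross <- crossfit_mds(coh, "RF", n_folds = 5, seed = s)
    insample - lin_ccc(cross$gmfm_true, cross$mds)
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) + 2 * sd(diffs) / sqrt(5), 0)
})

test_that("RF holdout concordance on the default cohort is strong", {
  coh <- min_count_filter(default_cohort_seed(1))
  fm <- encode_features(coh)
  sp <- holdout_split(coh, 0.7, seed = 2)
  tr <- fm$ids %in% sp$train_ids
  m <- train_predictor(fm$x[tr, ], fm$y[tr], "RF", seed = 2)
  pred <- predict_mds(m, fm$x[!tr, ], ids = fm$ids[!tr],
                      gmfm_true = fm$y[!tr])
  # the generator is designed so the device pattern carries enough signal
  # to land in the strong-concordance band
  expect_gt(lin_ccc(pred$gmfm_true, pred$mds), 0.6)
  expect_lt(rmse(pred$gmfm_true, pred$mds), 18)
})

test_that("shuffling the outcome destroys holdout concordance", {
  coh <- default_cohort_seed(1)
  coh <- min_count_filter(coh)
  fm <- encode_features(coh)
  set.seed(33)
  y_perm <- sample(fm$y)
  sp <- holdout_split(coh, 0.7, seed = 3)
  tr <- fm$ids %in% sp$train_ids
  m <- train_predictor(fm$x[tr, ], y_perm[tr], "RF", seed = 3)
  pred <- predict_mds(m, fm$x[!tr, ])
  expect_lt(abs(lin_ccc(y_perm[!tr], pred$mds)), 0.1)
})

test_that("re-admitting GMFCS (debug) strictly improves concordance", {
  coh <- min_count_filter(default_cohort_seed(1))
  sp <- holdout_split(coh, 0.7, seed = 5)
  ccc_for <- function(include_gmfcs) {
    fm <- encode_features(coh, include_gmfcs = include_gmfcs)
    tr <- fm$ids %in% sp$train_ids
    m <- train_predictor(fm$x[tr, ], fm$y[tr], "RF", seed = 5)
    lin_ccc(fm$y[!tr], predict_mds(m, fm$x[!tr, ])$mds)
  }
  expect_gt(ccc_for(TRUE), ccc_for(FALSE))
})

test_that("family comparison report has the Table-2 structure", {
  coh <- generate_cohort(default_sim_config(n_patients = 300, seed = 21))
  res <- evaluate_families(coh, split_seed = 2, train_seed = 2, reps = 150)
  expect_setequal(unique(res$report$family), c("RF", "SVM", "FNN", "XGBoost"))
  expect_equal(nrow(res$report), 12)
  for (fam in unique(res$report$family)) {
    sub <- res$report[res$report$family == fam, ]
    expect_gte(sub$estimate[sub$metric == "rmse"],
               sub$estimate[sub$metric == "mae"])
    expect_true(all(sub$lo <= sub$estimate & sub$estimate <= sub$hi))
  }
  # all families consumed the identical holdout patients
  ids <- lapply(res$predictions, function(p) p$patient_id)
  expect_true(all(vapply(ids, identical, NA, ids[[1]])))
})
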