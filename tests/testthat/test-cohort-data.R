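# Data model: CSV round trip, validation, device filtering, feature
# encoding, holdout splits.

test_that("cohort CSV write-then-read is an identity on patient data", {
  coh <- generate_cohort(default_sim_config(n_patients = 150, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$patient_id, coh$patient_id)
  expect_equal(back$age, coh$age, tolerance = 1e-12)
  expect_equal(back$gmfm66, coh$gmfm66, tolerance = 1e-12)
  expect_identical(back$gmfcs, coh$gmfcs)
  expect_identical(back$cp_subtype, coh$cp_subtype)
  expect_identical(lapply(back$devices, sort), lapply(coh$devices, sort))
  # labels are not serialized in the CSV; codes and counts must agree
  expect_equal(device_catalog(back)[, c("code", "count")],
               device_catalog(coh)[, c("code", "count")])
})

test_that("validation names offending rows and accepts empty device sets", {
  expect_error(
    cohort(data.frame(patient_id = c("x1", "x2", "x3"),
                      age = c(5, 6, 7), sex = "female",
                      cp_subtype = "ataxic", gmfcs = "II",
                      gmfm66 = c(30, 50, 101)),
           devices = list("a", character(0), "b")),
    "gmfm66 outside \\[0,100\\] \\(row 3\\)")
  ok <- toy_cohort(gmfm = c(30, 50), devices = list(character(0), "b"))
  expect_identical(ok$devices[[1]], character(0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ok, path)
  expect_identical(read_cohort(path)$devices[[1]], character(0))
  # missing required column
  bad_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,age\np1,5", bad_csv)
  expect_error(read_cohort(bad_csv), "missing required column")
})

test_that("min-count filter keeps devices at the threshold, inclusively", {
  # counts: A = 5, B = 4, C = 12 across 12 patients
  devs <- c(
    lapply(1:4, function(i) c("A", "B", "C")),
    list(c("A", "C")),
    lapply(6:12, function(i) "C"))
  coh <- toy_cohort(gmfm = seq(10, 90, length.out = 12), devices = devs)
  filt <- min_count_filter(coh, 5)
  expect_setequal(device_catalog(filt)$code, c("A", "C"))
  expect_identical(min_count_filter(coh, 1)$devices, coh$devices)
  expect_equal(nrow(filt), nrow(coh))  # records never removed
})

test_that("min-count filter recount matches brute force and is idempotent", {
  devs <- list(c("A", "B"), "B", c("B", "C"), "B", character(0), "C")
  coh <- toy_cohort(gmfm = c(10, 25, 40, 55, 70, 85), devices = devs)
  filt <- min_count_filter(coh, 4)  # B appears 4 times, A once, C twice
  brute <- table(unlist(lapply(devs, function(d) {
    counts <- table(unlist(devs))
    d[counts[d] >= 4]
  })))
  cat_f <- device_catalog(filt)
  expect_identical(cat_f$code, names(brute))
  expect_identical(cat_f$count, as.integer(brute))
  expect_identical(min_count_filter(filt, 4)$devices, filt$devices)
})

test_that("feature encoding: indicators, one-hot subtype, no GMFCS leak", {
  devs <- list(c("walker"), c("brace", "walker"), "wheelchair",
               character(0), "brace", "walker")
  subtype <- c("bilateral_spastic", "unilateral_spastic", "dyskinetic",
               "ataxic", "mixed", "bilateral_spastic")
  coh <- toy_cohort(gmfm = c(80, 60, 30, 90, 55, 70), devices = devs,
                    subtype = subtype)
  fm <- encode_features(min_count_filter(coh, 1))
  # lexicographic device block, then age, then subtype block
  expect_identical(colnames(fm$x),
                   c("dev_brace", "dev_walker", "dev_wheelchair", "age",
                     paste0("subtype_", c("bilateral_spastic",
                                          "unilateral_spastic", "dyskinetic",
                                          "ataxic", "mixed"))))
  expect_equal(unname(fm$x[1, 1:3]), c(0, 1, 0))
  sub_block <- fm$x[, grep("^subtype_", colnames(fm$x))]
  expect_true(all(rowSums(sub_block) == 1))
  expect_false(any(grepl("gmfcs", tolower(colnames(fm$x)))))
  expect_equal(fm$y, coh$gmfm66)
  # debug flag is the only way a GMFCS column appears
  fm_dbg <- encode_features(coh, include_gmfcs = TRUE)
  expect_true("gmfcs_debug" %in% colnames(fm_dbg$x))
  # no devices at all -> error
  none <- toy_cohort(gmfm = c(50, 60), devices = list(character(0), character(0)))
  expect_error(encode_features(none), "empty device catalog")
})

test_that("feature rows depend only on their own record", {
  coh <- generate_cohort(default_sim_config(n_patients = 60, seed = 8))
  coh <- min_count_filter(coh, 1)
  fm <- encode_features(coh)
  set.seed(1)
  perm <- sample(nrow(coh))
  coh_p <- cohort(as.data.frame(coh[perm, setdiff(names(coh), "devices")]),
                  devices = coh$devices[perm],
                  labels = attr(coh, "device_labels"))
  fm_p <- encode_features(coh_p)
  expect_equal(fm_p$x[order(perm), ], fm$x)
  expect_equal(fm_p$y[order(perm)], fm$y)
})

test_that("holdout split: sizes, determinism, uniformity", {
  coh <- generate_cohort(default_sim_config(n_patients = 1581, seed = 2))
  sp <- holdout_split(coh, 0.7, seed = 4)
  expect_length(sp$train_ids, 1107)  # round(0.7 * 1581), half-up
  expect_length(sp$test_ids, 474)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), coh$patient_id)
  expect_identical(holdout_split(coh, 0.7, seed = 4), sp)

  small <- toy_cohort(gmfm = seq(10, 90, length.out = 10),
                      devices = rep(list("a"), 10))
  sp10 <- holdout_split(small, 0.5, seed = 1)
  expect_length(sp10$train_ids, 5)

  # over seeds, each patient is held out about 30% of the time
  tiny <- toy_cohort(gmfm = seq(5, 95, length.out = 20),
                     devices = rep(list("a"), 20))
  in_test <- rowMeans(vapply(1:300, function(s) {
    tiny$patient_id %in% holdout_split(tiny, 0.7, seed = s)$test_ids
  }, logical(20)))
  expect_true(all(abs(in_test - 0.3) < 0.1))
  expect_error(holdout_split(small, 0.01), "empty train or test")
})

test_that("device grouping map is applied with identity default", {
  devs <- list(c("afo_left", "afo_right"), "walker_post", "afo_left")
  coh <- toy_cohort(gmfm = c(40, 50, 60), devices = devs)
  map <- data.frame(device_code = c("afo_left", "afo_right"),
                    group_code = c("afo", "afo"))
  grouped <- apply_device_grouping(coh, map)
  expect_identical(grouped$devices,
                   list("afo", "walker_post", "afo"))  # dupes collapsed
  cat_g <- device_catalog(grouped)
  expect_equal(cat_g$count[cat_g$code == "afo"], 2L)
})
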