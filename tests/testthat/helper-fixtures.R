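# Shared fixtures, built in code.

# Hand-built toy cohort: n patients, explicit scores and device sets.
toy_cohort <- function(gmfm, devices, gmfcs = NULL, age = NULL,
                       subtype = NULL) {
  n <- length(gmfm)
  if (is.null(gmfcs))
    gmfcs <- c("I", "II", "III", "IV", "V")[
      pmin(5L, pmax(1L, 6L - ceiling(gmfm / 20)))]
  if (is.null(age)) age <- seq(3, 15, length.out = n)
  if (is.null(subtype)) subtype <- rep("bilateral_spastic", n)
  cohort(data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = age,
    sex = rep(c("female", "male"), length.out = n),
    cp_subtype = subtype,
    gmfcs = gmfcs,
    gmfm66 = gmfm,
    stringsAsFactors = FALSE
  ), devices = devices)
}

# Memoized expensive fixtures shared across test files (cohorts and
# cross-fitted predictions at the default study size).
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_cohort_seed <- function(seed) {
  cached_fixture(paste0("cohort_", seed), function() {
    generate_cohort(default_sim_config(seed = seed))
  })
}

crossfit_seed <- function(seed) {
  cached_fixture(paste0("crossfit_", seed), function() {
    crossfit_mds(default_cohort_seed(seed), family = "RF", seed = seed)
  })
}

# 2-SE band (percentage points) for comparing two empirical power values
# estimated from `reps` Monte-Carlo repetitions each.
power_2se <- function(p1_pct, p2_pct, reps) {
  p1 <- p1_pct / 100; p2 <- p2_pct / 100
  200 * sqrt(p1 * (1 - p1) / reps + p2 * (1 - p2) / reps)
}

# exhaustive candidate list: every ordered half/half partition (for odd N,
# every choice of left-out patient)
exhaustive_candidates <- function(n) {
  half <- n %/% 2L
  out <- list()
  pool <- seq_len(n)
  a_sets <- utils::combn(n, half)
  for (j in seq_len(ncol(a_sets))) {
    a <- a_sets[, j]
    rest <- setdiff(pool, a)
    if (length(rest) == half) {
      out[[length(out) + 1L]] <- list(a = a, b = rest)
    } else {
      for (drop in rest)
        out[[length(out) + 1L]] <- list(a = a, b = setdiff(rest, drop))
    }
  }
  out
}
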