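# Synthetic cohort generator. All samplers draw from R's current RNG stream;
# generate_cohort() seeds that stream once from config$seed, so a single
# integer governs the whole cohort and sampling is reproducible bit-for-bit.

# Inversion sampler for a normal truncated to [lo, hi]: monotone in the
# uniform draw, so one RNG variate per sample regardless of bounds.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Mean of a normal(mean, sd) truncated to [lo, hi]; closed form, used by
# tests as an independent oracle and exported for power users.
truncnorm_mean <- function(mean, sd, lo, hi) {
  if (sd == 0) return(pmin(pmax(mean, lo), hi))
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

#' Sample GMFCS levels
#'
#' Draws GMFCS severity levels I--V from the configured marginal
#' distribution. Uses R's current RNG stream (seed it, or call via
#' \code{\link{generate_cohort}}).
#'
#' @param n Number of draws.
#' @param config A \code{\link{sim_config}}.
#' @return Character vector of levels in \code{c("I","II","III","IV","V")}.
#' @export
sample_gmfcs <- function(n, config) {
  validate_sim_config(config)
  GMFCS_LEVELS[sample.int(5L, n, replace = TRUE, prob = config$gmfcs_probs)]
}

#' Sample GMFM-66 scores given GMFCS level
#'
#' Conditional model: Normal(level mean, common SD) truncated to [0, 100].
#'
#' @param level Character vector of GMFCS levels.
#' @param config A \code{\link{sim_config}}.
#' @return Numeric scores in [0, 100], one per element of \code{level}.
#' @export
sample_gmfm_given_gmfcs <- function(level, config) {
  validate_sim_config(config)
  idx <- match(level, GMFCS_LEVELS)
  if (anyNA(idx)) stop("unknown GMFCS level", call. = FALSE)
  mu <- config$gmfm_level_means[idx]
  if (config$gmfm_level_sd == 0) return(mu)
  plo <- pnorm(0, mu, config$gmfm_level_sd)
  phi <- pnorm(100, mu, config$gmfm_level_sd)
  qnorm(runif(length(mu), plo, phi), mu, config$gmfm_level_sd)
}

#' Sample CP subtype given GMFCS level
#'
#' @param level Character vector of GMFCS levels.
#' @param config A \code{\link{sim_config}}.
#' @return Character vector of subtypes (see \code{CP_SUBTYPES}).
#' @export
sample_subtype_given_gmfcs <- function(level, config) {
  validate_sim_config(config)
  idx <- match(level, GMFCS_LEVELS)
  if (anyNA(idx)) stop("unknown GMFCS level", call. = FALSE)
  out <- character(length(idx))
  for (k in sort(unique(idx))) {
    sel <- idx == k
    out[sel] <- CP_SUBTYPES[sample.int(5L, sum(sel), replace = TRUE,
                                       prob = config$subtype_probs_by_level[k, ])]
  }
  out
}

# Usage probability of each device profile at score s (vectorized over s).
device_usage_prob <- function(profile, score) {
  profile$base_rate *
    exp(-(score - profile$score_center)^2 / (2 * profile$score_width^2))
}

#' Sample device sets given GMFM-66 scores
#'
#' Each device in the catalog is used independently with the profile's
#' Gaussian-bump probability evaluated at the patient's score; the resulting
#' set may be empty (plausible for mildly affected patients and retained).
#'
#' @param score Numeric vector of GMFM-66 scores in [0, 100].
#' @param config A \code{\link{sim_config}}.
#' @return List of character vectors of device codes, one per score.
#' @export
sample_devices <- function(score, config) {
  validate_sim_config(config)
  if (any(score < 0 | score > 100)) stop("score outside [0,100]", call. = FALSE)
  n <- length(score)
  use <- vapply(config$device_profiles, function(pr) {
    runif(n) < device_usage_prob(pr, score)
  }, logical(n))
  use <- matrix(use, nrow = n)
  codes <- vapply(config$device_profiles, `[[`, "", "code")
  lapply(seq_len(n), function(i) codes[use[i, ]])
}

#' Generate a synthetic cohort
#'
#' Composes the hierarchical samplers (GMFCS level, then GMFM-66 given level,
#' then subtype given level, device set given score; age independently) into
#' a full cohort. Deterministic given \code{config$seed}: the seed is set
#' once and all stages draw from that single stream in a fixed order.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A \code{\link{cohort}} object of \code{config$n_patients} records.
#' @examples
#' coh <- generate_cohort(default_sim_config(n_patients = 200, seed = 7))
#' table(coh$gmfcs)
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  n <- config$n_patients
  set.seed(config$seed)
  gmfcs <- sample_gmfcs(n, config)
  gmfm <- sample_gmfm_given_gmfcs(gmfcs, config)
  subtype <- sample_subtype_given_gmfcs(gmfcs, config)
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  sex <- SEX_LEVELS[sample.int(2L, n, replace = TRUE)]
  devices <- sample_devices(gmfm, config)
  labels <- setNames(vapply(config$device_profiles, `[[`, "", "label"),
                     vapply(config$device_profiles, `[[`, "", "code"))
  cohort(data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex, cp_subtype = subtype, gmfcs = gmfcs,
    gmfm66 = gmfm, stringsAsFactors = FALSE
  ), devices = devices, labels = labels)
}
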