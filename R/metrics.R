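#' Lin's concordance correlation coefficient
#'
#' Agreement between two measurements of the same quantity on the same
#' subjects:
#' \deqn{CCC = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},}
#' with moments using the n-divisor (Lin's original definition; the divisor
#' choice changes small-sample values and is therefore fixed and documented).
#' Unlike Pearson's r, the CCC penalizes location and scale shifts: it equals
#' 1 only for exact elementwise agreement, and |CCC| <= |r| always.
#'
#' Degenerate inputs: if both vectors are constant with equal means the
#' statistic is 0/0 and an error is raised; if at least one vector is
#' constant but the means differ, the covariance is zero against a positive
#' denominator and 0 is returned.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A single value in [-1, 1].
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))  # 4/7: perfect correlation, unit shift
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2)
  vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0)
    stop("CCC undefined: both inputs constant with equal means", call. = FALSE)
  2 * sxy / denom
}

#' Mean absolute error and root mean square error
#'
#' Standard definitions on paired scores; both are in GMFM-66 units when
#' applied to (true score, predicted score) pairs. \code{rmse >= mae} always
#' (Jensen).
#'
#' @param x,y Numeric vectors of equal, positive length.
#' @return A single non-negative value.
#' @export
mae <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must have equal length >= 1", call. = FALSE)
  mean(abs(x - y))
}

#' @rdname mae
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("x and y must have equal length >= 1", call. = FALSE)
  sqrt(mean((x - y)^2))
}

metric_fun <- function(metric) {
  switch(metric,
         ccc = lin_ccc, mae = mae, rmse = rmse,
         stop("unknown metric: ", metric, call. = FALSE))
}

#' Percentile-bootstrap confidence interval for an agreement metric
#'
#' Resamples whole patient pairs with replacement, recomputes the metric on
#' each resample, and returns the percentile interval. Resamples on which
#' the metric is undefined (e.g. a constant resample for the CCC) are
#' redrawn; the number of redraws is attached as attribute
#' \code{"n_redrawn"}. Attribute \code{"point_outside"} flags the rare
#' percentile-method case where the interval excludes the point estimate.
#'
#' @param metric One of \code{"ccc"}, \code{"mae"}, \code{"rmse"}.
#' @param x,y Paired score vectors.
#' @param reps Bootstrap replicates (>= 100; default 2000).
#' @param level Coverage level in (0, 1); default 0.95.
#' @param seed Integer seed.
#' @return Length-2 numeric \code{c(lo, hi)} with attributes as above.
#' @export
bootstrap_ci <- function(metric, x, y, reps = 2000L, level = 0.95,
                         seed = 1L) {
  if (reps < 100L) stop("reps must be >= 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  f <- metric_fun(metric)
  point <- f(x, y)
  n <- length(x)
  set.seed(seed)
  stat <- numeric(reps)
  redrawn <- 0L
  for (r in seq_len(reps)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      val <- tryCatch(f(x[idx], y[idx]), error = function(e) NULL)
      if (!is.null(val)) break
      redrawn <- redrawn + 1L
      if (redrawn > 100L * reps)
        stop("metric undefined on virtually every resample", call. = FALSE)
    }
    stat[r] <- val
  }
  alpha <- (1 - level) / 2
  ci <- unname(quantile(stat, c(alpha, 1 - alpha), type = 7))
  attr(ci, "n_redrawn") <- redrawn
  attr(ci, "point_outside") <- point < ci[1] || point > ci[2]
  ci
}

#' Full agreement report for paired scores
#'
#' Computes the three evaluation statistics used to judge the Medical Device
#' Score against the measured GMFM-66 — Lin's CCC, MAE and RMSE — each with
#' a percentile-bootstrap confidence interval over patient pairs.
#'
#' @param x True GMFM-66 scores.
#' @param y Predicted scores (MDS).
#' @param reps,level,seed Passed to \code{\link{bootstrap_ci}}.
#' @return Data frame with one row per metric: \code{metric},
#'   \code{estimate}, \code{lo}, \code{hi}, \code{n}, \code{reps}.
#' @export
metrics_report <- function(x, y, reps = 2000L, level = 0.95, seed = 1L) {
  rows <- lapply(c("ccc", "mae", "rmse"), function(m) {
    ci <- bootstrap_ci(m, x, y, reps = reps, level = level, seed = seed)
    data.frame(metric = m, estimate = metric_fun(m)(x, y),
               lo = ci[1], hi = ci[2], n = length(x), reps = reps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' GMFCS-stratified bias of the Medical Device Score
#'
#' Splits paired (GMFM-66, MDS) scores by GMFCS level and reports, per
#' level: pair count, mean signed error (MDS - GMFM; positive =
#' overestimation), mean absolute error, and quartiles of both score
#' sources. A bounded score predicted from device patterns shows a
#' floor/ceiling effect — underestimation at level I (mild, near the score
#' ceiling) and overestimation at level V (severe, near the floor) — and
#' this table is the diagnostic for it.
#'
#' @param gmfm True GMFM-66 scores.
#' @param mds Predicted scores.
#' @param strata GMFCS level per pair (character, I--V).
#' @return Data frame with one row per level (levels with no pairs get
#'   \code{n = 0} and \code{NA} statistics).
#' @export
stratified_bias <- function(gmfm, mds, strata) {
  if (length(gmfm) != length(mds) || length(gmfm) != length(strata))
    stop("gmfm, mds and strata must have equal length", call. = FALSE)
  if (any(!strata %in% GMFCS_LEVELS))
    stop("unknown GMFCS level in strata", call. = FALSE)
  rows <- lapply(GMFCS_LEVELS, function(lv) {
    sel <- strata == lv
    n <- sum(sel)
    if (n == 0L) {
      return(data.frame(gmfcs = lv, n = 0L, mean_signed_error = NA_real_,
                        mean_abs_error = NA_real_,
                        gmfm_q1 = NA_real_, gmfm_median = NA_real_,
                        gmfm_q3 = NA_real_, mds_q1 = NA_real_,
                        mds_median = NA_real_, mds_q3 = NA_real_,
                        stringsAsFactors = FALSE))
    }
    qg <- quantile(gmfm[sel], c(0.25, 0.5, 0.75), names = FALSE)
    qm <- quantile(mds[sel], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(gmfcs = lv, n = n,
               mean_signed_error = mean(mds[sel] - gmfm[sel]),
               mean_abs_error = mean(abs(mds[sel] - gmfm[sel])),
               gmfm_q1 = qg[1], gmfm_median = qg[2], gmfm_q3 = qg[3],
               mds_q1 = qm[1], mds_median = qm[2], mds_q3 = qm[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
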