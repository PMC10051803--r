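#' Random half/half split candidates
#'
#' Generates \code{k} independent uniformly random partitions of the cohort
#' into two groups of floor(N/2) patients each. For odd N, each candidate
#' leaves one uniformly chosen patient out (e.g. 1581 patients split into
#' 790 + 790 with 1 unused). Deterministic given \code{seed}.
#'
#' @param coh A cohort (or any data frame with \code{patient_id}).
#' @param k Number of candidate partitions (>= 1).
#' @param seed Integer seed.
#' @return List of candidates; each is a list with integer row-index vectors
#'   \code{a} and \code{b}.
#' @export
random_splits <- function(coh, k, seed = 1L) {
  n <- nrow(coh)
  if (n < 4L) stop("cohort too small to split", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  half <- n %/% 2L
  set.seed(seed)
  lapply(seq_len(k), function(i) {
    perm <- sample.int(n)
    list(a = perm[seq_len(half)], b = perm[half + seq_len(half)])
  })
}

#' Select the candidate split closest to a target score difference
#'
#' Among candidate partitions, returns the one whose absolute difference in
#' group mean scores is closest to \code{target_d} (ties broken by earliest
#' candidate). Groups are oriented so group A has the higher mean and
#' \code{achieved_d >= 0}. This is the split-selection device used to build
#' two populations with an engineered GMFM-66 difference out of one cohort.
#'
#' @param candidates List of candidates from \code{\link{random_splits}}.
#' @param scores Numeric score vector indexed by the candidates' row indices
#'   (the true GMFM-66 scores; the group difference is defined on the
#'   measured scale, never on predictions).
#' @param target_d Target mean difference, GMFM-66 units (>= 0).
#' @return A \code{split_pair}: list with \code{a}, \code{b} (row indices,
#'   A = higher-mean group), \code{target_d}, \code{achieved_d},
#'   \code{candidate_index}.
#' @export
select_split_for_difference <- function(candidates, scores, target_d) {
  if (!length(candidates)) stop("no candidates", call. = FALSE)
  if (target_d < 0) stop("target_d must be >= 0", call. = FALSE)
  diffs <- vapply(candidates, function(cand) {
    abs(mean(scores[cand$a]) - mean(scores[cand$b]))
  }, 0)
  best <- which.min(abs(diffs - target_d))  # which.min takes the first tie
  cand <- candidates[[best]]
  if (mean(scores[cand$a]) < mean(scores[cand$b]))
    cand <- list(a = cand$b, b = cand$a)
  structure(list(a = cand$a, b = cand$b, target_d = target_d,
                 achieved_d = diffs[best], candidate_index = best),
            class = "split_pair")
}

# Vectorized two-sample tests on subsample matrices: xa, xb are n x reps
# matrices (one subsample per column). Returns a logical rejection vector.
# The Welch and Student routes are closed-form on column moments (verified
# against stats::t.test in the test suite); Mann-Whitney falls back to
# stats::wilcox.test per column.
reject_two_sample <- function(xa, xb, test = "welch_t", alpha = 0.05,
                              two_sided = TRUE) {
  na <- nrow(xa); nb <- nrow(xb)
  if (test == "mann_whitney") {
    p <- vapply(seq_len(ncol(xa)), function(j) {
      wilcox.test(xa[, j], xb[, j], exact = FALSE,
                  alternative = if (two_sided) "two.sided" else "greater")$p.value
    }, 0)
    return(p < alpha)
  }
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- (colSums(xa^2) - na * ma^2) / (na - 1)
  vb <- (colSums(xb^2) - nb * mb^2) / (nb - 1)
  if (test == "welch_t") {
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else if (test == "student_t") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else stop("unknown test: ", test, call. = FALSE)
  p <- if (two_sided) 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
       else stats::pt(tstat, df, lower.tail = FALSE)
  p < alpha
}

#' Refine a split pair toward a target mean difference by patient swaps
#'
#' Selection among uniformly random halvings alone cannot engineer large
#' group differences: for a cohort of N patients with score SD sigma, the
#' mean difference of a random halving has SD about 2 sigma / sqrt(N)
#' (roughly 0.9 GMFM-66 points at N = 1581, sigma 19), so even the best of
#' 10,000 candidates differs by at most ~4 points. To construct groups that
#' differ "most precisely" by larger targets, this refinement greedily swaps
#' one patient of group A with one of group B — each swap changes the mean
#' difference by 2 (score_b - score_a) / m for groups of size m — always
#' choosing the swap that brings the achieved difference closest to the
#' target, until no swap improves it. Group sizes are preserved; orientation
#' keeps group A the higher-mean group.
#'
#' @param pair A \code{split_pair} (e.g. from
#'   \code{\link{select_split_for_difference}}).
#' @param scores Score vector indexed by the pair's row indices.
#' @param target_d Target mean difference (>= 0), score units.
#' @param max_iter Safety cap on swaps.
#' @return A refined \code{split_pair} with updated \code{achieved_d}.
#' @export
refine_split <- function(pair, scores, target_d, max_iter = 10000L) {
  a <- pair$a; b <- pair$b
  m <- length(a)
  if (mean(scores[a]) < mean(scores[b])) { tmp <- a; a <- b; b <- tmp }
  va <- scores[a]; vb <- scores[b]
  D <- mean(va) - mean(vb)
  for (iter in seq_len(max_iter)) {
    gap <- target_d - D
    if (abs(gap) < 1e-12) break
    # swapping a_i and b_j changes D by 2 (vb_j - va_i) / m; find the pair
    # whose change lands closest to the remaining gap
    want <- va + gap * m / 2        # ideal vb_j for each i
    ord <- order(vb)
    sb <- vb[ord]
    pos <- findInterval(want, sb)
    lo <- pmin(pmax(pos, 1L), m)
    hi <- pmin(pos + 1L, m)
    gap_lo <- abs(gap - 2 * (sb[lo] - va) / m)
    gap_hi <- abs(gap - 2 * (sb[hi] - va) / m)
    use_hi <- gap_hi < gap_lo
    best_each <- ifelse(use_hi, gap_hi, gap_lo)
    i <- which.min(best_each)
    j <- ord[if (use_hi[i]) hi[i] else lo[i]]
    if (best_each[i] >= abs(gap) - 1e-12) break  # no improving swap
    tmp <- a[i]; a[i] <- b[j]; b[j] <- tmp
    tmp <- va[i]; va[i] <- vb[j]; vb[j] <- tmp
    D <- mean(va) - mean(vb)
  }
  if (D < 0) { tmp <- a; a <- b; b <- tmp; D <- -D }
  structure(list(a = a, b = b, target_d = target_d, achieved_d = D,
                 candidate_index = pair$candidate_index),
            class = "split_pair")
}

#' Specification of the significance test used in power estimation
#'
#' @param test One of \code{"welch_t"} (default; robust to unequal
#'   variances), \code{"student_t"}, \code{"mann_whitney"}.
#' @param alpha Significance level in (0, 0.5]; default 0.05.
#' @param two_sided Two-sided test? Default TRUE.
#' @return A \code{test_spec} list.
#' @export
test_spec <- function(test = c("welch_t", "student_t", "mann_whitney"),
                      alpha = 0.05, two_sided = TRUE) {
  test <- match.arg(test)
  if (alpha <= 0 || alpha > 0.5) stop("alpha must be in (0, 0.5]",
                                      call. = FALSE)
  structure(list(test = test, alpha = alpha, two_sided = two_sided),
            class = "test_spec")
}

# Draw reps subsamples of size n without replacement from a score vector;
# returns an n x reps matrix of values.
draw_subsamples <- function(scores, n, reps) {
  vapply(seq_len(reps), function(r) scores[sample.int(length(scores), n)],
         numeric(n))
}

#' Empirical power of a two-group comparison by Monte Carlo
#'
#' Repeatedly draws \code{n} patients without replacement from each group,
#' applies the significance test to the drawn values, and reports the
#' rejection percentage. With both arguments set to the same group this
#' estimates the type-I error (times 100).
#'
#' @param scores_a,scores_b Score vectors of the two groups.
#' @param n Subsample size per group (<= each group size).
#' @param reps Monte-Carlo repetitions (>= 1; 10,000 for production runs).
#' @param spec A \code{\link{test_spec}}.
#' @param seed Integer seed.
#' @return Power in percent (0--100), with attribute \code{"reps"}.
#' @export
estimate_power <- function(scores_a, scores_b, n, reps = 10000L,
                           spec = test_spec(), seed = 1L) {
  if (n > length(scores_a) || n > length(scores_b))
    stop("n exceeds a group size", call. = FALSE)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  set.seed(seed)
  xa <- draw_subsamples(scores_a, n, reps)
  xb <- draw_subsamples(scores_b, n, reps)
  rej <- reject_two_sample(xa, xb, spec$test, spec$alpha, spec$two_sided)
  structure(100 * mean(rej), reps = reps)
}

#' Empirical power grid for GMFM-66 versus Medical Device Score
#'
#' The sample-size planning procedure: for each target difference \code{d},
#' one split pair is selected (on the true GMFM-66 scores) from
#' \code{k_splits} random half/half partitions; then, for every subsample
#' size \code{n}, power is estimated twice over the \emph{same} drawn
#' patients per repetition — once testing their GMFM-66 values, once their
#' MDS values. The paired drawing makes the two sources directly comparable
#' cell by cell; the grid shows how much larger \code{n} must be when the
#' predicted score replaces the measured one.
#'
#' @param coh A cohort.
#' @param mds Numeric MDS vector aligned to cohort rows, or a
#'   \code{prediction_result} covering every patient (e.g. from
#'   \code{\link{crossfit_mds}}).
#' @param d_list Target differences in GMFM-66 points (default 3:10).
#' @param n_list Subsample sizes (default c(30, 40, 50, 75, 100, 150, 200,
#'   250)).
#' @param k_splits Candidate partitions examined (default 10,000).
#' @param reps Monte-Carlo repetitions per cell (default 10,000).
#' @param spec A \code{\link{test_spec}}.
#' @param seed Integer seed.
#' @param refine If TRUE (default), the selected split is polished by
#'   \code{\link{refine_split}} so each target difference is achieved
#'   essentially exactly, and the splits for successive targets are chained
#'   (each refined from the previous one), giving an internally consistent
#'   family of engineered differences. With \code{refine = FALSE} only
#'   candidate selection is used, and targets beyond roughly
#'   \eqn{4\sigma/\sqrt{N}} times the extreme order statistic of the
#'   candidate pool are unattainable (\code{achieved_d} saturates; see
#'   \code{\link{refine_split}}).
#' @return A \code{power_grid} data frame with columns \code{n},
#'   \code{target_d}, \code{achieved_d}, \code{source} ("GMFM" or "MDS"),
#'   \code{power_pct}, \code{reps}, \code{seed}.
#' @export
power_table <- function(coh, mds, d_list = 3:10,
                        n_list = c(30, 40, 50, 75, 100, 150, 200, 250),
                        k_splits = 10000L, reps = 10000L,
                        spec = test_spec(), seed = 1L, refine = TRUE) {
  if (!length(d_list) || !length(n_list))
    stop("d_list and n_list must be non-empty", call. = FALSE)
  gmfm <- coh$gmfm66
  n_coh <- length(gmfm)
  if (any(n_list > n_coh %/% 2L))
    stop("n_list contains sizes exceeding half the cohort", call. = FALSE)
  if (inherits(mds, "data.frame")) {
    if (!all(coh$patient_id %in% mds$patient_id))
      stop("mds must cover every cohort patient", call. = FALSE)
    mds <- mds$mds[match(coh$patient_id, mds$patient_id)]
  }
  if (length(mds) != n_coh)
    stop("mds not aligned to cohort", call. = FALSE)
  rows <- list()
  d_order <- order(d_list)
  pairs <- vector("list", length(d_list))
  if (refine) {
    # one candidate pool; the split for the smallest target is selected from
    # it, then each larger target's split is refined from the previous one
    cands <- random_splits(coh, k_splits, seed = seed)
    prev <- select_split_for_difference(cands, gmfm, d_list[d_order[1]])
    for (di in d_order) {
      prev <- refine_split(prev, gmfm, d_list[di])
      pairs[[di]] <- prev
    }
  } else {
    for (di in d_order) {
      cands <- random_splits(coh, k_splits, seed = seed + di)
      pairs[[di]] <- select_split_for_difference(cands, gmfm, d_list[di])
    }
  }
  for (di in seq_along(d_list)) {
    d <- d_list[di]
    pair <- pairs[[di]]
    for (n in n_list) {
      set.seed(seed + 1000L * di + n)
      ia <- draw_subsamples(seq_along(pair$a), n, reps)
      ib <- draw_subsamples(seq_along(pair$b), n, reps)
      # identical drawn patients for both score sources
      for (source in c("GMFM", "MDS")) {
        vals <- if (source == "GMFM") gmfm else mds
        rej <- reject_two_sample(
          matrix(vals[pair$a[ia]], nrow = n),
          matrix(vals[pair$b[ib]], nrow = n),
          spec$test, spec$alpha, spec$two_sided)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, target_d = d, achieved_d = pair$achieved_d,
          source = source, power_pct = 100 * mean(rej),
          reps = reps, seed = as.integer(seed), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("power_grid", "data.frame")
  out
}

#' Smallest sample size reaching a power target
#'
#' Reads the required group size off an empirical power grid, the way a
#' study planner uses the power table: for a given target difference and
#' score source, the smallest \code{n} whose estimated power meets
#' \code{target_power}.
#'
#' @param grid A \code{power_grid} from \code{\link{power_table}}.
#' @param d Target difference (must be present in the grid).
#' @param source \code{"GMFM"} or \code{"MDS"}.
#' @param target_power Required power in percent (default 80).
#' @return The smallest qualifying \code{n}, or \code{NA} if no grid cell
#'   reaches the target.
#' @export
required_n <- function(grid, d, source = c("MDS", "GMFM"),
                       target_power = 80) {
  source <- match.arg(source)
  sel <- grid$target_d == d & grid$source == source &
    grid$power_pct >= target_power
  if (!any(sel)) return(NA_integer_)
  min(grid$n[sel])
}
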