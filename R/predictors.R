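PREDICTOR_FAMILIES <- c("RF", "SVM", "FNN", "XGBoost")

#' Train one predictor family on a feature matrix
#'
#' Fits one of the four model families compared for the Medical Device Score
#' Calculator: random forest (\code{randomForest}), support vector machine
#' (\code{e1071}, radial eps-regression), feed-forward neural net
#' (\code{nnet}, one hidden layer, linear output, standardized inputs), or
#' gradient boosting (\code{xgboost}). Library defaults are used throughout
#' (no tuning protocol is imposed); the only harness-set values are the FNN
#' topology (hidden size = number of features capped at 32, decay 0.1,
#' maxit 500) and the XGBoost round count (\code{nrounds = 100}), both
#' recorded in the returned handle's \code{hyperparameters}. Stochastic
#' families are seeded, so refits with the same seed are identical. A
#' zero-variance outcome yields a warning and a constant predictor.
#'
#' @param x Numeric feature matrix (rows = training patients).
#' @param y GMFM-66 outcome vector aligned to rows of \code{x}.
#' @param family One of \code{"RF"}, \code{"SVM"}, \code{"FNN"},
#'   \code{"XGBoost"}.
#' @param seed Integer seed.
#' @return An \code{mds_model} handle usable by \code{\link{predict_mds}}.
#' @export
train_predictor <- function(x, y, family = "RF", seed = 1L) {
  family <- match.arg(family, PREDICTOR_FAMILIES)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y))
    stop("features and outcome are not aligned", call. = FALSE)
  handle <- list(family = family, feature_names = colnames(x),
                 seed = as.integer(seed), hyperparameters = list())
  if (var(y) == 0) {
    warning("outcome has zero variance; returning a constant predictor")
    handle$constant <- y[1]
    class(handle) <- "mds_model"
    return(handle)
  }
  set.seed(seed)
  if (family == "RF") {
    handle$fit <- randomForest::randomForest(x = x, y = y)
    handle$hyperparameters <- list(ntree = handle$fit$ntree,
                                   mtry = handle$fit$mtry)
  } else if (family == "SVM") {
    handle$fit <- e1071::svm(x = x, y = y, type = "eps-regression",
                             kernel = "radial")
    handle$hyperparameters <- list(kernel = "radial",
                                   cost = handle$fit$cost,
                                   epsilon = handle$fit$epsilon,
                                   gamma = handle$fit$gamma)
  } else if (family == "FNN") {
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    scale[scale == 0] <- 1
    xs <- sweep(sweep(x, 2, center), 2, scale, "/")
    size <- min(ncol(x), 32L)
    handle$fit <- nnet::nnet(xs, y, size = size, linout = TRUE,
                             decay = 0.1, maxit = 500,
                             MaxNWts = 100000, trace = FALSE)
    handle$preproc <- list(center = center, scale = scale)
    handle$hyperparameters <- list(size = size, decay = 0.1, maxit = 500)
  } else { # XGBoost
    handle$fit <- xgboost::xgboost(x = x, y = y, nrounds = 100,
                                   nthreads = 1, verbosity = 0)
    handle$hyperparameters <- list(nrounds = 100, nthreads = 1)
  }
  class(handle) <- "mds_model"
  handle
}

#' Predict the Medical Device Score on held-out patients
#'
#' Applies a fitted model to a test feature matrix. Test columns must match
#' the training columns exactly (a mismatch error names the differing
#' columns). Predictions are clipped to the GMFM-66 range [0, 100] and
#' clipped pairs are flagged.
#'
#' @param model An \code{mds_model} from \code{\link{train_predictor}}.
#' @param x Test feature matrix.
#' @param ids Optional patient ids aligned to rows of \code{x}.
#' @param gmfm_true Optional true scores aligned to rows (carried into the
#'   result for downstream agreement analysis).
#' @return A \code{prediction_result} data frame with columns
#'   \code{patient_id}, \code{gmfm_true}, \code{mds}, \code{clipped}, and
#'   attribute \code{"family"}.
#' @export
predict_mds <- function(model, x, ids = NULL, gmfm_true = NULL) {
  stopifnot(inherits(model, "mds_model"))
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!identical(colnames(x), model$feature_names)) {
    extra <- setdiff(colnames(x), model$feature_names)
    missing <- setdiff(model$feature_names, colnames(x))
    stop("feature columns differ from training columns",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  n <- nrow(x)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(gmfm_true)) gmfm_true <- rep(NA_real_, n)
  raw <- if (n == 0L) {
    numeric(0)
  } else if (!is.null(model$constant)) {
    rep(model$constant, n)
  } else if (model$family == "FNN") {
    xs <- sweep(sweep(x, 2, model$preproc$center), 2, model$preproc$scale, "/")
    as.numeric(predict(model$fit, xs))
  } else if (model$family == "XGBoost") {
    as.numeric(predict(model$fit, x))
  } else {
    as.numeric(predict(model$fit, x))
  }
  if (any(!is.finite(raw))) stop("non-finite prediction", call. = FALSE)
  clipped <- raw < 0 | raw > 100
  out <- data.frame(patient_id = as.character(ids), gmfm_true = gmfm_true,
                    mds = pmin(pmax(raw, 0), 100), clipped = clipped,
                    stringsAsFactors = FALSE)
  attr(out, "family") <- model$family
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Out-of-fold Medical Device Scores for every patient
#'
#' Cross-fitting: partitions the cohort into \code{n_folds} folds and
#' predicts each patient's MDS from a model trained on the other folds, so
#' no patient's score is predicted by a model that saw it. Use this when a
#' downstream analysis (e.g. the power procedure) needs an MDS for all
#' patients without in-sample optimism.
#'
#' @param coh A cohort (min-count filtered before encoding).
#' @param family Predictor family tag.
#' @param n_folds Number of folds (2 <= n_folds <= N).
#' @param seed Integer seed (fold assignment and per-fold training).
#' @param min_n Device min-count threshold applied before encoding.
#' @return A \code{prediction_result} covering every patient, with
#'   \code{gmfcs} carried as an extra column for stratified diagnostics.
#' @export
crossfit_mds <- function(coh, family = "RF", n_folds = 5L, seed = 1L,
                         min_n = 5L) {
  n <- nrow(coh)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (n_folds > n) stop("n_folds exceeds cohort size", call. = FALSE)
  coh <- min_count_filter(coh, min_n)
  fm <- encode_features(coh)
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  parts <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    test <- fold == k
    model <- train_predictor(fm$x[!test, , drop = FALSE], fm$y[!test],
                             family = family, seed = seed + k)
    parts[[k]] <- predict_mds(model, fm$x[test, , drop = FALSE],
                              ids = fm$ids[test], gmfm_true = fm$y[test])
  }
  out <- do.call(rbind, parts)
  out <- out[match(fm$ids, out$patient_id), ]
  rownames(out) <- NULL
  out$gmfcs <- coh$gmfcs
  attr(out, "family") <- family
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Compare the four predictor families on one holdout split
#'
#' Runs the full evaluation protocol: min-count filter, GMFCS-free feature
#' encoding, a 70/30 train/holdout split, training each requested family on
#' the same training matrix, predicting the holdout, and scoring agreement
#' (CCC, MAE, RMSE with bootstrap CIs).
#'
#' @param coh A cohort.
#' @param families Character vector of family tags (default all four).
#' @param split_seed Seed for the holdout split.
#' @param train_seed Seed for model training.
#' @param fraction Training fraction (default 0.7).
#' @param min_n Device min-count threshold (default 5).
#' @param reps Bootstrap replicates for the CIs.
#' @return List with \code{report} (one row per family x metric),
#'   \code{predictions} (named list of \code{prediction_result}s), and
#'   \code{split}.
#' @export
evaluate_families <- function(coh, families = PREDICTOR_FAMILIES,
                              split_seed = 1L, train_seed = 1L,
                              fraction = 0.7, min_n = 5L, reps = 2000L) {
  families <- match.arg(families, PREDICTOR_FAMILIES, several.ok = TRUE)
  coh <- min_count_filter(coh, min_n)
  fm <- encode_features(coh)
  split <- holdout_split(coh, fraction = fraction, seed = split_seed)
  tr <- fm$ids %in% split$train_ids
  preds <- list()
  rows <- list()
  for (fam in families) {
    model <- train_predictor(fm$x[tr, , drop = FALSE], fm$y[tr],
                             family = fam, seed = train_seed)
    pr <- predict_mds(model, fm$x[!tr, , drop = FALSE],
                      ids = fm$ids[!tr], gmfm_true = fm$y[!tr])
    pr$gmfcs <- coh$gmfcs[!tr]
    preds[[fam]] <- pr
    rep_fam <- metrics_report(pr$gmfm_true, pr$mds, reps = reps,
                              seed = train_seed)
    rep_fam$family <- fam
    rows[[fam]] <- rep_fam
  }
  report <- do.call(rbind, rows)
  report <- report[, c("family", "metric", "estimate", "lo", "hi", "n",
                       "reps")]
  rownames(report) <- NULL
  list(report = report, predictions = preds, split = split)
}
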