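#' Construct a cohort object
#'
#' A cohort is a data frame with one row per patient (columns
#' \code{patient_id}, \code{age}, \code{sex}, \code{cp_subtype},
#' \code{gmfcs}, \code{gmfm66}, and a list-column \code{devices} of device
#' codes) plus a device catalog attribute mapping each code to its label and
#' cohort-wide usage count. Validation enforces the clinical ranges:
#' GMFM-66 in [0, 100], age in [2, 26), GMFCS in I--V, known subtype,
#' unique patient ids, unique device codes within a record.
#'
#' @param records Data frame with the patient columns above (without
#'   \code{devices}).
#' @param devices List of character vectors of device codes, one per record.
#' @param labels Optional named character vector mapping device codes to
#'   labels; unmapped codes get their code as label.
#' @return An object of class \code{cp_cohort} (also a \code{data.frame}).
#' @export
cohort <- function(records, devices, labels = character()) {
  records$devices <- devices
  coh <- structure(records, class = c("cp_cohort", "data.frame"))
  attr(coh, "device_labels") <- labels
  validate_cohort(coh)
  attr(coh, "catalog") <- device_catalog(coh)
  coh
}

validate_cohort <- function(coh) {
  need <- c("patient_id", "age", "sex", "cp_subtype", "gmfcs", "gmfm66",
            "devices")
  miss <- setdiff(need, names(coh))
  if (length(miss))
    stop("cohort missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  problems <- character()
  row_problem <- function(rows, what) {
    if (length(rows))
      problems <<- c(problems,
                     paste0(what, " (row ", paste(rows, collapse = ", "), ")"))
  }
  row_problem(which(coh$gmfm66 < 0 | coh$gmfm66 > 100 | is.na(coh$gmfm66)),
              "gmfm66 outside [0,100]")
  row_problem(which(coh$age < 2 | coh$age >= 26 | is.na(coh$age)),
              "age outside [2, 26)")
  row_problem(which(!coh$gmfcs %in% GMFCS_LEVELS), "unknown GMFCS level")
  row_problem(which(!coh$cp_subtype %in% CP_SUBTYPES), "unknown CP subtype")
  row_problem(which(!coh$sex %in% SEX_LEVELS), "unknown sex")
  row_problem(which(vapply(coh$devices, anyDuplicated, 0L) > 0),
              "duplicate device code within record")
  if (anyDuplicated(coh$patient_id))
    problems <- c(problems, "duplicate patient_id")
  if (length(problems))
    stop("invalid cohort: ", paste(problems, collapse = "; "), call. = FALSE)
  invisible(coh)
}

#' Device catalog of a cohort
#'
#' Recomputes usage counts from the records (the stored catalog attribute is
#' kept consistent with this by every cohort-modifying operation).
#'
#' @param coh A cohort.
#' @return Data frame with columns \code{code}, \code{label}, \code{count},
#'   sorted by decreasing count then code.
#' @export
device_catalog <- function(coh) {
  all_codes <- unlist(coh$devices, use.names = FALSE)
  if (!length(all_codes))
    return(data.frame(code = character(0), label = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  tab <- table(all_codes)
  labels <- attr(coh, "device_labels")
  code <- names(tab)
  lab <- ifelse(code %in% names(labels), labels[code], code)
  out <- data.frame(code = code, label = unname(lab),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$code), ]
  rownames(out) <- NULL
  out
}

#' Write / read a cohort as CSV
#'
#' Plain UTF-8 comma-separated values with a header; the device set is
#' serialized pipe-delimited inside one \code{devices} field (empty field =
#' empty set). \code{read_cohort} validates every row and reports offending
#' row numbers; write-then-read is an identity on the patient data.
#'
#' @param coh A cohort.
#' @param path File path.
#' @return \code{read_cohort} returns a \code{cp_cohort};
#'   \code{write_cohort} returns \code{path} invisibly.
#' @export
write_cohort <- function(coh, path) {
  validate_cohort(coh)
  df <- as.data.frame(coh[, c("patient_id", "age", "sex", "cp_subtype",
                              "gmfcs", "gmfm66")])
  df$devices <- vapply(coh$devices, paste, "", collapse = "|")
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop("cohort file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("patient_id", "age", "sex", "cp_subtype", "gmfcs", "gmfm66",
            "devices")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort file missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$patient_id <- as.character(df$patient_id)
  dev_field <- as.character(df$devices)
  dev_field[is.na(dev_field)] <- ""
  devices <- lapply(strsplit(dev_field, "|", fixed = TRUE),
                    function(x) x[nzchar(x)])
  df$devices <- NULL
  cohort(df, devices = devices)
}

#' Regroup device codes before filtering
#'
#' The raw device inventory of a clinical registry is typically grouped into
#' coarser categories before analysis. The grouping is supplied as a mapping
#' (device code to group code); codes absent from the map are kept as-is
#' (identity default). Duplicate group codes arising within one record are
#' collapsed.
#'
#' @param coh A cohort.
#' @param map Data frame with columns \code{device_code}, \code{group_code},
#'   or a path to such a CSV.
#' @return The regrouped cohort.
#' @export
apply_device_grouping <- function(coh, map) {
  if (is.character(map)) map <- read.csv(map, stringsAsFactors = FALSE)
  stopifnot(all(c("device_code", "group_code") %in% names(map)))
  lut <- setNames(map$group_code, map$device_code)
  devices <- lapply(coh$devices, function(d) {
    mapped <- ifelse(d %in% names(lut), lut[d], d)
    unique(unname(mapped))
  })
  labels <- attr(coh, "device_labels")
  cohort(as.data.frame(coh[, setdiff(names(coh), "devices")]),
         devices = devices, labels = labels)
}

#' Remove rarely used devices
#'
#' Devices used by fewer than \code{min_n} patients cohort-wide are dropped
#' from the catalog and stripped from every record's device set (the default
#' threshold of 5 follows the study protocol of keeping only groups with a
#' minimum count of n = 5, read inclusively: count >= \code{min_n} is kept).
#' Patients themselves are never removed. Idempotent.
#'
#' @param coh A cohort.
#' @param min_n Minimum usage count a device needs to be retained (>= 1).
#' @return The filtered cohort.
#' @export
min_count_filter <- function(coh, min_n = 5L) {
  if (min_n < 1) stop("min_n must be >= 1", call. = FALSE)
  cat <- device_catalog(coh)
  keep <- cat$code[cat$count >= min_n]
  devices <- lapply(coh$devices, function(d) d[d %in% keep])
  cohort(as.data.frame(coh[, setdiff(names(coh), "devices")]),
         devices = devices, labels = attr(coh, "device_labels"))
}

#' Encode GMFCS-free predictor features
#'
#' Builds the model matrix used by every predictor family: one binary
#' indicator per retained device (lexicographic by code), then age
#' (continuous, years), then five one-hot CP-subtype columns. The GMFCS
#' level is deliberately excluded: the score predictor must work from data
#' a payer registry holds, which does not include clinical GMFCS grading.
#' A debug flag can re-admit GMFCS (as an integer 1--5 column) for leakage
#' audits only.
#'
#' @param coh A cohort (device catalog already min-count filtered).
#' @param include_sex,include_anthropometrics Optional flags to add sex and
#'   (if present in the records) height/weight columns; off by default, the
#'   standard feature set is devices + age + subtype.
#' @param include_gmfcs Debug flag; never use for reported models.
#' @return A \code{feature_matrix}: list with \code{x} (numeric matrix),
#'   \code{y} (GMFM-66 outcome vector), \code{ids} (patient ids aligned to
#'   rows).
#' @export
encode_features <- function(coh, include_sex = FALSE,
                            include_anthropometrics = FALSE,
                            include_gmfcs = FALSE) {
  validate_cohort(coh)
  cat <- device_catalog(coh)
  if (nrow(cat) == 0L)
    stop("empty device catalog: nothing to predict from", call. = FALSE)
  codes <- sort(cat$code)
  n <- nrow(coh)
  dev <- vapply(codes, function(cd) {
    as.numeric(vapply(coh$devices, function(d) cd %in% d, NA))
  }, numeric(n))
  dev <- matrix(dev, nrow = n, dimnames = list(NULL, paste0("dev_", codes)))
  sub <- vapply(CP_SUBTYPES, function(s) as.numeric(coh$cp_subtype == s),
                numeric(n))
  sub <- matrix(sub, nrow = n,
                dimnames = list(NULL, paste0("subtype_", CP_SUBTYPES)))
  x <- cbind(dev, age = coh$age, sub)
  if (include_sex) x <- cbind(x, sex_male = as.numeric(coh$sex == "male"))
  if (include_anthropometrics) {
    for (col in intersect(c("height", "weight"), names(coh)))
      x <- cbind(x, setNames(list(coh[[col]]), col)[[1]])
  }
  if (include_gmfcs) x <- cbind(x, gmfcs_debug = match(coh$gmfcs, GMFCS_LEVELS))
  structure(list(x = x, y = coh$gmfm66, ids = coh$patient_id),
            class = "feature_matrix")
}

#' Random train/holdout partition
#'
#' Uniformly random split of the cohort into a training set of
#' round(fraction * N) patients (half-up rounding) and a holdout set of the
#' rest; deterministic given \code{seed}. The default 0.7 mirrors the 70/30
#' protocol used to evaluate the score predictor.
#'
#' @param coh A cohort (or anything with a \code{patient_id} column).
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with \code{train_ids}, \code{test_ids}, \code{fraction},
#'   \code{seed}.
#' @export
holdout_split <- function(coh, fraction = 0.7, seed = 1L) {
  ids <- coh$patient_id
  n <- length(ids)
  if (n < 2L) stop("need at least 2 patients to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  n_train <- floor(fraction * n + 0.5)  # round half up
  if (n_train < 1L || n_train >= n)
    stop("fraction yields an empty train or test set", call. = FALSE)
  set.seed(seed)
  train <- sort(sample.int(n, n_train))
  list(train_ids = ids[train], test_ids = ids[-train],
       fraction = fraction, seed = as.integer(seed))
}
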