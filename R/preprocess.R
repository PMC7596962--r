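#' Filter a cohort to the eligible admission set
#'
#' Retains admissions with age >= 18 years, length of stay >= 1 day, at
#' least one temporal observation and at least one note. Order is
#' preserved and the operation is idempotent.
#'
#' @param cohort An `ehr_cohort`.
#' @return The filtered `ehr_cohort`.
#' @export
filter_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  st <- cohort$static
  has_obs <- st$admission_id %in% cohort$observations$admission_id
  has_note <- st$admission_id %in% cohort$notes$admission_id
  keep <- st$age >= 18 & st$length_of_stay >= 1 & has_obs & has_note
  ids <- st$admission_id[keep]
  subset_cohort(cohort, ids)
}

#' Subset a cohort by admission ids (order of `ids` is respected)
#' @param cohort An `ehr_cohort`.
#' @param ids Character vector of admission ids.
#' @return An `ehr_cohort` restricted to `ids`.
#' @export
subset_cohort <- function(cohort, ids) {
  st <- cohort$static[match(ids, cohort$static$admission_id), , drop = FALSE]
  rownames(st) <- NULL
  ob <- cohort$observations[cohort$observations$admission_id %in% ids, , drop = FALSE]
  rownames(ob) <- NULL
  nt <- cohort$notes[cohort$notes$admission_id %in% ids, , drop = FALSE]
  rownames(nt) <- NULL
  new_ehr_cohort(st, ob, nt, cohort$variables, cohort$config)
}

# Age group boundaries: half-open [18,25), [25,45), [45,65), [65,89), [89,Inf)
age_breaks <- c(18, 25, 45, 65, 89, Inf)
age_bucket_labels <- c("[18,25)", "[25,45)", "[45,65)", "[65,89)", "[89,Inf)")

#' Age group index for adult ages
#' @param age Numeric vector of ages (>= 18).
#' @return Integer bucket index in 1..5.
#' @export
age_bucket <- function(age) {
  if (any(age < 18)) stop("age_bucket is defined for adult ages (>= 18)")
  findInterval(age, age_breaks)
}

#' Build the one-hot layout for static features from a training split
#'
#' The layout freezes, per categorical field, the set of category levels
#' observed in the training data (age uses the five fixed adult buckets).
#' Encoding any later split against this layout guarantees identical
#' feature positions; unseen levels map to an all-zero block.
#'
#' @param static_df The `static` data frame of the training split.
#' @return A `static_layout`: data frame with columns `field`, `category`.
#' @export
static_layout <- function(static_df) {
  fields <- c("gender", "marital_status", "ethnicity", "insurance",
              "admission_type")
  rows <- data.frame(field = "age_group", category = age_bucket_labels,
                     stringsAsFactors = FALSE)
  for (f in fields) {
    lv <- sort(unique(static_df[[f]]))
    if (length(lv)) {
      rows <- rbind(rows, data.frame(field = f, category = lv,
                                     stringsAsFactors = FALSE))
    }
  }
  structure(rows, class = c("static_layout", "data.frame"))
}

#' One-hot encode static features against a frozen layout
#'
#' @param static_df A `static` data frame (any split).
#' @param layout A [static_layout()].
#' @return Numeric matrix (admissions x layout rows); within each field's
#'   block exactly one position is 1 for a known level, all zero for an
#'   unseen level.
#' @export
encode_static <- function(static_df, layout) {
  n <- nrow(static_df)
  d <- nrow(layout)
  out <- matrix(0, n, d,
                dimnames = list(static_df$admission_id,
                                paste(layout$field, layout$category, sep = "=")))
  if (n == 0) return(out)
  key <- paste(layout$field, layout$category, sep = "=")
  vals <- cbind(
    paste0("age_group=", age_bucket_labels[age_bucket(static_df$age)]),
    paste0("gender=", static_df$gender),
    paste0("marital_status=", static_df$marital_status),
    paste0("ethnicity=", static_df$ethnicity),
    paste0("insurance=", static_df$insurance),
    paste0("admission_type=", static_df$admission_type))
  for (j in seq_len(ncol(vals))) {
    col <- match(vals[, j], key)
    ok <- !is.na(col)
    out[cbind(which(ok), col[ok])] <- 1
  }
  out
}

#' Hourly binning of temporal observations for one or all admissions
#'
#' Builds, per admission, a 24 x V grid whose cell (h, v) is the
#' arithmetic mean of all observations of variable v with time offset in
#' \[h-1, h) hours; observations at offset >= 24 h (or < 0) are discarded.
#' A parallel mask marks cells backed by at least one observation.
#'
#' @param cohort An `ehr_cohort`.
#' @return A `temporal_tensor`: list with `values` and `mask`, both
#'   arrays of dim (admissions, 24, V), dimnames carrying admission ids
#'   and variable names.
#' @export
bin_temporal <- function(cohort) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  ids <- cohort$static$admission_id
  vars <- cohort$variables$variable
  ob <- cohort$observations
  unknown <- setdiff(unique(ob$variable), vars)
  if (length(unknown)) {
    stop("observations reference undeclared variables: ",
         paste(unknown, collapse = ", "))
  }
  n <- length(ids); V <- length(vars)
  values <- array(0, c(n, 24L, V), dimnames = list(ids, NULL, vars))
  mask <- array(0L, c(n, 24L, V), dimnames = list(ids, NULL, vars))
  ob <- ob[ob$hour_offset >= 0 & ob$hour_offset < 24, , drop = FALSE]
  if (nrow(ob)) {
    dt <- data.table::data.table(
      ai = match(ob$admission_id, ids),
      hi = as.integer(floor(ob$hour_offset)) + 1L,
      vi = match(ob$variable, vars),
      value = ob$value)
    dt <- dt[!is.na(dt$ai)]
    agg <- dt[, list(m = mean(value)), by = c("ai", "hi", "vi")]
    idx <- cbind(agg$ai, agg$hi, agg$vi)
    values[idx] <- agg$m
    mask[idx] <- 1L
  }
  structure(list(values = values, mask = mask),
            class = "temporal_tensor")
}

#' Fit per-variable min-max normalization statistics on a training split
#'
#' Statistics are computed over *observed* hourly cells of the training
#' admissions only, so validation/test observations can never leak into
#' the normalization.
#'
#' @param tensor A `temporal_tensor` from [bin_temporal()].
#' @param train_ids Admission ids of the training split.
#' @return A `normalization_stats` data frame: `variable`, `min`, `max`,
#'   `n_obs`. Variables never observed in training get `NA` bounds (their
#'   normalized column is all zeros, with a warning at application time).
#' @export
fit_normalization <- function(tensor, train_ids = NULL) {
  ids <- dimnames(tensor$values)[[1]]
  rows <- if (is.null(train_ids)) seq_along(ids) else match(train_ids, ids)
  if (anyNA(rows)) stop("train_ids not present in tensor")
  vars <- dimnames(tensor$values)[[3]]
  V <- length(vars)
  mn <- mx <- rep(NA_real_, V)
  nobs <- integer(V)
  for (v in seq_len(V)) {
    vals <- tensor$values[rows, , v]
    obs <- tensor$mask[rows, , v] == 1L
    nobs[v] <- sum(obs)
    if (nobs[v] > 0) {
      mn[v] <- min(vals[obs])
      mx[v] <- max(vals[obs])
    }
  }
  structure(data.frame(variable = vars, min = mn, max = mx, n_obs = nobs,
                       stringsAsFactors = FALSE),
            class = c("normalization_stats", "data.frame"))
}

#' Apply min-max normalization with zero imputation
#'
#' Observed cells are mapped to `(x - min_v) / (max_v - min_v)` and
#' clipped to \[0, 1\] (values outside the training range can occur on
#' held-out splits). Unobserved cells are imputed with exactly 0. A
#' degenerate training range (max == min) maps to 0.
#'
#' @param tensor A `temporal_tensor`.
#' @param stats A `normalization_stats` from [fit_normalization()].
#' @return A `temporal_tensor` with normalized `values` (all in \[0,1\])
#'   and the original `mask`.
#' @export
apply_normalization <- function(tensor, stats) {
  vars <- dimnames(tensor$values)[[3]]
  if (!identical(vars, stats$variable)) stop("variable order mismatch")
  out <- tensor$values
  never <- is.na(stats$min)
  if (any(never)) {
    warning("variables never observed in training set to zero: ",
            paste(stats$variable[never], collapse = ", "))
  }
  for (v in seq_along(vars)) {
    rng <- stats$max[v] - stats$min[v]
    if (is.na(rng) || rng == 0) {
      out[, , v] <- 0
    } else {
      z <- (tensor$values[, , v] - stats$min[v]) / rng
      out[, , v] <- pmin(pmax(z, 0), 1)
    }
  }
  out[tensor$mask == 0L] <- 0
  structure(list(values = out, mask = tensor$mask), class = "temporal_tensor")
}

#' Per-variable summary aggregations for the baseline models
#'
#' For each admission and each variable, computes
#' (mean, min, max, sd, count) over the *observed* hourly cells of the raw
#' (pre-normalization) grid. The standard deviation uses the population
#' formula (divide by count), so a single observed cell gives sd 0; a
#' variable with no observed cells contributes (0, 0, 0, 0, 0).
#'
#' @param tensor A raw `temporal_tensor` from [bin_temporal()].
#' @return Numeric matrix (admissions x 5V); columns are grouped by
#'   variable in panel order, named `<variable>.<stat>`.
#' @export
aggregate_for_baselines <- function(tensor) {
  dn <- dimnames(tensor$values)
  n <- dim(tensor$values)[1]; V <- dim(tensor$values)[3]
  stats_names <- c("mean", "min", "max", "sd", "count")
  out <- matrix(0, n, 5L * V,
                dimnames = list(dn[[1]],
                                paste(rep(dn[[3]], each = 5L), stats_names,
                                      sep = ".")))
  for (v in seq_len(V)) {
    vals <- matrix(tensor$values[, , v], nrow = n)
    obs <- matrix(tensor$mask[, , v] == 1L, nrow = n)
    cnt <- rowSums(obs)
    sm <- rowSums(vals * obs)
    mu <- ifelse(cnt > 0, sm / cnt, 0)
    sq <- rowSums((vals - mu)^2 * obs)
    sdv <- ifelse(cnt > 0, sqrt(sq / cnt), 0)
    vals_na <- vals
    vals_na[!obs] <- NA
    mnv <- suppressWarnings(apply(vals_na, 1, min, na.rm = TRUE))
    mxv <- suppressWarnings(apply(vals_na, 1, max, na.rm = TRUE))
    mnv[!is.finite(mnv)] <- 0
    mxv[!is.finite(mxv)] <- 0
    block <- (v - 1L) * 5L
    out[, block + 1L] <- mu
    out[, block + 2L] <- mnv
    out[, block + 3L] <- mxv
    out[, block + 4L] <- sdv
    out[, block + 5L] <- cnt
  }
  out
}

#' Random 70/10/20 train/validation/test split at the admission level
#'
#' @param cohort An `ehr_cohort` (or an admission-id character vector).
#' @param seed Integer seed driving the permutation.
#' @param ratios Length-3 proportions for train/validation (test takes the
#'   remainder); defaults `c(0.7, 0.1, 0.2)`.
#' @return List with character vectors `train`, `validation`, `test`:
#'   disjoint, exhaustive, of sizes floor(0.7 n), floor(0.1 n), rest.
#' @export
split_data <- function(cohort, seed, ratios = c(0.7, 0.1, 0.2)) {
  ids <- if (inherits(cohort, "ehr_cohort")) cohort$static$admission_id else cohort
  n <- length(ids)
  if (n < 10) stop("split_data needs at least 10 admissions")
  stopifnot(length(ratios) == 3, all(ratios > 0), abs(sum(ratios) - 1) < 1e-8)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(ratios[1] * n)
  n_val <- floor(ratios[2] * n)
  list(train = ids[perm[seq_len(n_train)]],
       validation = ids[perm[n_train + seq_len(n_val)]],
       test = ids[perm[(n_train + n_val + 1L):n]])
}
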