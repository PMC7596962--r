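#' Configuration for the synthetic EHR cohort generator
#'
#' Builds a validated configuration object for [generate_cohort()]. The
#' generator emulates the statistical structure of a critical-care cohort:
#' static demographics and admission information, irregular hourly vital-sign
#' and lab time series inside the first 24 h of admission, variable-length
#' sequences of clinical notes whose token content carries outcome signal,
#' and three binary outcome labels (in-hospital mortality, 30-day
#' readmission, long length of stay).
#'
#' Outcome labels are driven by a per-admission latent risk score
#' \deqn{r = w_S g_S + w_T g_T + w_U g_U + \epsilon,}
#' where \eqn{g_S} is a standardized static summary (age plus an emergency
#' admission indicator), \eqn{g_T} is a latent physiological severity factor
#' loading on every temporal variable, \eqn{g_U} is a latent note factor
#' tilting note tokens toward a risk topic, and \eqn{\epsilon} is Gaussian
#' noise (sd 0.5). Each task label is Bernoulli with probability
#' \eqn{\sigma(\alpha + r)}; the intercept \eqn{\alpha} is calibrated by
#' bisection so the mean predicted probability over the realized cohort
#' equals the requested prevalence.
#'
#' @param n_admissions Number of admissions to generate.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param prevalence Named or unnamed numeric vector of length 3 giving the
#'   target prevalence for mortality, readmission and long length of stay.
#'   Defaults to the task base rates of a large ICU cohort
#'   (0.096, 0.057, 0.499).
#' @param static_signal,temporal_signal,note_signal Non-negative weights
#'   \eqn{w_S, w_T, w_U} of each modality in the latent risk score.
#' @param missing_rate Probability in \[0, 1) that an (hour, variable) cell
#'   carries no observation.
#' @param vocab_size Size of the note token vocabulary (split evenly into a
#'   risk topic and a background topic).
#' @param notes_per_admission_range Integer interval (length 2) for the
#'   number of notes per admission.
#' @param tokens_per_note_range Integer interval (length 2) for the number
#'   of tokens per note.
#' @param n_vitals,n_labs Number of vital-sign and lab-test variables. With
#'   the defaults (7, 19) the variables carry the names and marginal
#'   location/scale of the standard ICU panel (heart rate, blood pressures,
#'   respiratory rate, temperature, SpO2; anion gap through WBC).
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_admissions,
                          seed = 1L,
                          prevalence = c(mortality = 0.096,
                                         readmission = 0.057,
                                         long_los = 0.499),
                          static_signal = 1,
                          temporal_signal = 1,
                          note_signal = 1,
                          missing_rate = 0.5,
                          vocab_size = 200L,
                          notes_per_admission_range = c(2L, 8L),
                          tokens_per_note_range = c(20L, 60L),
                          n_vitals = 7L,
                          n_labs = 19L) {
  stopifnot(length(n_admissions) == 1, is.numeric(n_admissions),
            length(seed) == 1, is.numeric(seed))
  if (length(prevalence) != 3 || !is.numeric(prevalence)) {
    stop("`prevalence` must be a numeric vector of length 3")
  }
  if (any(prevalence <= 0) || any(prevalence >= 1)) {
    stop("each prevalence must lie strictly in (0, 1)")
  }
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)")
  }
  if (any(c(static_signal, temporal_signal, note_signal) < 0)) {
    stop("signal weights must be non-negative")
  }
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2] && r[1] >= 0
  if (!rng_ok(notes_per_admission_range) || !rng_ok(tokens_per_note_range)) {
    stop("note/token ranges must be non-empty integer intervals")
  }
  if (vocab_size < 4) stop("`vocab_size` must be at least 4")
  names(prevalence) <- c("mortality", "readmission", "long_los")
  structure(list(
    n_admissions = as.integer(n_admissions),
    seed = as.integer(seed),
    prevalence = prevalence,
    static_signal = static_signal,
    temporal_signal = temporal_signal,
    note_signal = note_signal,
    missing_rate = missing_rate,
    vocab_size = as.integer(vocab_size),
    notes_per_admission_range = as.integer(notes_per_admission_range),
    tokens_per_note_range = as.integer(tokens_per_note_range),
    n_vitals = as.integer(n_vitals),
    n_labs = as.integer(n_labs)
  ), class = "cohort_config")
}

# Marginal location/scale of the standard 7-vital / 19-lab ICU panel, used
# when the config asks for the default panel so synthetic values live on a
# clinically familiar scale. Arbitrary-width panels fall back to N(0, 1).
default_variable_panel <- function() {
  data.frame(
    variable = c("heart_rate", "sysbp", "diasbp", "meanbp", "resp_rate",
                 "temperature", "spo2",
                 "anion_gap", "albumin", "bands", "bicarbonate", "bilirubin",
                 "creatinine", "chloride", "glucose", "hematocrit",
                 "hemoglobin", "lactate", "platelet", "potassium", "ptt",
                 "inr", "pt", "sodium", "bun", "wbc"),
    kind = rep(c("vital", "lab"), c(7L, 19L)),
    mu = c(85, 120, 61, 78, 19, 36.9, 97,
           14, 3.1, 10, 23.5, 2, 1.5, 105, 142, 31.5, 10.8, 2.6, 210, 4.1,
           41, 1.5, 16, 138.8, 26, 12),
    sigma = c(18, 21, 14, 15, 5.3, 0.8, 2.9,
              3.9, 0.6, 10, 4.9, 4.5, 1.7, 6.5, 72, 5.5, 1.9, 2.2, 113,
              0.7, 25, 1, 7, 5.2, 22, 11),
    stringsAsFactors = FALSE
  )
}

cohort_variable_table <- function(config) {
  if (config$n_vitals == 7L && config$n_labs == 19L) {
    return(default_variable_panel())
  }
  v <- config$n_vitals
  l <- config$n_labs
  data.frame(
    variable = c(sprintf("vital_%02d", seq_len(v)),
                 sprintf("lab_%02d", seq_len(l))),
    kind = rep(c("vital", "lab"), c(v, l)),
    mu = rep(0, v + l),
    sigma = rep(1, v + l),
    stringsAsFactors = FALSE
  )
}

#' Note categories consumed by the downstream pipeline
#' @keywords internal
note_categories <- function() c("Nursing", "Nursing/Other", "Physician", "Radiology")

# Calibrate the logistic intercept by bisection so that
# mean(plogis(alpha + r)) == target over the realized risk vector.
calibrate_intercept <- function(r, target, tol = 1e-10) {
  stopifnot(target > 0, target < 1)
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mean(stats::plogis(mid + r)) < target) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic multi-modal EHR cohort
#'
#' Draws a cohort of admissions under the latent-risk model described in
#' [cohort_config()]. Every admission carries static fields, timestamped
#' numeric observations within the first 24 h, timestamped notes of the
#' four downstream note categories, three binary outcome labels and a
#' length of stay consistent with the long-length-of-stay label.
#'
#' All randomness is a pure function of `config$seed`, so a fixed
#' configuration reproduces the cohort exactly.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `ehr_cohort`: a list with data frames
#'   `static` (one row per admission, including labels and latent factors
#'   are *not* included), `observations` (long format: admission_id,
#'   variable, hour_offset, value) and `notes` (admission_id, note_id,
#'   category, hour_offset, tokens list-column), plus the `variables`
#'   table and the generating `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("`config` must be a cohort_config")
  n <- config$n_admissions
  vars <- cohort_variable_table(config)
  V <- nrow(vars)
  if (n <= 0) {
    return(empty_cohort(config, vars))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  admission_id <- sprintf("adm%06d", seq_len(n))

  ## ---- static fields -------------------------------------------------
  age <- sample(18:95, n, replace = TRUE)
  gender <- sample(c("F", "M"), n, replace = TRUE)
  marital_status <- sample(c("MARRIED", "SINGLE", "WIDOWED", "DIVORCED"),
                           n, replace = TRUE, prob = c(0.45, 0.3, 0.15, 0.1))
  ethnicity <- sample(c("WHITE", "BLACK", "HISPANIC", "ASIAN", "OTHER"),
                      n, replace = TRUE, prob = c(0.6, 0.15, 0.1, 0.05, 0.1))
  insurance <- sample(c("MEDICARE", "PRIVATE", "MEDICAID", "SELFPAY"),
                      n, replace = TRUE, prob = c(0.45, 0.35, 0.15, 0.05))
  admission_type <- sample(c("EMERGENCY", "ELECTIVE", "URGENT"),
                           n, replace = TRUE, prob = c(0.7, 0.25, 0.05))

  ## ---- latent modality factors --------------------------------------
  g_static_raw <- (age - mean(18:95)) / stats::sd(18:95) +
    0.8 * (admission_type == "EMERGENCY")
  g_static <- as.numeric(scale(g_static_raw))
  if (any(!is.finite(g_static))) g_static <- rep(0, n)  # degenerate n = 1
  g_temporal <- stats::rnorm(n)
  g_note <- stats::rnorm(n)

  risk <- config$static_signal * g_static +
    config$temporal_signal * g_temporal +
    config$note_signal * g_note +
    stats::rnorm(n, sd = 0.5)

  labels <- sapply(config$prevalence, function(p) {
    alpha <- calibrate_intercept(risk, p)
    as.integer(stats::runif(n) < stats::plogis(alpha + risk))
  })
  labels <- matrix(labels, nrow = n,
                   dimnames = list(NULL, names(config$prevalence)))

  ## LOS consistent with the long-LOS label (> 7 days vs [1, 7] days)
  long <- labels[, "long_los"] == 1L
  length_of_stay <- numeric(n)
  length_of_stay[long] <- 7 + stats::rgamma(sum(long), shape = 2, scale = 3.5)
  length_of_stay[!long] <- stats::runif(sum(!long), 1, 7)
  length_of_stay <- round(length_of_stay, 2)

  static <- data.frame(
    admission_id = admission_id, age = age, gender = gender,
    marital_status = marital_status, ethnicity = ethnicity,
    insurance = insurance, admission_type = admission_type,
    length_of_stay = length_of_stay,
    mortality = labels[, "mortality"],
    readmission = labels[, "readmission"],
    long_los = labels[, "long_los"],
    stringsAsFactors = FALSE
  )

  ## ---- temporal observations ----------------------------------------
  # Per-variable loading on the severity factor, fixed for the cohort.
  beta <- stats::runif(V, 0.3, 0.8)
  # observation layout: admissions x 24 hours x variables, Bernoulli cell
  # missingness, observation time uniform inside its hour.
  n_cells <- n * 24L * V
  observed <- stats::runif(n_cells) >= config$missing_rate
  idx <- which(observed)
  adm_i <- ((idx - 1L) %% n) + 1L
  hour_i <- (((idx - 1L) %/% n) %% 24L)
  var_i <- ((idx - 1L) %/% (n * 24L)) + 1L
  offset <- hour_i + stats::runif(length(idx))
  # severity expresses itself partly as a level shift and partly as a
  # within-day trend, so hourly dynamics carry signal that per-variable
  # summary aggregations cannot fully recover
  shape <- 0.5 + 1.5 * (offset - 12) / 6.93
  value <- vars$mu[var_i] + vars$sigma[var_i] *
    (beta[var_i] * g_temporal[adm_i] * shape +
       sqrt(1 - beta[var_i]^2) * stats::rnorm(length(idx)))
  observations <- data.frame(
    admission_id = admission_id[adm_i],
    variable = vars$variable[var_i],
    hour_offset = offset,
    value = round(value, 4),
    stringsAsFactors = FALSE
  )
  # guarantee at least one observation per admission so generated cohorts
  # are eligible for the downstream filters by construction
  missing_adm <- setdiff(admission_id, observations$admission_id)
  if (length(missing_adm)) {
    k <- match(missing_adm, admission_id)
    vsel <- sample.int(V, length(k), replace = TRUE)
    toff <- stats::runif(length(k), 0, 24)
    tshape <- 0.5 + 1.5 * (toff - 12) / 6.93
    extra <- data.frame(
      admission_id = missing_adm,
      variable = vars$variable[vsel],
      hour_offset = toff,
      value = round(vars$mu[vsel] + vars$sigma[vsel] *
                      (beta[vsel] * g_temporal[k] * tshape +
                         sqrt(1 - beta[vsel]^2) * stats::rnorm(length(k))), 4),
      stringsAsFactors = FALSE
    )
    observations <- rbind(observations, extra)
  }
  observations <- observations[order(observations$admission_id,
                                     observations$variable,
                                     observations$hour_offset), ]
  rownames(observations) <- NULL

  ## ---- notes ---------------------------------------------------------
  # Two-topic bag-of-tokens: risk topic = first half of the vocabulary,
  # background = second half; per-admission risk-topic share is a logistic
  # transform of the latent note factor.
  half <- config$vocab_size %/% 2L
  risk_words <- sprintf("w%04d", seq_len(half))
  bg_words <- sprintf("w%04d", (half + 1L):config$vocab_size)
  zipf <- function(k) { p <- 1 / seq_len(k)^0.8; p / sum(p) }
  p_risk_words <- zipf(length(risk_words))
  p_bg_words <- zipf(length(bg_words))
  topic_share <- stats::plogis(1.5 * g_note)

  n_notes <- sample(config$notes_per_admission_range[1]:config$notes_per_admission_range[2],
                    n, replace = TRUE)
  note_adm <- rep(seq_len(n), n_notes)
  total_notes <- length(note_adm)
  cat_pool <- note_categories()
  note_cat <- sample(cat_pool, total_notes, replace = TRUE,
                     prob = c(0.35, 0.3, 0.2, 0.15))
  note_time <- stats::runif(total_notes, 0, 24)
  n_tok <- sample(config$tokens_per_note_range[1]:config$tokens_per_note_range[2],
                  total_notes, replace = TRUE)
  tok_note <- rep(seq_len(total_notes), n_tok)
  from_risk <- stats::runif(length(tok_note)) < topic_share[note_adm[tok_note]]
  tokens_flat <- character(length(tok_note))
  n_r <- sum(from_risk)
  if (n_r) tokens_flat[from_risk] <-
      sample(risk_words, n_r, replace = TRUE, prob = p_risk_words)
  if (n_r < length(tok_note)) tokens_flat[!from_risk] <-
      sample(bg_words, length(tok_note) - n_r, replace = TRUE, prob = p_bg_words)
  tokens <- split(tokens_flat, factor(tok_note, levels = seq_len(total_notes)))
  names(tokens) <- NULL

  notes <- data.frame(
    admission_id = admission_id[note_adm],
    note_id = sprintf("note%07d", seq_len(total_notes)),
    category = note_cat,
    hour_offset = note_time,
    stringsAsFactors = FALSE
  )
  notes$tokens <- tokens
  notes <- notes[order(notes$admission_id, notes$hour_offset, notes$note_id), ]
  rownames(notes) <- NULL

  new_ehr_cohort(static, observations, notes, vars, config)
}

empty_cohort <- function(config = NULL, vars = NULL) {
  if (is.null(vars)) vars <- default_variable_panel()
  static <- data.frame(
    admission_id = character(), age = integer(), gender = character(),
    marital_status = character(), ethnicity = character(),
    insurance = character(), admission_type = character(),
    length_of_stay = numeric(), mortality = integer(),
    readmission = integer(), long_los = integer(), stringsAsFactors = FALSE)
  observations <- data.frame(
    admission_id = character(), variable = character(),
    hour_offset = numeric(), value = numeric(), stringsAsFactors = FALSE)
  notes <- data.frame(
    admission_id = character(), note_id = character(), category = character(),
    hour_offset = numeric(), stringsAsFactors = FALSE)
  notes$tokens <- list()
  new_ehr_cohort(static, observations, notes, vars, config)
}

new_ehr_cohort <- function(static, observations, notes, variables, config = NULL) {
  structure(list(static = static, observations = observations, notes = notes,
                 variables = variables, config = config),
            class = "ehr_cohort")
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d admissions, %d observations, %d notes, %d variables\n",
              nrow(x$static), nrow(x$observations), nrow(x$notes),
              nrow(x$variables)))
  if (nrow(x$static)) {
    prev <- colMeans(x$static[, c("mortality", "readmission", "long_los")])
    cat(sprintf("  prevalence: mortality %.3f, readmission %.3f, long LOS %.3f\n",
                prev[1], prev[2], prev[3]))
  }
  invisible(x)
}

#' Number of admissions in a cohort
#' @param cohort An `ehr_cohort`.
#' @return Integer count.
#' @export
n_admissions <- function(cohort) nrow(cohort$static)

# save/restore the session RNG so generator calls don't disturb caller state
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
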