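# Shared fixtures: small cohorts and handcrafted records built in code.

small_cohort <- function(n = 120, seed = 7, prevalence = c(0.2, 0.2, 0.3),
                         ...) {
  generate_cohort(cohort_config(n_admissions = n, seed = seed,
                                prevalence = prevalence, ...))
}

# A three-admission cohort with fully handcrafted values, exercising
# awkward content (delimiters, quotes, newlines inside tokens).
handmade_cohort <- function() {
  static <- data.frame(
    admission_id = c("a1", "a2", "a3"),
    age = c(40L, 17L, 70L),
    gender = c("F", "M", "F"),
    marital_status = c("SINGLE", "MARRIED", "WIDOWED"),
    ethnicity = c("WHITE", "ASIAN", "OTHER"),
    insurance = c("PRIVATE", "MEDICARE", "MEDICAID"),
    admission_type = c("EMERGENCY", "ELECTIVE", "URGENT"),
    length_of_stay = c(3.25, 5, 0.5),
    mortality = c(0L, 1L, 0L),
    readmission = c(0L, 0L, 1L),
    long_los = c(0L, 1L, 0L),
    stringsAsFactors = FALSE)
  observations <- data.frame(
    admission_id = c("a1", "a1", "a1", "a2", "a3"),
    variable = c("heart_rate", "heart_rate", "lactate", "heart_rate", "wbc"),
    hour_offset = c(3.2, 3.9, 10.5, 25.0, 1.1),
    value = c(80, 90, 2.4, 99, 11.5),
    stringsAsFactors = FALSE)
  notes <- data.frame(
    admission_id = c("a1", "a1", "a2", "a3"),
    note_id = c("n1", "n2", "n3", "n4"),
    category = c("Nursing", "Radiology", "Physician", "Discharge summary"),
    hour_offset = c(1.5, 26.0, 2.0, 3.0),
    stringsAsFactors = FALSE)
  notes$tokens <- list(
    c("pt", "stable", "afebrile"),
    c("chest, x-ray", "clear\nfindings", "\"quoted\""),
    c("icu", "admission"),
    c("ineligible", "category"))
  vars <- ehrfusion:::default_variable_panel()
  ehrfusion:::new_ehr_cohort(static, observations, notes, vars)
}

# Tiny deterministic model-input tensors for architecture tests.
tiny_inputs <- function(n = 8, t_steps = 24, n_vars = 5, L_max = 10,
                        emb_dim = 6, seed = 1) {
  set.seed(seed)
  lens <- sample(0:L_max, n, replace = TRUE)
  notes <- array(0, c(n, L_max, emb_dim))
  for (i in seq_len(n)) {
    if (lens[i] > 0) notes[i, seq_len(lens[i]), ] <- rnorm(lens[i] * emb_dim)
  }
  list(static = matrix(sample(0:1, n * 4, replace = TRUE), n, 4),
       temporal = array(runif(n * t_steps * n_vars), c(n, t_steps, n_vars)),
       notes = notes, note_lens = lens,
       y = sample(0:1, n, replace = TRUE))
}
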