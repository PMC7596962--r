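#' Write a cohort to a directory of plain-text files
#'
#' The on-disk layout follows the data dictionary shipped in
#' `inst/extdata/data_dictionary.json`:
#' * `static.csv` — one row per admission: static fields, length of stay
#'   and the three task labels;
#' * `observations.csv` — long format: `admission_id, variable,
#'   hour_offset, value`;
#' * `notes.jsonl` — one JSON object per line: `admission_id, note_id,
#'   category, hour_offset, tokens`;
#' * `cohort.json` — variable table and (if present) the generating config.
#'
#' Doubles are serialized with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces `x` field for field.
#'
#' @param cohort An `ehr_cohort`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ehr_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fmt_num <- function(x) {
    out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
    out[is.na(x)] <- "NA"
    out
  }
  st <- cohort$static
  st$length_of_stay <- fmt_num(st$length_of_stay)
  utils::write.csv(st, file.path(path, "static.csv"), row.names = FALSE)
  ob <- cohort$observations
  ob$hour_offset <- fmt_num(ob$hour_offset)
  ob$value <- fmt_num(ob$value)
  utils::write.csv(ob, file.path(path, "observations.csv"), row.names = FALSE)

  con <- file(file.path(path, "notes.jsonl"), "w")
  on.exit(close(con), add = TRUE)
  nt <- cohort$notes
  if (nrow(nt)) {
    for (i in seq_len(nrow(nt))) {
      rec <- list(admission_id = nt$admission_id[i], note_id = nt$note_id[i],
                  category = nt$category[i],
                  hour_offset = sprintf("%.17g", nt$hour_offset[i]),
                  tokens = as.list(nt$tokens[[i]]))
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
    }
  }
  meta <- list(variables = cohort$variables,
               n_admissions = nrow(cohort$static))
  if (!is.null(cohort$config)) meta$config <- unclass(cohort$config)
  jsonlite::write_json(meta, file.path(path, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Directory containing `static.csv`, `observations.csv`,
#'   `notes.jsonl` and `cohort.json`.
#' @return An `ehr_cohort`.
#' @export
read_cohort <- function(path) {
  need <- c("static.csv", "observations.csv", "notes.jsonl", "cohort.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing)) {
    stop("not a cohort directory; missing: ", paste(missing, collapse = ", "))
  }
  static <- utils::read.csv(file.path(path, "static.csv"),
                            colClasses = "character")
  static$age <- as.integer(static$age)
  static$length_of_stay <- as.numeric(static$length_of_stay)
  for (col in c("mortality", "readmission", "long_los")) {
    static[[col]] <- as.integer(static[[col]])
  }
  observations <- utils::read.csv(file.path(path, "observations.csv"),
                                  colClasses = "character")
  observations$hour_offset <- as.numeric(observations$hour_offset)
  observations$value <- as.numeric(observations$value)
  lines <- readLines(file.path(path, "notes.jsonl"))
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    parsed <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e) NULL)
      ok <- !is.null(rec) &&
        all(c("admission_id", "note_id", "category", "hour_offset", "tokens")
            %in% names(rec))
      if (!ok) stop(sprintf("notes.jsonl: malformed record at line %d", i))
      rec
    })
    notes <- data.frame(
      admission_id = vapply(parsed, `[[`, character(1), "admission_id"),
      note_id = vapply(parsed, `[[`, character(1), "note_id"),
      category = vapply(parsed, `[[`, character(1), "category"),
      hour_offset = vapply(parsed, function(r) as.numeric(r$hour_offset),
                           numeric(1)),
      stringsAsFactors = FALSE)
    notes$tokens <- lapply(parsed, function(r) as.character(unlist(r$tokens)))
  } else {
    notes <- data.frame(admission_id = character(), note_id = character(),
                        category = character(), hour_offset = numeric(),
                        stringsAsFactors = FALSE)
    notes$tokens <- list()
  }
  meta <- jsonlite::fromJSON(file.path(path, "cohort.json"))
  variables <- as.data.frame(meta$variables, stringsAsFactors = FALSE)
  config <- NULL
  if (!is.null(meta$config)) {
    cf <- meta$config
    prev <- unlist(cf$prevalence)
    config <- cohort_config(
      n_admissions = cf$n_admissions, seed = cf$seed, prevalence = prev,
      static_signal = cf$static_signal, temporal_signal = cf$temporal_signal,
      note_signal = cf$note_signal, missing_rate = cf$missing_rate,
      vocab_size = cf$vocab_size,
      notes_per_admission_range = unlist(cf$notes_per_admission_range),
      tokens_per_note_range = unlist(cf$tokens_per_note_range),
      n_vitals = cf$n_vitals, n_labs = cf$n_labs)
  }
  new_ehr_cohort(static, observations, notes, variables, config)
}
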