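#' Fit all per-run preprocessing artifacts for one data split
#'
#' Runs, in order and with training-split-only fitting wherever a fit is
#' involved: static one-hot layout, static encoding, hourly binning,
#' min-max normalization, baseline aggregations, PV-DBOW training on the
#' training split's notes, and note-embedding sequences for every
#' admission.
#'
#' @param cohort A filtered `ehr_cohort`.
#' @param splits A [split_data()] result.
#' @param doc_params A [doc2vec_params()].
#' @param L_max Maximum notes per admission for the sequence tensor.
#' @return A `run_artifacts` list: `layout`, `static` (matrix),
#'   `norm_stats`, `temporal` (normalized tensor), `agg`, `doc_model`,
#'   `notes` (embedding tensor list) and `splits`.
#' @export
prepare_run_data <- function(cohort, splits, doc_params = doc2vec_params(),
                             L_max = 32L) {
  layout <- static_layout(
    cohort$static[cohort$static$admission_id %in% splits$train, , drop = FALSE])
  static_mat <- encode_static(cohort$static, layout)
  tensor <- bin_temporal(cohort)
  norm_stats <- fit_normalization(tensor, splits$train)
  norm <- apply_normalization(tensor, norm_stats)
  agg <- aggregate_for_baselines(tensor)
  train_notes <- cohort$notes[cohort$notes$admission_id %in% splits$train, ,
                              drop = FALSE]
  tok <- train_notes$tokens
  names(tok) <- train_notes$note_id
  doc_model <- train_doc_embeddings(tok, doc_params)
  notes <- embed_cohort_notes(doc_model, cohort, L_max)
  structure(list(layout = layout, static = static_mat,
                 norm_stats = norm_stats, temporal = norm, agg = agg,
                 doc_model = doc_model, notes = notes, splits = splits,
                 L_max = L_max),
            class = "run_artifacts")
}

#' Assemble fusion-model inputs for a set of admissions
#'
#' @param prep A [prepare_run_data()] result.
#' @param cohort The cohort the artifacts were built from.
#' @param ids Admission ids to include.
#' @param task One of `"mortality"`, `"readmission"`, `"long_los"`.
#' @return List `static`, `temporal`, `notes`, `note_lens`, `y`.
#' @export
model_inputs <- function(prep, cohort, ids, task) {
  stopifnot(task %in% c("mortality", "readmission", "long_los"))
  rows <- match(ids, cohort$static$admission_id)
  if (anyNA(rows)) stop("unknown admission ids")
  list(static = prep$static[ids, , drop = FALSE],
       temporal = prep$temporal$values[ids, , , drop = FALSE],
       notes = prep$notes$embeddings[ids, , , drop = FALSE],
       note_lens = rowSums(prep$notes$mask[ids, , drop = FALSE]),
       y = cohort$static[[task]][rows])
}

#' Default model roster of the benchmark
#'
#' Two baselines and the two fusion networks.
#' @return Named list of model descriptors (`kind` in
#'   `lr`, `rf`, `fusion_cnn`, `fusion_lstm`).
#' @export
default_models <- function() {
  list(lr = list(kind = "lr"),
       rf = list(kind = "rf"),
       fusion_cnn = list(kind = "fusion_cnn"),
       fusion_lstm = list(kind = "fusion_lstm"))
}

modality_label <- function(modalities) {
  paste(intersect(c("U", "T", "S"), modalities), collapse = "+")
}

fit_score_one <- function(model_desc, model_name, modalities, task, prep,
                          cohort, cfg, seed) {
  splits <- prep$splits
  if (model_desc$kind %in% c("lr", "rf")) {
    feats <- build_features(static_mat = prep$static, agg_mat = prep$agg,
                            mean_note_mat = prep$notes$mean_vectors,
                            modalities = modalities,
                            train_ids = splits$train)
    rows <- match(rownames(feats), cohort$static$admission_id)
    labels <- stats::setNames(cohort$static[[task]][rows], rownames(feats))
    res <- train_eval_baseline(substr(model_desc$kind, 1, 2), feats, labels,
                               splits, seed = seed)
    res$metrics
  } else {
    variant <- if (model_desc$kind == "fusion_cnn") "cnn" else "lstm"
    spec_args <- model_desc$spec_args
    if (is.null(spec_args)) spec_args <- list()
    spec <- do.call(fusion_spec, c(list(
      variant = variant, modalities = modalities,
      d_static = ncol(prep$static),
      n_vars = dim(prep$temporal$values)[3],
      emb_dim = dim(prep$notes$embeddings)[3],
      L_max = dim(prep$notes$embeddings)[2]), spec_args))
    cfg$seed <- seed
    fit <- train_model(spec,
                       model_inputs(prep, cohort, splits$train, task),
                       model_inputs(prep, cohort, splits$validation, task),
                       cfg)
    test <- model_inputs(prep, cohort, splits$test, task)
    run_metrics(predict_fusion(fit, test), test$y)
  }
}

#' Run the full multi-run ablation benchmark
#'
#' Implements the evaluation protocol: for each of `n_runs` runs a fresh
#' 70/10/20 split is drawn from a run seed, all preprocessing and the
#' document-embedding model are refit on that run's training split, every
#' (model, modality set) combination is trained per task and scored on
#' the run's test split; metrics are averaged over runs with 95%
#' t-distribution confidence intervals and a pairwise Welch t-test
#' p-value matrix of AUROC per task. Run seeds are drawn deterministically
#' from `master_seed`, so the whole report is reproducible.
#'
#' @param cohort An `ehr_cohort` (filtered internally).
#' @param tasks Character subset of
#'   `c("mortality", "readmission", "long_los")`.
#' @param models Model roster as in [default_models()].
#' @param modality_sets List of modality subsets, e.g.
#'   `list("U", c("T","S"), c("U","T","S"))`.
#' @param n_runs Number of runs with different data splits (default 5).
#' @param master_seed Master seed generating the per-run seeds.
#' @param doc_params A [doc2vec_params()] (its seed is overridden per
#'   run).
#' @param fit_config A [train_config()] for the fusion models (its seed
#'   is overridden per run).
#' @param L_max Maximum notes per admission.
#' @param verbose Print progress.
#' @return An `experiment_report`: `results` (per-run long table),
#'   `summary` (means and CI bounds), `pvalues` (per-task matrices) and
#'   `manifest`.
#' @export
run_experiment <- function(cohort,
                           tasks = c("mortality", "readmission", "long_los"),
                           models = default_models(),
                           modality_sets = list("U", c("T", "S"),
                                                c("U", "T", "S")),
                           n_runs = 5L, master_seed = 1L,
                           doc_params = doc2vec_params(),
                           fit_config = train_config(),
                           L_max = 32L, verbose = FALSE) {
  cohort <- filter_cohort(cohort)
  if (n_admissions(cohort) < 10) stop("cohort too small after filtering")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(master_seed)
  run_seeds <- sample.int(1000000L, n_runs)
  results <- list()
  for (r in seq_len(n_runs)) {
    seed_r <- run_seeds[r]
    splits <- split_data(cohort, seed_r)
    dp <- doc_params; dp$seed <- seed_r
    prep <- prepare_run_data(cohort, splits, dp, L_max)
    for (task in tasks) {
      for (mi in seq_along(models)) {
        for (ms in modality_sets) {
          if (verbose) {
            message(sprintf("run %d | %s | %s | %s", r, task,
                            names(models)[mi], modality_label(ms)))
          }
          met <- fit_score_one(models[[mi]], names(models)[mi], ms, task,
                               prep, cohort, fit_config, seed_r)
          results[[length(results) + 1L]] <- data.frame(
            run = r, task = task, model = names(models)[mi],
            modalities = modality_label(ms),
            f1 = met[["f1"]], auroc = met[["auroc"]],
            auprc = met[["auprc"]], stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, results)
  build_experiment_report(results, n_runs, master_seed, run_seeds)
}

#' Aggregate per-run metrics into an experiment report
#'
#' @param results Long data frame with columns run, task, model,
#'   modalities, f1, auroc, auprc.
#' @param n_runs,master_seed,run_seeds Manifest fields.
#' @param level Confidence level for the t intervals.
#' @return An `experiment_report`.
#' @export
build_experiment_report <- function(results, n_runs, master_seed = NA,
                                    run_seeds = NULL, level = 0.95) {
  key <- interaction(results$task, results$model, results$modalities,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(results, key), function(d) {
    row <- data.frame(task = d$task[1], model = d$model[1],
                      modalities = d$modalities[1], n_runs = nrow(d),
                      stringsAsFactors = FALSE)
    for (m in c("f1", "auroc", "auprc")) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      if (nrow(d) >= 2) {
        ci <- t_confidence_interval(d[[m]], level)
        row[[paste0(m, "_lo")]] <- ci[["lo"]]
        row[[paste0(m, "_hi")]] <- ci[["hi"]]
      } else {
        row[[paste0(m, "_lo")]] <- NA_real_
        row[[paste0(m, "_hi")]] <- NA_real_
      }
    }
    row
  }))
  summ <- summ[order(summ$task, summ$model, summ$modalities), ]
  rownames(summ) <- NULL
  pvals <- if (n_runs < 2) {
    # a single run has no sampling variance to test against
    structure(vector("list", 0), names = character())
  } else lapply(split(results, results$task), function(d) {
    combos <- split(d, interaction(d$model, d$modalities, drop = TRUE))
    vecs <- lapply(combos, function(x) x$auroc[order(x$run)])
    names(vecs) <- vapply(combos, function(x)
      paste(x$model[1], x$modalities[1], sep = " | "), character(1))
    pvalue_matrix(vecs)
  })
  structure(list(results = results, summary = summ, pvalues = pvals,
                 manifest = list(n_runs = n_runs, master_seed = master_seed,
                                 run_seeds = run_seeds,
                                 ci_level = level,
                                 single_run = n_runs < 2)),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d runs, %d model/modality/task combinations\n",
              x$manifest$n_runs, nrow(x$summary)))
  if (isTRUE(x$manifest$single_run)) {
    cat("  note: single run; confidence intervals unavailable\n")
  }
  print(x$summary, digits = 3)
  invisible(x)
}

#' Serialize an experiment report to JSON and delimited tables
#'
#' Writes `report.json` (results, summary, p-value matrices, manifest)
#' plus one `metrics_<task>.tsv` and `pvalues_<task>.tsv` per task. The
#' JSON is byte-stable for identical inputs.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- lapply(report$pvalues, function(m) {
    list(models = rownames(m), p = unname(as.data.frame(m)))
  })
  jsonlite::write_json(
    list(manifest = report$manifest, summary = report$summary,
         results = report$results, pvalues = pv),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  for (task in names(report$pvalues)) {
    s <- report$summary[report$summary$task == task, , drop = FALSE]
    utils::write.table(s, file.path(dir, paste0("metrics_", task, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    m <- report$pvalues[[task]]
    utils::write.table(data.frame(model = rownames(m), m,
                                  check.names = FALSE),
                       file.path(dir, paste0("pvalues_", task, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

# 32-bit FNV-1a hash of a string (config fingerprinting in manifests)
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  sprintf("%08x", content_hash(utf8ToInt(as.character(s))))
}
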