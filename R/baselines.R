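#' Assemble flattened feature vectors for the baseline models
#'
#' Concatenates, per active modality and in fixed order: the static
#' one-hot block (S), the per-variable (mean, min, max, sd, count)
#' aggregations of the raw hourly grid (T), and the element-wise mean
#' note embedding (U). The aggregation block is standardized with a
#' mean/sd scaler fit on the training rows (`train_ids`); the one-hot and
#' embedding blocks are used as-is.
#'
#' @param static_mat Static one-hot matrix (admissions x d_static).
#' @param agg_mat Aggregation matrix from [aggregate_for_baselines()].
#' @param mean_note_mat Mean-note-embedding matrix (admissions x dim).
#' @param modalities Subset of `c("S", "T", "U")`.
#' @param train_ids Admission ids used to fit the scaler (defaults to all
#'   rows).
#' @return Numeric feature matrix with admission-id rownames.
#' @export
build_features <- function(static_mat = NULL, agg_mat = NULL,
                           mean_note_mat = NULL,
                           modalities = c("S", "T", "U"),
                           train_ids = NULL) {
  modalities <- unique(toupper(modalities))
  if (length(modalities) == 0 || !all(modalities %in% c("S", "T", "U"))) {
    stop("`modalities` must be a non-empty subset of S, T, U")
  }
  parts <- list()
  if ("S" %in% modalities) {
    if (is.null(static_mat)) stop("static block missing for modality S")
    parts$S <- static_mat
  }
  if ("T" %in% modalities) {
    if (is.null(agg_mat)) stop("aggregation block missing for modality T")
    rows <- if (is.null(train_ids)) seq_len(nrow(agg_mat))
            else match(train_ids, rownames(agg_mat))
    if (anyNA(rows)) stop("train_ids not present in agg_mat")
    mu <- colMeans(agg_mat[rows, , drop = FALSE])
    sg <- apply(agg_mat[rows, , drop = FALSE], 2, stats::sd)
    sg[sg == 0 | is.na(sg)] <- 1
    parts$T <- sweep(sweep(agg_mat, 2, mu, "-"), 2, sg, "/")
  }
  if ("U" %in% modalities) {
    if (is.null(mean_note_mat)) stop("note block missing for modality U")
    parts$U <- mean_note_mat
  }
  out <- do.call(cbind, parts)
  rn <- rownames(parts[[1]])
  if (!is.null(rn)) rownames(out) <- rn
  out
}

#' Train and evaluate a baseline classifier
#'
#' Logistic regression is an L2-penalized (ridge) fit with penalty
#' `lambda = 1 / n_train` (the unit-inverse-strength convention); the
#' random forest uses 100 trees with a fixed seed and a single thread so
#' repeated fits are identical.
#'
#' @param kind `"lr"` or `"rf"`.
#' @param features Feature matrix with admission-id rownames.
#' @param labels Named (by admission id) or aligned binary label vector.
#' @param splits A [split_data()] list (`train`, `validation`, `test`).
#'   The validation split is unused by the baselines and folded into
#'   nothing; fitting uses `train`, scoring uses `test`.
#' @param seed Seed for the random forest.
#' @param num_trees Random-forest size.
#' @return List with `metrics` (f1/auroc/auprc on the test split),
#'   `scores`, `test_labels` and the fitted model object.
#' @export
train_eval_baseline <- function(kind = c("lr", "rf"), features, labels,
                                splits, seed = 1L, num_trees = 100L) {
  kind <- match.arg(kind)
  if (is.null(rownames(features))) stop("features need admission-id rownames")
  if (!is.null(names(labels))) labels <- labels[rownames(features)]
  if (length(labels) != nrow(features)) stop("labels/features mismatch")
  tr <- match(splits$train, rownames(features))
  te <- match(splits$test, rownames(features))
  if (anyNA(tr) || anyNA(te)) stop("split ids not present in features")
  y_tr <- labels[tr]; y_te <- labels[te]
  if (length(unique(y_tr)) < 2) stop("training labels are single-class")
  if (kind == "lr") {
    fit <- glmnet::glmnet(features[tr, , drop = FALSE], y_tr,
                          family = "binomial", alpha = 0,
                          lambda = 1 / length(tr), standardize = FALSE)
    scores <- as.numeric(stats::predict(fit, features[te, , drop = FALSE],
                                        type = "response"))
  } else {
    fit <- ranger::ranger(x = features[tr, , drop = FALSE],
                          y = factor(y_tr, levels = c(0, 1)),
                          num.trees = num_trees, probability = TRUE,
                          seed = seed, num.threads = 1)
    pred <- stats::predict(fit, features[te, , drop = FALSE],
                           num.threads = 1)
    scores <- pred$predictions[, "1"]
  }
  list(metrics = run_metrics(scores, y_te), scores = scores,
       test_labels = y_te, fit = fit)
}
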