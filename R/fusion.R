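#' Specification of a fusion architecture
#'
#' Describes one of the two multi-modal patient-representation networks:
#' * `variant = "cnn"`: temporal signals through 2 blocks of
#'   (1-D convolution over time, ReLU, width-2 max-pooling) then flatten;
#'   note-embedding sequences through 2 (convolution, ReLU) blocks with an
#'   intermediate width-2 max-pooling and a final masked global
#'   max-pooling over time.
#' * `variant = "lstm"`: temporal signals through a 2-layer LSTM (dropout
#'   on the non-recurrent connections between layers and before the
#'   output) taking the last hidden state; note sequences through a
#'   bidirectional LSTM whose per-step forward/backward outputs are
#'   concatenated and max-pooled over the valid (unpadded) steps.
#'
#' Static features bypass encoding (they are already one-hot). The patient
#' representation is the concatenation `[z_static; z_temporal; z_text]`
#' restricted to the active modalities, in that fixed order, feeding a
#' single sigmoid output unit.
#'
#' @param variant `"cnn"` or `"lstm"`.
#' @param modalities Subset of `c("S", "T", "U")`: static, temporal
#'   signals, unstructured notes.
#' @param d_static Width of the static one-hot block (required if `"S"`
#'   is active).
#' @param n_vars Number of temporal variables (columns of the hourly
#'   grid).
#' @param t_steps Number of hourly steps (24).
#' @param emb_dim Note embedding dimension.
#' @param L_max Maximum notes per admission.
#' @param temporal_channels,note_channels Convolution channels (CNN
#'   variant).
#' @param kernel Convolution kernel width.
#' @param temporal_hidden LSTM hidden size for the temporal path.
#' @param note_hidden BiLSTM hidden size per direction for the note path.
#' @param dropout Dropout rate on the temporal LSTM's non-recurrent
#'   connections.
#' @param note_dropout Dropout rate on the note encoder's embedding input
#'   and pooled output (defaults to `dropout`); the embedding path is the
#'   dominant source of overfitting on small cohorts.
#' @return A `fusion_spec` object; `d_temporal`, `d_text` and the total
#'   representation width `d_p` are derived fields.
#' @export
fusion_spec <- function(variant = c("cnn", "lstm"),
                        modalities = c("S", "T", "U"),
                        d_static = NULL,
                        n_vars = 26L, t_steps = 24L,
                        emb_dim = 200L, L_max = 32L,
                        temporal_channels = 64L, kernel = 3L,
                        temporal_hidden = 128L,
                        note_channels = 128L, note_hidden = 128L,
                        dropout = 0.2, note_dropout = dropout) {
  variant <- match.arg(variant)
  modalities <- unique(toupper(modalities))
  if (length(modalities) == 0 || !all(modalities %in% c("S", "T", "U"))) {
    stop("`modalities` must be a non-empty subset of S, T, U")
  }
  if ("S" %in% modalities && is.null(d_static)) {
    stop("`d_static` is required when the static modality is active")
  }
  d_temporal <- 0L
  if ("T" %in% modalities) {
    if (variant == "cnn") {
      t1 <- t_steps - kernel + 1L; p1 <- t1 %/% 2L
      t2 <- p1 - kernel + 1L; p2 <- t2 %/% 2L
      if (p2 < 1L) stop("temporal CNN collapses the sequence; reduce kernel")
      d_temporal <- p2 * temporal_channels
    } else {
      d_temporal <- temporal_hidden
    }
  }
  d_text <- 0L
  if ("U" %in% modalities) {
    if (variant == "cnn" && ((L_max - kernel + 1L) %/% 2L) < kernel) {
      stop("note CNN needs L_max >= 3*kernel - 1; increase L_max or shrink kernel")
    }
    d_text <- if (variant == "cnn") note_channels else 2L * note_hidden
  }
  d_s <- if ("S" %in% modalities) as.integer(d_static) else 0L
  structure(list(variant = variant, modalities = modalities,
                 d_static = d_s, n_vars = as.integer(n_vars),
                 t_steps = as.integer(t_steps), emb_dim = as.integer(emb_dim),
                 L_max = as.integer(L_max),
                 temporal_channels = as.integer(temporal_channels),
                 kernel = as.integer(kernel),
                 temporal_hidden = as.integer(temporal_hidden),
                 note_channels = as.integer(note_channels),
                 note_hidden = as.integer(note_hidden),
                 dropout = dropout, note_dropout = note_dropout,
                 d_temporal = as.integer(d_temporal),
                 d_text = as.integer(d_text),
                 d_p = as.integer(d_s + d_temporal + d_text)),
            class = "fusion_spec")
}

#' Initialize a fusion model's parameters
#'
#' @param spec A [fusion_spec()].
#' @param seed Integer seed for the (uniform fan-in) initialization.
#' @return A `fusion_model`: list of `spec` and `params`.
#' @export
init_fusion_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fusion_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p <- list()
  if ("T" %in% spec$modalities) {
    if (spec$variant == "cnn") {
      p$tconv1 <- conv1d_init(spec$n_vars, spec$temporal_channels, spec$kernel)
      p$tconv2 <- conv1d_init(spec$temporal_channels, spec$temporal_channels,
                              spec$kernel)
    } else {
      p$tlstm1 <- lstm_init(spec$n_vars, spec$temporal_hidden)
      p$tlstm2 <- lstm_init(spec$temporal_hidden, spec$temporal_hidden)
    }
  }
  if ("U" %in% spec$modalities) {
    if (spec$variant == "cnn") {
      p$nconv1 <- conv1d_init(spec$emb_dim, spec$note_channels, spec$kernel)
      p$nconv2 <- conv1d_init(spec$note_channels, spec$note_channels,
                              spec$kernel)
    } else {
      p$nlstm_f <- lstm_init(spec$emb_dim, spec$note_hidden)
      p$nlstm_b <- lstm_init(spec$emb_dim, spec$note_hidden)
    }
  }
  p$head <- linear_init(spec$d_p, 1L)
  structure(list(spec = spec, params = p), class = "fusion_model")
}

## ---- encoders ----------------------------------------------------------

encode_temporal_forward <- function(spec, p, x, training) {
  if (spec$variant == "cnn") {
    c1 <- conv1d_forward(x, p$tconv1); r1 <- relu_forward(c1$out)
    p1 <- pool2_forward(r1$out)
    c2 <- conv1d_forward(p1$out, p$tconv2); r2 <- relu_forward(c2$out)
    p2 <- pool2_forward(r2$out)
    d <- dim(p2$out)
    z <- matrix(p2$out, d[1], d[2] * d[3])
    dr <- dropout_forward(z, spec$dropout, training)
    list(z = dr$out, cache = list(c1 = c1, r1 = r1, p1 = p1, c2 = c2,
                                  r2 = r2, p2 = p2, zdim = d, dr = dr))
  } else {
    l1 <- lstm_forward(x, p$tlstm1)
    dr <- dropout_forward(l1$out, spec$dropout, training)
    l2 <- lstm_forward(dr$out, p$tlstm2)
    h_last <- matrix(l2$out[, spec$t_steps, ], dim(x)[1], spec$temporal_hidden)
    dr2 <- dropout_forward(h_last, spec$dropout, training)
    list(z = dr2$out, cache = list(l1 = l1, dr = dr, l2 = l2, dr2 = dr2))
  }
}

encode_temporal_backward <- function(spec, p, cache, dz) {
  if (spec$variant == "cnn") {
    d <- cache$zdim
    g <- array(dropout_backward(dz, cache$dr), d)
    g <- pool2_backward(g, cache$p2)
    g <- relu_backward(g, cache$r2)
    b2 <- conv1d_backward(g, cache$c2, p$tconv2)
    g <- pool2_backward(b2$dx, cache$p1)
    g <- relu_backward(g, cache$r1)
    b1 <- conv1d_backward(g, cache$c1, p$tconv1)
    list(grads = list(tconv1 = list(W = b1$dW, b = b1$db),
                      tconv2 = list(W = b2$dW, b = b2$db)))
  } else {
    g <- dropout_backward(dz, cache$dr2)
    dH2 <- array(0, dim(cache$l2$out))
    dH2[, spec$t_steps, ] <- g
    b2 <- lstm_backward(dH2, cache$l2, p$tlstm2)
    g1 <- dropout_backward(b2$dx, cache$dr)
    b1 <- lstm_backward(g1, cache$l1, p$tlstm1)
    list(grads = list(tlstm1 = list(Wx = b1$dWx, Wh = b1$dWh, b = b1$db),
                      tlstm2 = list(Wx = b2$dWx, Wh = b2$dWh, b = b2$db)))
  }
}

# validity bookkeeping for the note CNN: an output position is valid when
# its receptive field touches at least one real note, so the final masked
# pooling never sees features computed purely from padding.
# Dropout is applied on the note path's non-recurrent connections: on the
# embedding inputs and on the pooled output, for both variants (the
# embedding inputs are the dominant source of memorization at small n).
encode_notes_forward <- function(spec, p, x, lens, training) {
  din <- dropout_forward(x, spec$note_dropout, training)
  x <- din$out
  if (spec$variant == "cnn") {
    c1 <- conv1d_forward(x, p$nconv1); r1 <- relu_forward(c1$out)
    t1 <- dim(c1$out)[2]
    len1 <- pmin(lens, t1)
    pl <- pool2_forward(r1$out)
    len2 <- pmin(ceiling(len1 / 2), dim(pl$out)[2])
    c2 <- conv1d_forward(pl$out, p$nconv2); r2 <- relu_forward(c2$out)
    len3 <- pmin(len2, dim(c2$out)[2])
    len3[lens == 0] <- 0
    mp <- masked_maxpool_forward(r2$out, len3)
    dout <- dropout_forward(mp$out, spec$note_dropout, training)
    list(z = dout$out, cache = list(c1 = c1, r1 = r1, pl = pl, c2 = c2,
                                    r2 = r2, mp = mp, din = din,
                                    dout = dout))
  } else {
    lf <- lstm_forward(x, p$nlstm_f)
    x_rev <- reverse_within_mask(x, lens)
    lb <- lstm_forward(x_rev, p$nlstm_b)
    hb <- reverse_within_mask(lb$out, lens)
    d <- dim(lf$out)
    hcat <- array(0, c(d[1], d[2], 2L * d[3]))
    hcat[, , 1:d[3]] <- lf$out
    hcat[, , (d[3] + 1L):(2L * d[3])] <- hb
    mp <- masked_maxpool_forward(hcat, lens)
    dout <- dropout_forward(mp$out, spec$note_dropout, training)
    list(z = dout$out, cache = list(lf = lf, lb = lb, mp = mp, lens = lens,
                                    h = d[3], din = din, dout = dout))
  }
}

encode_notes_backward <- function(spec, p, cache, dz) {
  dz <- dropout_backward(dz, cache$dout)
  if (spec$variant == "cnn") {
    g <- masked_maxpool_backward(dz, cache$mp)
    g <- relu_backward(g, cache$r2)
    b2 <- conv1d_backward(g, cache$c2, p$nconv2)
    g <- pool2_backward(b2$dx, cache$pl)
    g <- relu_backward(g, cache$r1)
    b1 <- conv1d_backward(g, cache$c1, p$nconv1)
    list(grads = list(nconv1 = list(W = b1$dW, b = b1$db),
                      nconv2 = list(W = b2$dW, b = b2$db)))
  } else {
    g <- masked_maxpool_backward(dz, cache$mp)
    H <- cache$h
    df <- g[, , 1:H, drop = FALSE]
    db_ <- g[, , (H + 1L):(2L * H), drop = FALSE]
    bf <- lstm_backward(df, cache$lf, p$nlstm_f)
    db_rev <- reverse_within_mask(db_, cache$lens)
    bb <- lstm_backward(db_rev, cache$lb, p$nlstm_b)
    list(grads = list(nlstm_f = list(Wx = bf$dWx, Wh = bf$dWh, b = bf$db),
                      nlstm_b = list(Wx = bb$dWx, Wh = bb$dWh, b = bb$db)))
  }
}

#' Forward pass of a fusion model
#'
#' @param model A `fusion_model`.
#' @param batch List with the active-modality inputs: `static`
#'   (batch x d_static), `temporal` (batch x 24 x V), `notes`
#'   (batch x L_max x dim) and `note_lens` (valid-note counts).
#' @param training Logical; enables dropout.
#' @return List with `prob` (sigmoid outputs), `z_p` (patient
#'   representations) and the backward cache.
#' @export
fusion_forward <- function(model, batch, training = FALSE) {
  spec <- model$spec; p <- model$params
  parts <- list(); caches <- list()
  if ("S" %in% spec$modalities) parts$static <- batch$static
  if ("T" %in% spec$modalities) {
    enc <- encode_temporal_forward(spec, p, batch$temporal, training)
    parts$temporal <- enc$z; caches$temporal <- enc$cache
  }
  if ("U" %in% spec$modalities) {
    enc <- encode_notes_forward(spec, p, batch$notes, batch$note_lens,
                                training)
    parts$text <- enc$z; caches$text <- enc$cache
  }
  z_p <- do.call(cbind, parts)
  head <- linear_forward(z_p, p$head)
  prob <- sigm(head$out)
  list(prob = as.numeric(prob), z_p = z_p,
       cache = list(parts = lapply(parts, ncol), caches = caches,
                    head = head))
}

fusion_backward <- function(model, fwd, dlogit) {
  spec <- model$spec; p <- model$params
  hb <- linear_backward(matrix(dlogit, ncol = 1), fwd$cache$head, p$head)
  grads <- list(head = list(W = hb$dW, b = hb$db))
  dz <- hb$dx
  off <- 0L
  widths <- fwd$cache$parts
  if ("S" %in% spec$modalities) off <- off + widths$static
  if ("T" %in% spec$modalities) {
    dzt <- dz[, (off + 1L):(off + widths$temporal), drop = FALSE]
    off <- off + widths$temporal
    tb <- encode_temporal_backward(spec, p, fwd$cache$caches$temporal, dzt)
    grads <- grad_add(grads, tb$grads)
  }
  if ("U" %in% spec$modalities) {
    dzu <- dz[, (off + 1L):(off + widths$text), drop = FALSE]
    ub <- encode_notes_backward(spec, p, fwd$cache$caches$text, dzu)
    grads <- grad_add(grads, ub$grads)
  }
  grads
}

#' Sigmoid output layer
#'
#' Computes `o = sigmoid(W z_p + b)` for a patient representation (or a
#' matrix of them, one per row).
#'
#' @param z_p Numeric vector or matrix of patient representations.
#' @param W Weight vector conformable with `z_p`.
#' @param b Scalar bias.
#' @return Probabilities in (0, 1).
#' @export
predict_output <- function(z_p, W, b) {
  z_p <- if (is.matrix(z_p)) z_p else matrix(z_p, nrow = 1)
  W <- as.numeric(W)
  if (ncol(z_p) != length(W)) stop("dimension mismatch between z_p and W")
  as.numeric(sigm(z_p %*% W + b))
}

#' Binary cross-entropy loss
#'
#' `L = -(y log o + (1 - y) log(1 - o))`, averaged over the batch.
#' Probabilities are clamped to `[eps, 1 - eps]` before taking logs.
#'
#' @param o Predicted probabilities.
#' @param y Binary labels.
#' @param eps Clamping constant (default 1e-12).
#' @return Mean loss (non-negative scalar).
#' @export
bce_loss <- function(o, y, eps = 1e-12) {
  if (length(o) != length(y)) stop("o and y must have the same length")
  if (!all(y %in% c(0, 1))) stop("labels must be binary")
  o <- pmin(pmax(o, eps), 1 - eps)
  -mean(y * log(o) + (1 - y) * log(1 - o))
}

#' Concatenate modality representations into a patient representation
#'
#' @param z_static,z_temporal,z_text Component vectors/matrices (only
#'   those for active modalities are consulted).
#' @param modalities Active modality set, subset of `c("S","T","U")`.
#' @return The concatenation in fixed order static, temporal, text.
#' @export
fuse_representation <- function(z_static = NULL, z_temporal = NULL,
                                z_text = NULL,
                                modalities = c("S", "T", "U")) {
  modalities <- unique(toupper(modalities))
  if (length(modalities) == 0) stop("`modalities` must be non-empty")
  parts <- list()
  if ("S" %in% modalities) {
    if (is.null(z_static)) stop("static modality active but z_static missing")
    parts$static <- z_static
  }
  if ("T" %in% modalities) {
    if (is.null(z_temporal)) stop("temporal modality active but z_temporal missing")
    parts$temporal <- z_temporal
  }
  if ("U" %in% modalities) {
    if (is.null(z_text)) stop("text modality active but z_text missing")
    parts$text <- z_text
  }
  if (all(vapply(parts, is.matrix, logical(1)))) do.call(cbind, parts)
  else do.call(c, lapply(parts, as.numeric))
}

#' Training configuration for the fusion models
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size Mini-batch size (default 64).
#' @param max_epochs Epoch cap (default 50).
#' @param patience Early-stopping patience on validation AUROC (default
#'   5 epochs); the returned model is the checkpoint with the best
#'   validation AUROC.
#' @param seed Seed for initialization, shuffling and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 64L,
                         max_epochs = 50L, patience = 5L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

slice_batch <- function(data, idx, modalities) {
  b <- list()
  if ("S" %in% modalities) b$static <- data$static[idx, , drop = FALSE]
  if ("T" %in% modalities) {
    b$temporal <- data$temporal[idx, , , drop = FALSE]
  }
  if ("U" %in% modalities) {
    b$notes <- data$notes[idx, , , drop = FALSE]
    b$note_lens <- data$note_lens[idx]
  }
  b
}

#' Train a fusion model with Adam and early stopping
#'
#' Minimizes the mean binary cross-entropy by mini-batch Adam. After each
#' epoch the model is scored on the validation set by AUROC; training
#' stops when the cap is reached or the validation AUROC has not improved
#' for `patience` epochs, and the best-validation checkpoint is returned.
#' Fixed seeds give an identical epoch-by-epoch training log.
#'
#' @param spec A [fusion_spec()].
#' @param train_data,val_data Model-input lists as produced by
#'   [prepare_model_inputs()]: elements `static`, `temporal`, `notes`,
#'   `note_lens`, `y`.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `fusion_fit`: the trained `fusion_model`, the training `log`
#'   (epoch, train_loss, val_auroc) and the selected epoch.
#' @export
train_model <- function(spec, train_data, val_data, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(spec, "fusion_spec"), inherits(config, "train_config"))
  n <- length(train_data$y)
  if (n == 0) stop("empty training set")
  model <- init_fusion_model(spec, seed = config$seed)
  state <- adam_init(model$params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  best_auc <- -Inf; best_params <- model$params; best_epoch <- 0L
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_auroc = numeric())
  stall <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n)
    losses <- numeric()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      batch <- slice_batch(train_data, idx, spec$modalities)
      y <- train_data$y[idx]
      fwd <- fusion_forward(model, batch, training = TRUE)
      losses <- c(losses, bce_loss(fwd$prob, y))
      dlogit <- (fwd$prob - y) / length(y)
      grads <- fusion_backward(model, fwd, dlogit)
      upd <- adam_step(model$params, grads, state, config$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    val_prob <- predict_fusion(model, val_data)
    val_auc <- if (length(unique(val_data$y)) > 1) {
      auroc(val_prob, val_data$y)
    } else NA_real_
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(losses),
                                 val_auroc = val_auc))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f  val AUROC %s", epoch,
                      mean(losses), format(val_auc, digits = 4)))
    }
    if (!is.na(val_auc) && val_auc > best_auc) {
      best_auc <- val_auc; best_params <- model$params
      best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  model$params <- best_params
  structure(list(model = model, log = log, best_epoch = best_epoch,
                 best_val_auroc = best_auc, config = config),
            class = "fusion_fit")
}

#' Predict outcome probabilities with a fusion model
#'
#' @param model A `fusion_model` or `fusion_fit`.
#' @param data Model-input list (as for [train_model()]).
#' @param batch_size Evaluation batch size.
#' @return Numeric vector of probabilities.
#' @export
predict_fusion <- function(model, data, batch_size = 256L) {
  if (inherits(model, "fusion_fit")) model <- model$model
  n <- if (!is.null(data$y)) length(data$y) else {
    if (!is.null(data$static)) nrow(data$static)
    else if (!is.null(data$temporal)) dim(data$temporal)[1]
    else dim(data$notes)[1]
  }
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    batch <- slice_batch(data, idx, model$spec$modalities)
    out[idx] <- fusion_forward(model, batch, training = FALSE)$prob
  }
  out
}
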