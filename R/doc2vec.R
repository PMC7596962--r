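#' Tokenize clinical note text
#'
#' Lowercases the input and extracts maximal runs of ASCII alphanumeric
#' characters. Accepts either a single string or an already-split token
#' vector (each element is re-tokenized), so the operation is idempotent:
#' `tokenize(tokenize(x))` equals `tokenize(x)`.
#'
#' @param x Character scalar or vector.
#' @return Character vector of lowercase alphanumeric tokens (possibly
#'   empty).
#' @export
tokenize <- function(x) {
  if (is.null(x)) stop("tokenize: input must not be NULL")
  if (length(x) == 0) return(character())
  x <- tolower(paste(x, collapse = " "))
  m <- gregexpr("[a-z0-9]+", x)[[1]]
  if (m[1] == -1) return(character())
  regmatches(x, list(m))[[1]]
}

#' Hyperparameters for PV-DBOW document embeddings
#'
#' Defaults follow the standard paragraph-vector setup for clinical notes:
#' 200-dimensional vectors, 30 training epochs, initial learning rate
#' 0.025 decreased by 0.0002 per epoch, negative sampling with 5 noise
#' words drawn from the unigram distribution raised to 0.75.
#'
#' @param dim Embedding dimension.
#' @param epochs Number of passes over the corpus.
#' @param initial_lr Starting learning rate.
#' @param lr_decay Per-epoch learning-rate decrement.
#' @param min_lr Learning-rate floor.
#' @param negative Number of negative samples per target token.
#' @param min_token_count Minimum corpus frequency for a token to enter
#'   the vocabulary.
#' @param seed Integer seed for the (single-threaded, deterministic)
#'   trainer.
#' @return A `doc2vec_params` list.
#' @export
doc2vec_params <- function(dim = 200L, epochs = 30L, initial_lr = 0.025,
                           lr_decay = 0.0002, min_lr = 1e-4, negative = 5L,
                           min_token_count = 2L, seed = 1L) {
  stopifnot(dim > 0, epochs > 0, initial_lr > 0, lr_decay >= 0,
            negative >= 1, min_token_count >= 1)
  structure(list(dim = as.integer(dim), epochs = as.integer(epochs),
                 initial_lr = initial_lr, lr_decay = lr_decay,
                 min_lr = min_lr, negative = as.integer(negative),
                 min_token_count = as.integer(min_token_count),
                 seed = as.integer(seed)),
            class = "doc2vec_params")
}

#' Train PV-DBOW document embeddings on a note corpus
#'
#' Implements the Distributed Bag of Words flavour of paragraph vectors:
#' each document vector is trained to predict the tokens it contains via
#' negative sampling, with no word-order information. Training is
#' single-threaded and fully deterministic given `params$seed`.
#'
#' Train only on the training split's notes; embeddings for notes unseen
#' at training time are obtained by inference (gradient steps on a fresh
#' document vector against the frozen token matrix).
#'
#' @param notes_tokens Named list of character token vectors, one entry
#'   per note; names are note ids.
#' @param params A [doc2vec_params()].
#' @return A `pvdbow_model` with the learned document vectors (rows named
#'   by note id), the token output matrix, the vocabulary and `params`.
#' @export
train_doc_embeddings <- function(notes_tokens, params = doc2vec_params()) {
  stopifnot(inherits(params, "doc2vec_params"))
  if (length(notes_tokens) == 0 || all(lengths(notes_tokens) == 0)) {
    stop("empty corpus: need at least one non-empty note")
  }
  notes_tokens <- lapply(notes_tokens, tokenize)
  tab <- table(unlist(notes_tokens, use.names = FALSE))
  keep <- tab[tab >= params$min_token_count]
  # deterministic vocabulary order: frequency desc, token asc
  vocab <- names(keep)[order(-as.integer(keep), names(keep))]
  if (length(vocab) == 0) {
    stop("empty vocabulary after applying min_token_count; lower the threshold")
  }
  counts <- as.numeric(tab[vocab])
  docs <- lapply(notes_tokens, function(t) {
    ids <- match(t, vocab)
    as.integer(ids[!is.na(ids)] - 1L)
  })
  fit <- cpp_pvdbow_train(docs, counts, params$dim, params$epochs,
                          params$initial_lr, params$lr_decay, params$min_lr,
                          params$negative, 0.75, as.double(params$seed))
  doc_vecs <- t(fit$doc)
  rownames(doc_vecs) <- names(notes_tokens)
  structure(list(doc_vecs = doc_vecs, word_mat = fit$word, vocab = vocab,
                 counts = counts, params = params),
            class = "pvdbow_model")
}

#' @export
print.pvdbow_model <- function(x, ...) {
  cat(sprintf("<pvdbow_model> dim %d, vocab %d, %d training documents\n",
              x$params$dim, length(x$vocab), nrow(x$doc_vecs)))
  invisible(x)
}

# Deterministic 31-bit polynomial hash of an integer vector; seeds the
# per-document inference RNG so inference is a pure function of content.
# (Horner scheme mod a Mersenne prime keeps everything exact in doubles.)
content_hash <- function(ints) {
  h <- 17
  for (b in ints) h <- (h * 131 + (b %% 65536) + 1) %% 2147483647
  h
}

#' Embed one note with a trained PV-DBOW model
#'
#' Training-split notes (present in the model by id) return their learned
#' vector; any other note is embedded by inference. Notes with no
#' in-vocabulary tokens embed to the zero vector.
#'
#' @param model A `pvdbow_model`.
#' @param tokens Character token vector (or raw text; it is tokenized).
#' @param note_id Optional note id used to look up a learned training
#'   vector.
#' @return Numeric vector of length `model$params$dim`.
#' @export
infer_docvec <- function(model, tokens, note_id = NULL) {
  stopifnot(inherits(model, "pvdbow_model"))
  if (!is.null(note_id) && note_id %in% rownames(model$doc_vecs)) {
    return(as.numeric(model$doc_vecs[note_id, ]))
  }
  ids <- match(tokenize(tokens), model$vocab)
  ids <- as.integer(ids[!is.na(ids)] - 1L)
  if (length(ids) == 0) return(numeric(model$params$dim))
  p <- model$params
  as.numeric(cpp_pvdbow_infer(ids, model$word_mat, model$counts, p$epochs,
                              p$initial_lr, p$lr_decay, p$min_lr, p$negative,
                              0.75, content_hash(ids) + 1))
}

# Notes of an admission that feed the model: one of the four downstream
# categories, recorded inside the first 24 h, in time order (ties broken
# by note id for determinism).
eligible_notes <- function(notes_df) {
  keep <- notes_df$category %in% note_categories() &
    notes_df$hour_offset >= 0 & notes_df$hour_offset < 24
  nd <- notes_df[keep, , drop = FALSE]
  nd[order(nd$hour_offset, nd$note_id), , drop = FALSE]
}

#' Padded embedding sequence for one admission
#'
#' Filters the admission's notes to the four modeled categories within
#' the first 24 h, sorts them by time, embeds each note by inference
#' against the trained token matrix (so training-split and held-out notes
#' share one embedding distribution), truncates to the first `L_max`
#' notes and zero-pads the rest. The mask is a prefix: all real notes
#' precede all padding rows.
#'
#' @param model A `pvdbow_model`.
#' @param notes_df Rows of a cohort `notes` table for one admission.
#' @param L_max Maximum number of notes retained per admission.
#' @return List with `embeddings` (`L_max` x dim matrix, padded rows all
#'   zero), `mask` (length `L_max` 0/1 prefix vector) and `n_notes`.
#' @export
embed_admission <- function(model, notes_df, L_max = 32L) {
  nd <- eligible_notes(notes_df)
  k <- as.integer(min(nrow(nd), L_max))
  emb <- matrix(0, L_max, model$params$dim)
  if (k > 0) {
    for (i in seq_len(k)) {
      emb[i, ] <- infer_docvec(model, nd$tokens[[i]])
    }
  }
  list(embeddings = emb, mask = c(rep(1L, k), rep(0L, L_max - k)),
       n_notes = k)
}

#' Mean document vector across an admission's eligible notes
#'
#' Element-wise mean of the embeddings of all eligible notes (no `L_max`
#' truncation); the zero vector when the admission has none.
#'
#' @inheritParams embed_admission
#' @return Numeric vector of length `model$params$dim`.
#' @export
mean_note_vector <- function(model, notes_df) {
  nd <- eligible_notes(notes_df)
  if (nrow(nd) == 0) return(numeric(model$params$dim))
  embs <- vapply(seq_len(nrow(nd)),
                 function(i) infer_docvec(model, nd$tokens[[i]]),
                 numeric(model$params$dim))
  rowMeans(matrix(embs, nrow = model$params$dim))
}

#' Embed every admission of a cohort into a padded sequence tensor
#'
#' @param model A `pvdbow_model`.
#' @param cohort An `ehr_cohort`.
#' @param L_max Maximum notes per admission.
#' @return List with `embeddings` (admissions x L_max x dim array),
#'   `mask` (admissions x L_max), and `mean_vectors` (admissions x dim,
#'   the baseline representation), rows named by admission id.
#' @export
embed_cohort_notes <- function(model, cohort, L_max = 32L) {
  ids <- cohort$static$admission_id
  d <- model$params$dim
  emb <- array(0, c(length(ids), L_max, d), dimnames = list(ids, NULL, NULL))
  mask <- matrix(0L, length(ids), L_max, dimnames = list(ids, NULL))
  mean_vec <- matrix(0, length(ids), d, dimnames = list(ids, NULL))
  notes_by_adm <- split(seq_len(nrow(cohort$notes)), cohort$notes$admission_id)
  for (i in seq_along(ids)) {
    rows <- notes_by_adm[[ids[i]]]
    if (is.null(rows)) next
    nd <- eligible_notes(cohort$notes[rows, , drop = FALSE])
    if (nrow(nd) == 0) next
    vecs <- vapply(seq_len(nrow(nd)),
                   function(j) infer_docvec(model, nd$tokens[[j]]),
                   numeric(d))
    vecs <- t(matrix(vecs, nrow = d))
    mean_vec[i, ] <- colMeans(vecs)
    k <- min(nrow(vecs), L_max)
    emb[i, seq_len(k), ] <- vecs[seq_len(k), , drop = FALSE]
    mask[i, seq_len(k)] <- 1L
  }
  list(embeddings = emb, mask = mask, mean_vectors = mean_vec)
}
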