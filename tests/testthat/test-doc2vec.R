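# Tokenization rules, PV-DBOW training contracts, admission embedding.

test_that("tokenize lowercases, strips punctuation and is idempotent", {
  expect_identical(tokenize("Pt stable, afebrile."),
                   c("pt", "stable", "afebrile"))
  expect_identical(tokenize(""), character())
  expect_identical(tokenize("  \n\t "), character())
  expect_error(tokenize(NULL), "NULL")
  set.seed(11)
  for (i in 1:100) {
    x <- paste(sample(c("Ab1", "x-y", "NA?", "q9", ",", "Zz"),
                      sample(1:12, 1), replace = TRUE), collapse = " ")
    once <- tokenize(x)
    expect_identical(tokenize(paste(once, collapse = " ")), once)
  }
})

make_topic_corpus <- function(n_per_topic = 30, seed = 1) {
  set.seed(seed)
  wa <- sprintf("alpha%02d", 1:40)
  wb <- sprintf("beta%02d", 1:40)
  docs <- c(lapply(seq_len(n_per_topic),
                   function(i) sample(wa, 25, replace = TRUE)),
            lapply(seq_len(n_per_topic),
                   function(i) sample(wb, 25, replace = TRUE)))
  names(docs) <- sprintf("doc%03d", seq_along(docs))
  docs
}

test_that("every embedding has the configured dimension and training is
           deterministic", {
  docs <- make_topic_corpus()
  params <- doc2vec_params(dim = 200, epochs = 5, seed = 9)
  m1 <- train_doc_embeddings(docs, params)
  m2 <- train_doc_embeddings(docs, params)
  expect_identical(ncol(m1$doc_vecs), 200L)
  expect_identical(m1$doc_vecs, m2$doc_vecs)
  expect_identical(m1$word_mat, m2$word_mat)
  v <- infer_docvec(m1, c("alpha01", "alpha02"))
  expect_length(v, 200)
  expect_identical(v, infer_docvec(m1, c("alpha01", "alpha02")))
  expect_error(train_doc_embeddings(list(a = character())), "empty corpus")
})

test_that("disjoint-topic documents are closer within topics than between", {
  docs <- make_topic_corpus(n_per_topic = 30, seed = 2)
  m <- train_doc_embeddings(docs, doc2vec_params(dim = 50, epochs = 30,
                                                 seed = 1))
  D <- m$doc_vecs / sqrt(rowSums(m$doc_vecs^2))
  S <- D %*% t(D)
  grp <- rep(1:2, each = 30)
  same <- outer(grp, grp, "==") & row(S) != col(S)
  within <- mean(S[same])
  between <- mean(S[outer(grp, grp, "!=")])
  expect_gt(within, between)
})

test_that("the embedding model never sees held-out notes", {
  docs <- make_topic_corpus(seed = 3)
  train_docs <- docs[1:40]
  m1 <- train_doc_embeddings(train_docs, doc2vec_params(dim = 20, epochs = 5,
                                                        seed = 4))
  # perturbing notes outside the training corpus changes nothing
  m2 <- train_doc_embeddings(train_docs, doc2vec_params(dim = 20, epochs = 5,
                                                        seed = 4))
  expect_identical(m1$word_mat, m2$word_mat)
  # an unseen note is embedded by inference, not lookup
  unseen <- docs[[50]]
  v <- infer_docvec(m1, unseen, note_id = "not-in-model")
  expect_length(v, 20)
  # out-of-vocabulary-only notes embed to the zero vector
  expect_identical(infer_docvec(m1, c("zzz", "qqq")), numeric(20))
})

test_that("embed_admission filters, sorts, truncates and pads with a prefix
           mask", {
  co <- handmade_cohort()
  m <- train_doc_embeddings(list(n1 = c("pt", "stable", "pt", "stable")),
                            doc2vec_params(dim = 8, epochs = 2,
                                           min_token_count = 1, seed = 1))
  # a1 has one eligible note (n1); n2 is at 26 h
  seq1 <- embed_admission(m, co$notes[co$notes$admission_id == "a1", ],
                          L_max = 4)
  expect_identical(seq1$mask, c(1L, 0L, 0L, 0L))
  expect_identical(seq1$embeddings[1, ],
                   infer_docvec(m, c("pt", "stable", "afebrile")))
  expect_true(all(seq1$embeddings[2:4, ] == 0))
  # a3's only note has an ineligible category
  seq3 <- embed_admission(m, co$notes[co$notes$admission_id == "a3", ],
                          L_max = 4)
  expect_identical(seq3$mask, rep(0L, 4))
  expect_true(all(seq3$embeddings == 0))
  # truncation keeps the first L_max notes by time
  nd <- data.frame(admission_id = "x", note_id = sprintf("m%d", 1:6),
                   category = "Nursing", hour_offset = c(6, 5, 4, 3, 2, 1),
                   stringsAsFactors = FALSE)
  nd$tokens <- rep(list(c("pt", "stable")), 6)
  sq <- embed_admission(m, nd, L_max = 4)
  expect_identical(sq$n_notes, 4L)
  expect_identical(sq$mask, rep(1L, 4))
})

test_that("mean_note_vector averages eligible embeddings element-wise", {
  co <- handmade_cohort()
  m <- train_doc_embeddings(list(n1 = c("pt", "stable", "pt", "icu"),
                                 n3 = c("icu", "admission", "icu", "pt")),
                            doc2vec_params(dim = 8, epochs = 3,
                                           min_token_count = 1, seed = 2))
  nd <- data.frame(admission_id = "x", note_id = c("n1", "n3"),
                   category = c("Nursing", "Physician"),
                   hour_offset = c(1, 2), stringsAsFactors = FALSE)
  nd$tokens <- list(c("pt", "stable"), c("icu", "admission"))
  u <- infer_docvec(m, c("pt", "stable")); v <- infer_docvec(m, c("icu", "admission"))
  expect_equal(mean_note_vector(m, nd), (u + v) / 2, tolerance = 1e-12)
  expect_identical(mean_note_vector(m, nd[1, ]), u)
  expect_identical(mean_note_vector(m, nd[0, ]), numeric(8))
})
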