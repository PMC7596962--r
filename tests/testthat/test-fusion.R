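# Architecture contracts: shapes, padding invariance, ablation
# consistency, training behaviour.

test_that("fusion_spec derives representation sizes and validates input", {
  spec <- fusion_spec("cnn", c("S", "T", "U"), d_static = 10,
                      temporal_channels = 64, note_channels = 128)
  # 24 -> conv 22 -> pool 11 -> conv 9 -> pool 4; 4 * 64 channels
  expect_identical(spec$d_temporal, 256L)
  expect_identical(spec$d_text, 128L)
  expect_identical(spec$d_p, 10L + 256L + 128L)
  spec2 <- fusion_spec("lstm", c("S", "T", "U"), d_static = 10,
                       temporal_hidden = 128, note_hidden = 128)
  expect_identical(spec2$d_p, 10L + 128L + 256L)
  expect_error(fusion_spec("cnn", character()), "non-empty")
  expect_error(fusion_spec("cnn", "S"), "d_static")
})

test_that("fuse_representation concatenates in fixed order and enforces
           presence of active components", {
  z <- fuse_representation(z_static = rep(1, 10), z_temporal = rep(2, 64),
                           z_text = rep(3, 128))
  expect_length(z, 202)
  expect_identical(unname(z[1:10]), rep(1, 10))
  z2 <- fuse_representation(z_static = rep(1, 10), z_temporal = rep(2, 64),
                            z_text = rep(9, 128), modalities = c("T", "S"))
  expect_length(z2, 74)
  expect_false(any(z2 == 9))
  z3 <- fuse_representation(z_text = rep(3, 5), modalities = "U")
  expect_identical(unname(z3), rep(3, 5))
  expect_error(fuse_representation(z_static = 1:3, modalities = c("S", "U")),
               "z_text missing")
})

test_that("encoders emit fixed-size finite outputs whatever the missingness
           pattern", {
  inp <- tiny_inputs(n = 6, seed = 2)
  for (variant in c("cnn", "lstm")) {
    spec <- fusion_spec(variant, c("S", "T", "U"), d_static = 4, n_vars = 5,
                        emb_dim = 6, L_max = 10, temporal_channels = 4,
                        temporal_hidden = 5, note_channels = 4,
                        note_hidden = 5)
    model <- init_fusion_model(spec, 3)
    fwd <- fusion_forward(model, inp)
    expect_identical(dim(fwd$z_p), c(6L, spec$d_p))
    expect_true(all(is.finite(fwd$z_p)))
    expect_true(all(fwd$prob > 0 & fwd$prob < 1))
    # all-zero temporal grid still yields a finite fixed-size encoding
    inp0 <- inp; inp0$temporal[] <- 0
    expect_true(all(is.finite(fusion_forward(model, inp0)$z_p)))
  }
})

test_that("note encoders are padding-invariant: L_max 16 and 32 agree", {
  set.seed(12)
  n <- 5; emb <- 7
  # real sequences must fit the smaller pipeline without truncation for the
  # convolutional path (<= 10 notes at L_max 16 with kernel 3)
  lens <- c(0, 1, 4, 9, 10)
  notes16 <- array(0, c(n, 16, emb))
  notes32 <- array(0, c(n, 32, emb))
  for (i in seq_len(n)) {
    if (lens[i] > 0) {
      block <- matrix(rnorm(lens[i] * emb), lens[i], emb)
      notes16[i, seq_len(lens[i]), ] <- block
      notes32[i, seq_len(lens[i]), ] <- block
    }
  }
  for (variant in c("cnn", "lstm")) {
    s16 <- fusion_spec(variant, "U", emb_dim = emb, L_max = 16,
                       note_channels = 4, note_hidden = 4)
    s32 <- fusion_spec(variant, "U", emb_dim = emb, L_max = 32,
                       note_channels = 4, note_hidden = 4)
    m16 <- init_fusion_model(s16, seed = 7)
    m32 <- init_fusion_model(s32, seed = 7)
    # identical parameter sets (initialization ignores L_max)
    expect_identical(m16$params, m32$params)
    z16 <- fusion_forward(m16, list(notes = notes16, note_lens = lens))$z_p
    z32 <- fusion_forward(m32, list(notes = notes32, note_lens = lens))$z_p
    expect_equal(z16, z32, tolerance = 1e-12)
    # all-padding input maps to the defined neutral output (zeros)
    expect_identical(unname(z16[1, ]), rep(0, s16$d_text))
  }
})

test_that("a {T,S} model is exactly invariant to note perturbation", {
  inp <- tiny_inputs(n = 6, seed = 4)
  for (variant in c("cnn", "lstm")) {
    spec <- fusion_spec(variant, c("T", "S"), d_static = 4, n_vars = 5,
                        temporal_channels = 4, temporal_hidden = 5)
    model <- init_fusion_model(spec, 5)
    p1 <- fusion_forward(model, inp)$prob
    inp2 <- inp
    inp2$notes <- array(rnorm(length(inp$notes), sd = 50), dim(inp$notes))
    inp2$note_lens <- rep(10L, 6)
    expect_identical(p1, fusion_forward(model, inp2)$prob)
  }
})

test_that("training descends on separable data and is seed-reproducible", {
  set.seed(20)
  n <- 60
  inp <- tiny_inputs(n = n, seed = 21)
  # make the static block linearly separable for the label
  inp$y <- sample(0:1, n, replace = TRUE)
  inp$static <- cbind(inp$y, 1 - inp$y, inp$static[, 1:2])
  val <- tiny_inputs(n = 20, seed = 22)
  val$static <- cbind(val$y, 1 - val$y, val$static[, 1:2])
  spec <- fusion_spec("cnn", c("S", "T"), d_static = 4, n_vars = 5,
                      temporal_channels = 3)
  cfg <- train_config(learning_rate = 1e-2, batch_size = 16, max_epochs = 8,
                      patience = 8, seed = 2)
  fit <- train_model(spec, inp, val, cfg)
  expect_lt(fit$log$train_loss[nrow(fit$log)], fit$log$train_loss[1])
  fit2 <- train_model(spec, inp, val, cfg)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$model$params, fit2$model$params)
  expect_error(train_model(spec, list(y = integer()), val, cfg), "empty")
})
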