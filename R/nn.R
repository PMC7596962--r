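# Minimal neural-network primitives for the fusion architectures.
#
# Layers operate on batch-first arrays: time series are (batch, time,
# channels). Every layer exposes an explicit forward (returning a cache)
# and backward (returning parameter and input gradients), so the whole
# model is differentiated by hand and verified against numerical
# gradients in the test suite. Heavy lifting is plain matrix algebra,
# which R delegates to BLAS.

sigm <- function(x) 1 / (1 + exp(-x))

## ---- dense -----------------------------------------------------------

linear_init <- function(d_in, d_out) {
  s <- 1 / sqrt(d_in)
  list(W = matrix(stats::runif(d_in * d_out, -s, s), d_in, d_out),
       b = numeric(d_out))
}

linear_forward <- function(x, p) {
  list(out = x %*% p$W + rep(p$b, each = nrow(x)), x = x)
}

linear_backward <- function(grad, cache, p) {
  list(dx = grad %*% t(p$W),
       dW = crossprod(cache$x, grad),
       db = colSums(grad))
}

## ---- 1-D convolution over time (valid, stride 1) ---------------------

conv1d_init <- function(c_in, c_out, k) {
  s <- 1 / sqrt(k * c_in)
  list(W = matrix(stats::runif(k * c_in * c_out, -s, s), k * c_in, c_out),
       b = numeric(c_out), k = k)
}

conv1d_forward <- function(x, p) {
  d <- dim(x); B <- d[1]; Tt <- d[2]; Cin <- d[3]; k <- p$k
  Tout <- Tt - k + 1L
  if (Tout < 1) stop("conv1d: sequence shorter than kernel")
  cols <- matrix(0, B * Tout, k * Cin)
  for (j in seq_len(k)) {
    cols[, ((j - 1L) * Cin + 1L):(j * Cin)] <-
      matrix(x[, j:(j + Tout - 1L), , drop = FALSE], B * Tout, Cin)
  }
  y <- cols %*% p$W
  y <- y + rep(p$b, each = B * Tout)
  list(out = array(y, c(B, Tout, ncol(p$W))), cols = cols,
       dims = c(B, Tt, Cin, Tout))
}

conv1d_backward <- function(grad, cache, p) {
  B <- cache$dims[1]; Tt <- cache$dims[2]; Cin <- cache$dims[3]
  Tout <- cache$dims[4]; k <- p$k
  g2 <- matrix(grad, B * Tout, ncol(p$W))
  dW <- crossprod(cache$cols, g2)
  db <- colSums(g2)
  dcols <- g2 %*% t(p$W)
  dx <- array(0, c(B, Tt, Cin))
  for (j in seq_len(k)) {
    dx[, j:(j + Tout - 1L), ] <- dx[, j:(j + Tout - 1L), , drop = FALSE] +
      array(dcols[, ((j - 1L) * Cin + 1L):(j * Cin)], c(B, Tout, Cin))
  }
  list(dx = dx, dW = dW, db = db)
}

## ---- ReLU ------------------------------------------------------------

relu_forward <- function(x) list(out = pmax(x, 0), pos = x > 0)
relu_backward <- function(grad, cache) grad * cache$pos

## ---- max-pooling over time, width 2, stride 2 -------------------------

pool2_forward <- function(x) {
  d <- dim(x); Tout <- d[2] %/% 2L
  odd <- seq(1L, 2L * Tout, by = 2L)
  x1 <- x[, odd, , drop = FALSE]
  x2 <- x[, odd + 1L, , drop = FALSE]
  take1 <- x1 >= x2
  list(out = pmax(x1, x2), take1 = take1, Tin = d[2], odd = odd)
}

pool2_backward <- function(grad, cache) {
  d <- dim(grad)
  dx <- array(0, c(d[1], cache$Tin, d[3]))
  dx[, cache$odd, ] <- grad * cache$take1
  dx[, cache$odd + 1L, ] <- grad * !cache$take1
  dx
}

## ---- masked global max-pooling over time ------------------------------
# Only positions t <= lens[b] participate; rows with lens == 0 output 0.
# Ties resolve to the earliest position (deterministic).

masked_maxpool_forward <- function(x, lens) {
  d <- dim(x); B <- d[1]; Tt <- d[2]; C <- d[3]
  run <- matrix(-Inf, B, C)
  arg <- matrix(0L, B, C)
  for (t in seq_len(Tt)) {
    sl <- matrix(x[, t, ], B, C)
    upd <- (t <= lens) & (sl > run)
    run[upd] <- sl[upd]
    arg[upd] <- t
  }
  run[lens == 0, ] <- 0
  list(out = run, arg = arg, dims = d)
}

masked_maxpool_backward <- function(grad, cache) {
  d <- cache$dims
  dx <- array(0, d)
  sel <- which(cache$arg > 0, arr.ind = TRUE)
  if (nrow(sel)) {
    dx[cbind(sel[, 1], cache$arg[sel], sel[, 2])] <-
      dx[cbind(sel[, 1], cache$arg[sel], sel[, 2])] + grad[sel]
  }
  dx
}

## ---- LSTM layer -------------------------------------------------------
# Gate order i, f, g, o. Forget-gate bias initialized to 1.

lstm_init <- function(c_in, h) {
  s <- 1 / sqrt(h)
  b <- numeric(4L * h)
  b[(h + 1L):(2L * h)] <- 1
  list(Wx = matrix(stats::runif(c_in * 4L * h, -s, s), c_in, 4L * h),
       Wh = matrix(stats::runif(h * 4L * h, -s, s), h, 4L * h),
       b = b, h = h)
}

lstm_forward <- function(x, p) {
  d <- dim(x); B <- d[1]; Tt <- d[2]; Cin <- d[3]; H <- p$h
  xW <- matrix(x, B * Tt, Cin) %*% p$Wx
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  Hall <- array(0, c(B, Tt, H))
  cache <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    gates <- xW[((t - 1L) * B + 1L):(t * B), , drop = FALSE] +
      h %*% p$Wh
    gates <- gates + rep(p$b, each = B)
    i <- sigm(gates[, 1:H, drop = FALSE])
    f <- sigm(gates[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(gates[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigm(gates[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = cc, tc = tc,
                       h_prev = h)
    h <- o * tc
    cc <- c_new
    Hall[, t, ] <- h
  }
  list(out = Hall, cache = cache, x = x)
}

lstm_backward <- function(dHall, fwd, p) {
  x <- fwd$x
  d <- dim(x); B <- d[1]; Tt <- d[2]; Cin <- d[3]; H <- p$h
  dWx <- matrix(0, Cin, 4L * H); dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- array(0, c(B, Tt, Cin))
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    cc <- fwd$cache[[t]]
    dh_t <- matrix(dHall[, t, ], B, H) + dh
    do <- dh_t * cc$tc * cc$o * (1 - cc$o)
    dct <- dh_t * cc$o * (1 - cc$tc^2) + dc
    di <- dct * cc$g * cc$i * (1 - cc$i)
    df <- dct * cc$c_prev * cc$f * (1 - cc$f)
    dg <- dct * cc$i * (1 - cc$g^2)
    dc <- dct * cc$f
    dgates <- cbind(di, df, dg, do)
    x_t <- matrix(x[, t, ], B, Cin)
    dWx <- dWx + crossprod(x_t, dgates)
    dWh <- dWh + crossprod(cc$h_prev, dgates)
    db <- db + colSums(dgates)
    dX[, t, ] <- dgates %*% t(p$Wx)
    dh <- dgates %*% t(p$Wh)
  }
  list(dx = dX, dWx = dWx, dWh = dWh, db = db)
}

## ---- reversal of each row's valid prefix ------------------------------
# Reverses x[b, 1:lens[b], ] in time, leaving padding in place; its own
# inverse, which the bidirectional path uses on both activations and
# gradients.

reverse_within_mask <- function(x, lens) {
  out <- x
  for (b in seq_len(dim(x)[1])) {
    l <- lens[b]
    if (l > 1) out[b, 1:l, ] <- x[b, l:1, ]
  }
  out
}

## ---- inverted dropout --------------------------------------------------

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  m <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(m) <- dim(x)
  list(out = x * m, mask = m)
}

dropout_backward <- function(grad, cache) {
  if (is.null(cache$mask)) grad else grad * cache$mask
}

## ---- Adam optimizer ----------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(p) {
    lapply(p, function(v) if (is.list(v)) zero_like(v) else v * 0)
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    for (nm in names(g)) {
      if (is.list(p[[nm]])) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else if (is.numeric(g[[nm]])) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^t)
        vhat <- v[[nm]] / (1 - beta2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

# elementwise sum of two nested gradient lists (NULL-tolerant)
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) grad_add(a[[nm]], b[[nm]])
               else if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}
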