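# Neural-network primitives: dense, 1-D convolution (im2col), LSTM, dropout,
# activations, and Adam. Forward passes return a cache consumed by the
# matching backward pass; all heavy work is BLAS matrix multiplication.
# Gradient correctness is pinned by finite-difference tests.

he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
}

## dense ---------------------------------------------------------------

dense_fwd <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2L, b, "+")
  list(out = out, x = x)
}

dense_bwd <- function(dout, W, cache) {
  list(dW = crossprod(cache$x, dout),
       db = colSums(dout),
       dx = tcrossprod(dout, W))
}

## activations ----------------------------------------------------------

relu_fwd <- function(x) list(out = x * (x > 0), mask = x > 0)
relu_bwd <- function(dout, cache) dout * cache$mask

lrelu_fwd <- function(x, slope) {
  list(out = ifelse(x > 0, x, slope * x), mask = x > 0, slope = slope)
}
lrelu_bwd <- function(dout, cache) {
  dout * ifelse(cache$mask, 1, cache$slope)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## dropout (inverted; identity at rate 0 or at inference) ---------------

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL, rate = rate))
  keep <- array(runif(length(x)) >= rate, dim = dim(x) %||% length(x))
  list(out = x * keep / (1 - rate), mask = keep, rate = rate)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) return(dout)
  dout * cache$mask / (1 - cache$rate)
}

## 1-D convolution, valid padding --------------------------------------
# x: array (n, L, C_in); W: matrix (kernel * C_in, C_out); b: length C_out.

conv_out_len <- function(len, kernel, stride) {
  if (len < kernel) return(NA_integer_)
  as.integer((len - kernel) %/% stride + 1L)
}

conv1d_fwd <- function(x, W, b, kernel, stride) {
  d <- dim(x)
  n <- d[1L]; len <- d[2L]; cin <- d[3L]
  lout <- conv_out_len(len, kernel, stride)
  cout <- ncol(W)
  P <- array(0, c(n, lout, kernel * cin))
  for (t in seq_len(lout)) {
    xt <- x[, (t - 1L) * stride + seq_len(kernel), , drop = FALSE]
    dim(xt) <- c(n, kernel * cin)
    P[, t, ] <- xt
  }
  dim(P) <- c(n * lout, kernel * cin)
  out <- P %*% W
  out <- sweep(out, 2L, b, "+")
  dim(out) <- c(n, lout, cout)
  list(out = out, P = P, dims = list(n = n, len = len, cin = cin, lout = lout,
                                     cout = cout, kernel = kernel,
                                     stride = stride))
}

conv1d_bwd <- function(dout, W, cache) {
  dm <- cache$dims
  dim(dout) <- c(dm$n * dm$lout, dm$cout)
  dW <- crossprod(cache$P, dout)
  db <- colSums(dout)
  dP <- tcrossprod(dout, W)
  dim(dP) <- c(dm$n, dm$lout, dm$kernel * dm$cin)
  dx <- array(0, c(dm$n, dm$len, dm$cin))
  for (t in seq_len(dm$lout)) {
    dpt <- dP[, t, ]
    dim(dpt) <- c(dm$n, dm$kernel, dm$cin)
    idx <- (t - 1L) * dm$stride + seq_len(dm$kernel)
    dx[, idx, ] <- dx[, idx, , drop = FALSE] + dpt
  }
  list(dW = dW, db = db, dx = dx)
}

## LSTM (returns the last hidden state) ---------------------------------
# x: array (n, T, D); Wx: (D, 4H); Wh: (H, 4H); b: length 4H.
# Gate column blocks in order: input, forget, cell candidate, output.

lstm_init <- function(d_in, units) {
  b <- rep(0, 4L * units)
  b[units + seq_len(units)] <- 1  # forget-gate bias at 1
  list(Wx = he_init(d_in, 4L * units), Wh = he_init(units, 4L * units), b = b)
}

lstm_fwd <- function(x, Wx, Wh, b) {
  d <- dim(x)
  n <- d[1L]; Tn <- d[2L]; H <- ncol(Wh) / 4L
  h <- matrix(0, n, H)
  cc <- matrix(0, n, H)
  steps <- vector("list", Tn)
  gi <- seq_len(H); gf <- H + gi; gg <- 2L * H + gi; go <- 3L * H + gi
  for (t in seq_len(Tn)) {
    xt <- x[, t, , drop = FALSE]
    dim(xt) <- c(n, d[3L])
    a <- xt %*% Wx + h %*% Wh
    a <- sweep(a, 2L, b, "+")
    i <- sigmoid(a[, gi, drop = FALSE])
    f <- sigmoid(a[, gf, drop = FALSE])
    g <- tanh(a[, gg, drop = FALSE])
    o <- sigmoid(a[, go, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_new <- o * tc
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = c_prev, i = i, f = f,
                       g = g, o = o, tc = tc)
    h <- h_new
  }
  list(out = h, steps = steps, dims = list(n = n, Tn = Tn, D = d[3L], H = H))
}

lstm_bwd <- function(dh_last, Wx, Wh, cache) {
  dm <- cache$dims
  dWx <- matrix(0, nrow(Wx), ncol(Wx))
  dWh <- matrix(0, nrow(Wh), ncol(Wh))
  db <- rep(0, 4L * dm$H)
  dx <- array(0, c(dm$n, dm$Tn, dm$D))
  dh <- dh_last
  dc <- matrix(0, dm$n, dm$H)
  for (t in rev(seq_len(dm$Tn))) {
    s <- cache$steps[[t]]
    do_ <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    da <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, da)
    dWh <- dWh + crossprod(s$h_prev, da)
    db <- db + colSums(da)
    dx[, t, ] <- tcrossprod(da, Wx)
    dh <- tcrossprod(da, Wh)
    dc <- dc * s$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dx = dx)
}

## Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Learning rate under the exponential decay schedule
#'
#' Continuous exponential decay: `initial_lr * rate^(step / decay_steps)`,
#' e.g. 0.0004 at step 0 and 0.000384 at step 2,500 under the defaults.
#'
#' @param step Zero-based global step.
#' @param initial_lr Initial learning rate.
#' @param rate Decay factor per `decay_steps`.
#' @param decay_steps Steps per decay factor application.
#' @return The learning rate at `step`.
#' @export
lr_schedule <- function(step, initial_lr = 4e-4, rate = 0.96,
                        decay_steps = 2500) {
  initial_lr * rate^(step / decay_steps)
}
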