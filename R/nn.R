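# Minimal neural-network numerics: same-padded dilated 1-D convolutions as
# im2col block-copies + BLAS matrix products, with manual backpropagation and
# Adam updates. Kept dependency-free so the model trains on one CPU.

conv_cols <- function(X, width, dilation) {
  L <- nrow(X); Cin <- ncol(X)
  pad <- dilation * (width - 1L) / 2L
  Xpad <- matrix(0, L + 2L * pad, Cin)
  Xpad[pad + seq_len(L), ] <- X
  out <- matrix(0, L, width * Cin)
  for (j in seq_len(width)) {
    rows <- (j - 1L) * dilation + seq_len(L)
    out[, ((j - 1L) * Cin + 1L):(j * Cin)] <- Xpad[rows, ]
  }
  out
}

conv_fwd <- function(X, W, b, width, dilation = 1L) {
  Xcol <- conv_cols(X, width, dilation)
  Y <- Xcol %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(Y = Y, Xcol = Xcol)
}

# returns gradients and dX (input gradient)
conv_bwd <- function(dY, Xcol, W, width, dilation, L, Cin) {
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dXcol <- dY %*% t(W)
  pad <- dilation * (width - 1L) / 2L
  dXpad <- matrix(0, L + 2L * pad, Cin)
  for (j in seq_len(width)) {
    rows <- (j - 1L) * dilation + seq_len(L)
    dXpad[rows, ] <- dXpad[rows, ] + dXcol[, ((j - 1L) * Cin + 1L):(j * Cin)]
  }
  list(dW = dW, db = db, dX = dXpad[pad + seq_len(L), , drop = FALSE])
}

relu <- function(x) x * (x > 0)

softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
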