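# Minimal convolutional building blocks for the toy detector: im2col-based
# 2-D convolution with hand-written backward passes, plain matrices
# throughout. Feature arrays are H x W x C with the image's y-down row
# convention; flattened position matrices are (H*W) x C with row index
# i + (j-1)*H (row fastest), matching array() filling order.

# Precompute the im2col gather map for a fixed input geometry.
conv_index <- function(H, W, C, k = 3L, stride = 1L, pad = 1L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  oi <- rep(seq_len(Ho), times = Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  top <- (oi - 1L) * stride
  left <- (oj - 1L) * stride
  IM <- matrix(0L, Ho * Wo, k * k * C)
  col <- 0L
  for (ch in seq_len(C)) for (dj in 0:(k - 1L)) for (di in 0:(k - 1L)) {
    col <- col + 1L
    IM[, col] <- (top + di + 1L) + (left + dj) * Hp + (ch - 1L) * (Hp * Wp)
  }
  list(IM = IM, H = H, W = W, C = C, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
}

conv_forward <- function(X, ci, W, b) {
  Xp <- array(0, c(ci$Hp, ci$Wp, ci$C))
  Xp[ci$pad + seq_len(ci$H), ci$pad + seq_len(ci$W), ] <- X
  cols <- matrix(Xp[ci$IM], nrow(ci$IM), ncol(ci$IM))
  Z <- cols %*% W + rep(b, each = nrow(cols))
  list(cols = cols, Z = Z)
}

conv_backward <- function(dZ, cols, ci, W, need_dx = TRUE) {
  dW <- crossprod(cols, dZ)
  db <- colSums(dZ)
  dX <- NULL
  if (need_dx) {
    dcols <- dZ %*% t(W)
    dXp <- numeric(ci$Hp * ci$Wp * ci$C)
    for (kk in seq_len(ncol(ci$IM))) {
      idx <- ci$IM[, kk]
      dXp[idx] <- dXp[idx] + dcols[, kk]
    }
    dXp <- array(dXp, c(ci$Hp, ci$Wp, ci$C))
    dX <- dXp[ci$pad + seq_len(ci$H), ci$pad + seq_len(ci$W), , drop = FALSE]
  }
  list(dW = dW, db = db, dX = dX)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable binary cross-entropy with logits; returns per-element
# losses.
bce_with_logits <- function(o, y) {
  pmax(o, 0) - o * y + log1p(exp(-abs(o)))
}

smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)

smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

softmax_row <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
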