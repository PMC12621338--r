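# Minimal neural-network engine: dense / conv2d ("same", 3x3) / stacked LSTM
# layers with hand-written backward passes and an Adam optimiser. Everything
# runs on base-R matrix products (BLAS), which is fast enough at this
# problem's scale; there is no deep-learning framework dependency.

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc) {
  limit <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -limit, limit), nr, nc)
}

lstm_init <- function(input_dim, hidden) {
  list(Wx = glorot(input_dim, 4 * hidden),
       Wh = glorot(hidden, 4 * hidden),
       b = rep(0, 4 * hidden))
}

# X is time-stacked: a (T*B) x D matrix whose rows are grouped in T blocks
# of B (timestep-major). Stacking lets the input projection, the weight
# gradients and the input gradient each run as one large GEMM; only the
# recurrent product stays inside the timestep loop. Gate column order:
# i, f, o, g (the three sigmoid gates contiguous, tanh block last).
lstm_forward <- function(X, W, hidden, B) {
  Tn <- nrow(X) / B
  H <- hidden
  XW <- X %*% W$Wx
  XW <- XW + rep(W$b, each = nrow(XW))
  I <- FG <- G <- O <- C <- HC <- Hs <- matrix(0, Tn * B, H)
  h <- matrix(0, B, H)
  cc <- matrix(0, B, H)
  for (t in seq_len(Tn)) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    Z <- XW[rows, , drop = FALSE] + h %*% W$Wh
    sg <- sigmoid(Z[, 1:(3 * H), drop = FALSE])
    i <- sg[, 1:H, drop = FALSE]
    f <- sg[, (H + 1):(2 * H), drop = FALSE]
    o <- sg[, (2 * H + 1):(3 * H), drop = FALSE]
    g <- tanh(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cc + i * g
    hc <- tanh(c_new)
    h <- o * hc
    I[rows, ] <- i; FG[rows, ] <- f; G[rows, ] <- g; O[rows, ] <- o
    C[rows, ] <- c_new; HC[rows, ] <- hc; Hs[rows, ] <- h
    cc <- c_new
  }
  list(H = Hs, X = X, I = I, F = FG, G = G, O = O, C = C, HC = HC,
       B = B, Tn = Tn)
}

lstm_last <- function(fw) {
  rows <- ((fw$Tn - 1L) * fw$B + 1L):(fw$Tn * fw$B)
  fw$H[rows, , drop = FALSE]
}

# dH: either a (T*B) x H stacked sequence gradient or a B x H matrix taken
# as the gradient at the last timestep only.
lstm_backward <- function(dH, fw, W, hidden) {
  Tn <- fw$Tn
  B <- fw$B
  H <- hidden
  last_only <- nrow(dH) == B && Tn > 1L
  dZ <- matrix(0, Tn * B, 4L * H)
  dh_next <- matrix(0, B, H)
  dc_next <- matrix(0, B, H)
  zero <- matrix(0, B, H)
  for (t in rev(seq_len(Tn))) {
    rows <- ((t - 1L) * B + 1L):(t * B)
    i <- fw$I[rows, , drop = FALSE]
    f <- fw$F[rows, , drop = FALSE]
    g <- fw$G[rows, , drop = FALSE]
    o <- fw$O[rows, , drop = FALSE]
    hc <- fw$HC[rows, , drop = FALSE]
    c_prev <- if (t > 1L) fw$C[rows - B, , drop = FALSE] else zero
    dh <- dh_next
    if (last_only) {
      if (t == Tn) dh <- dh + dH
    } else {
      dh <- dh + dH[rows, , drop = FALSE]
    }
    do_ <- dh * hc * o * (1 - o)
    dc <- dh * o * (1 - hc^2) + dc_next
    di <- dc * g * i * (1 - i)
    df <- dc * c_prev * f * (1 - f)
    dg <- dc * i * (1 - g^2)
    dZt <- cbind(di, df, do_, dg)
    dZ[rows, ] <- dZt
    dh_next <- tcrossprod(dZt, W$Wh)
    dc_next <- dc * f
  }
  Hprev <- rbind(matrix(0, B, H),
                 fw$H[seq_len((Tn - 1L) * B), , drop = FALSE])
  list(dWx = crossprod(fw$X, dZ), dWh = crossprod(Hprev, dZ),
       db = colSums(dZ), dX = tcrossprod(dZ, W$Wx))
}

# --- conv plumbing (8 x 8 spatial grid, 3 x 3 kernel, "same" padding) -----

conv_geometry <- function(side = 8L) {
  pos <- expand.grid(r = seq_len(side), c = seq_len(side))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  idx <- matrix(NA_integer_, side * side, 9L)
  for (k in seq_len(9L)) {
    rr <- pos$r + offs$dr[k]
    cc <- pos$c + offs$dc[k]
    ok <- rr >= 1 & rr <= side & cc >= 1 & cc <= side
    idx[ok, k] <- (cc[ok] - 1L) * side + rr[ok]
  }
  half <- side %/% 2L
  pool <- matrix(0L, half * half, 4L)
  q <- 1L
  for (pc in seq_len(half)) for (pr in seq_len(half)) {
    rs <- (pr - 1L) * 2L + 1:2
    cs <- (pc - 1L) * 2L + 1:2
    pool[q, ] <- as.integer(outer(rs, (cs - 1L) * side, "+"))
    q <- q + 1L
  }
  list(idx = idx, pool = pool, side = side, half = half)
}

CONV_GEOM <- conv_geometry(8L)

# A: B x 64 x C array -> (B*64) x (9*C) patch matrix
im2col <- function(A, geom = CONV_GEOM) {
  B <- dim(A)[1]
  np <- dim(A)[2]
  C <- dim(A)[3]
  cols <- matrix(0, B * np, 9L * C)
  for (k in seq_len(9L)) {
    src <- geom$idx[, k]
    ok <- !is.na(src)
    M <- array(0, dim = c(B, np, C))
    M[, ok, ] <- A[, src[ok], , drop = FALSE]
    cols[, (seq_len(C) - 1L) * 9L + k] <- matrix(M, B * np, C)
  }
  cols
}

col2im <- function(dcols, B, C, geom = CONV_GEOM) {
  np <- geom$side^2
  dA <- array(0, dim = c(B, np, C))
  for (k in seq_len(9L)) {
    src <- geom$idx[, k]
    ok <- !is.na(src)
    dM <- array(dcols[, (seq_len(C) - 1L) * 9L + k], dim = c(B, np, C))
    dA[, src[ok], ] <- dA[, src[ok], , drop = FALSE] +
      dM[, ok, , drop = FALSE]
  }
  dA
}

maxpool_forward <- function(A, geom = CONV_GEOM) {
  B <- dim(A)[1]
  FF <- dim(A)[3]
  nq <- nrow(geom$pool)
  out <- A[, geom$pool[, 1], , drop = FALSE]
  arg <- array(1L, dim = c(B, nq, FF))
  for (k in 2:4) {
    cand <- A[, geom$pool[, k], , drop = FALSE]
    upd <- cand > out
    out[upd] <- cand[upd]
    arg[upd] <- k
  }
  list(out = out, arg = arg)
}

maxpool_backward <- function(dout, arg, geom = CONV_GEOM) {
  B <- dim(dout)[1]
  FF <- dim(dout)[3]
  dA <- array(0, dim = c(B, geom$side^2, FF))
  for (k in 1:4) {
    m <- arg == k
    dM <- array(0, dim = dim(dout))
    dM[m] <- dout[m]
    dA[, geom$pool[, k], ] <- dA[, geom$pool[, k], , drop = FALSE] + dM
  }
  dA
}

dropout_mask <- function(dim_, p) {
  if (p <= 0) return(NULL)
  array((stats::runif(prod(dim_)) >= p) / (1 - p), dim = dim_)
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
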