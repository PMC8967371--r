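## Internal neural-network math for the cascaded 2D-CNN + BiLSTM.
##
## Frames are held as a matrix with one row per (frame, grid-cell) pair,
## cells varying fastest (column-major cell index q = h + (w-1) * H), and
## one column per feature channel. A same-padded k x k convolution is then
## a sum of k^2 shifted GEMMs: out = sum_t gather(X, t) %*% W[t, , ], with
## gather() a precomputed row-index permutation whose out-of-grid rows
## point at an all-zero padding row. All heavy lifting is dgemm.

.shift_cache <- new.env(parent = emptyenv())

conv_shift_indices <- function(H, W, k, nf) {
  key <- paste(H, W, k, nf, sep = "x")
  hit <- .shift_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (k - 1L) %/% 2L
  P <- H * W
  h <- rep(seq_len(H), W)
  w <- rep(seq_len(W), each = H)
  offs <- expand.grid(dh = -r:r, dw = -r:r)
  pad_row <- nf * P + 1L
  idx <- lapply(seq_len(nrow(offs)), function(t) {
    hh <- h + offs$dh[t]; ww <- w + offs$dw[t]
    ok <- hh >= 1 & hh <= H & ww >= 1 & ww <= W
    cm <- ifelse(ok, hh + (ww - 1L) * H, NA_integer_)
    g <- rep(cm, nf) + rep((0:(nf - 1L)) * P, each = P)
    g[is.na(g)] <- pad_row
    as.integer(g)
  })
  .shift_cache[[key]] <- idx
  idx
}

relu <- function(x) (x > 0) * x

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- parameter initialisation -------------------------------------------

init_stn_params <- function(spec, seed) {
  set.seed(substream_seed(seed, "init"))
  k2 <- spec$kernel^2
  cin <- spec$input_dim[3]
  conv <- list()
  for (l in seq_along(spec$conv_widths)) {
    cout <- spec$conv_widths[l]
    conv[[l]] <- list(
      W = array(stats::rnorm(k2 * cin * cout, sd = sqrt(2 / (k2 * cin))),
                dim = c(k2, cin, cout)),
      b = numeric(cout))
    cin <- cout
  }
  P <- spec$input_dim[1] * spec$input_dim[2]
  fan_fc <- P * cin
  fc1 <- list(W = matrix(stats::rnorm(fan_fc * spec$embed_dim,
                                      sd = sqrt(2 / fan_fc)),
                         fan_fc, spec$embed_dim),
              b = numeric(spec$embed_dim))
  Hd <- spec$lstm_hidden
  lstm_init <- function() {
    r <- 1 / sqrt(Hd)
    b <- numeric(4 * Hd)
    b[(Hd + 1):(2 * Hd)] <- 1          # forget-gate bias
    list(Wx = matrix(stats::runif(spec$embed_dim * 4 * Hd, -r, r),
                     spec$embed_dim, 4 * Hd),
         Wh = matrix(stats::runif(Hd * 4 * Hd, -r, r), Hd, 4 * Hd),
         b = b)
  }
  out <- list(W = matrix(stats::rnorm(2 * Hd * spec$n_classes,
                                      sd = sqrt(1 / (2 * Hd))),
                         2 * Hd, spec$n_classes),
              b = numeric(spec$n_classes))
  list(conv = conv, fc1 = fc1, lstm_f = lstm_init(), lstm_b = lstm_init(),
       out = out)
}

## ---- convolution stack ---------------------------------------------------

conv_forward <- function(M, layer, idx) {
  nr <- nrow(M)
  cout <- length(layer$b)
  Mpad <- rbind(M, 0)
  Z <- matrix(rep(layer$b, each = nr), nr, cout)
  for (t in seq_along(idx))
    Z <- Z + Mpad[idx[[t]], , drop = FALSE] %*%
      matrix(layer$W[t, , ], ncol = cout)
  Z
}

conv_backward <- function(M, layer, idx, dZ) {
  nr <- nrow(M)
  cin <- ncol(M)
  cout <- length(layer$b)
  Mpad <- rbind(M, 0)
  dW <- array(0, dim = dim(layer$W))
  dM <- matrix(0, nr, cin)
  for (t in seq_along(idx)) {
    g <- idx[[t]]
    dW[t, , ] <- crossprod(Mpad[g, , drop = FALSE], dZ)
    dMt <- dZ %*% t(matrix(layer$W[t, , ], ncol = cout))
    valid <- g <= nr
    tgt <- g[valid]
    dM[tgt, ] <- dM[tgt, , drop = FALSE] + dMt[valid, , drop = FALSE]
  }
  list(dW = dW, db = colSums(dZ), dM = dM)
}

## ---- LSTM (one direction) ------------------------------------------------

lstm_forward <- function(E3, p, reverse = FALSE) {
  N <- dim(E3)[1]; TT <- dim(E3)[2]
  Hd <- nrow(p$Wh)
  order <- if (reverse) TT:1 else 1:TT
  h <- matrix(0, N, Hd); cc <- matrix(0, N, Hd)
  cache <- vector("list", TT)
  for (s in seq_len(TT)) {
    xt <- matrix(E3[, order[s], ], N)
    G <- xt %*% p$Wx + h %*% p$Wh + matrix(rep(p$b, each = N), N)
    i <- 1 / (1 + exp(-G[, 1:Hd, drop = FALSE]))
    f <- 1 / (1 + exp(-G[, (Hd + 1):(2 * Hd), drop = FALSE]))
    g <- tanh(G[, (2 * Hd + 1):(3 * Hd), drop = FALSE])
    o <- 1 / (1 + exp(-G[, (3 * Hd + 1):(4 * Hd), drop = FALSE]))
    c_new <- f * cc + i * g
    h_new <- o * tanh(c_new)
    cache[[s]] <- list(x = xt, h_prev = h, c_prev = cc,
                       i = i, f = f, g = g, o = o, c = c_new)
    h <- h_new; cc <- c_new
  }
  list(h_last = h, cache = cache, order = order)
}

lstm_backward <- function(fwd, p, dh_last) {
  TT <- length(fwd$cache)
  N <- nrow(dh_last); Hd <- ncol(dh_last)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dE <- array(0, dim = c(N, TT, nrow(p$Wx)))
  dh <- dh_last; dc <- matrix(0, N, Hd)
  for (s in TT:1) {
    cc <- fwd$cache[[s]]
    tc <- tanh(cc$c)
    dct <- dc + dh * cc$o * (1 - tc^2)
    G <- cbind(dct * cc$g * cc$i * (1 - cc$i),        # pre-activation gate grads
               dct * cc$c_prev * cc$f * (1 - cc$f),   # order i, f, g, o
               dct * cc$i * (1 - cc$g^2),
               dh * tc * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, G)
    dWh <- dWh + crossprod(cc$h_prev, G)
    db <- db + colSums(G)
    dE[, fwd$order[s], ] <- G %*% t(p$Wx)
    dh <- G %*% t(p$Wh)
    dc <- dct * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dE = dE)
}

## ---- full forward / backward --------------------------------------------

frames_to_matrix <- function(x) {
  ## x: (N, T, H, W, C) -> ((H*W*T*N) rows, C cols), cell fastest, then t,
  ## then n, so frame index = t + (n-1)*T.
  d <- dim(x)
  ap <- aperm(x, c(3, 4, 2, 1, 5))
  dim(ap) <- c(d[3] * d[4] * d[2] * d[1], d[5])
  ap
}

stn_forward <- function(params, x, spec, want_cache = FALSE) {
  d <- dim(x)
  N <- d[1]; TT <- d[2]
  P <- d[3] * d[4]
  nf <- N * TT
  idx <- conv_shift_indices(d[3], d[4], spec$kernel, nf)
  M <- frames_to_matrix(x)
  conv_in <- list(); conv_out <- list()
  A <- M
  for (l in seq_along(params$conv)) {
    conv_in[[l]] <- A
    Z <- conv_forward(A, params$conv[[l]], idx)
    A <- relu(Z)
    conv_out[[l]] <- A
  }
  clast <- ncol(A)
  dim(A) <- c(P, nf, clast)
  Ap <- aperm(A, c(2, 1, 3))
  dim(Ap) <- c(nf, P * clast)                      # one row per frame
  E <- relu(Ap %*% params$fc1$W +
              matrix(rep(params$fc1$b, each = nf), nf))
  E3 <- array(E, dim = c(TT, N, spec$embed_dim))   # frame = t + (n-1)T
  E3 <- aperm(E3, c(2, 1, 3))                      # (N, T, embed)
  fwd_f <- lstm_forward(E3, params$lstm_f, reverse = FALSE)
  fwd_b <- lstm_forward(E3, params$lstm_b, reverse = TRUE)
  Hcat <- cbind(fwd_f$h_last, fwd_b$h_last)
  logits <- Hcat %*% params$out$W +
    matrix(rep(params$out$b, each = N), N)
  prob <- softmax_rows(logits)
  if (!want_cache) return(list(prob = prob))
  list(prob = prob,
       cache = list(idx = idx, conv_in = conv_in, conv_out = conv_out,
                    Ap = Ap, E = E, E3 = E3, fwd_f = fwd_f, fwd_b = fwd_b,
                    Hcat = Hcat, dims = d, P = P, nf = nf, clast = clast))
}

stn_backward <- function(params, cache, prob, y_idx) {
  N <- nrow(prob); K <- ncol(prob)
  Y <- matrix(0, N, K); Y[cbind(seq_len(N), y_idx)] <- 1
  dlogits <- (prob - Y) / N
  g <- list()
  g$out <- list(W = crossprod(cache$Hcat, dlogits), b = colSums(dlogits))
  dH <- dlogits %*% t(params$out$W)
  Hd <- ncol(cache$fwd_f$h_last)
  bk_f <- lstm_backward(cache$fwd_f, params$lstm_f,
                        dH[, 1:Hd, drop = FALSE])
  bk_b <- lstm_backward(cache$fwd_b, params$lstm_b,
                        dH[, (Hd + 1):(2 * Hd), drop = FALSE])
  g$lstm_f <- list(Wx = bk_f$dWx, Wh = bk_f$dWh, b = bk_f$db)
  g$lstm_b <- list(Wx = bk_b$dWx, Wh = bk_b$dWh, b = bk_b$db)
  dE3 <- bk_f$dE + bk_b$dE                          # (N, T, embed)
  TT <- dim(dE3)[2]
  dE <- aperm(dE3, c(2, 1, 3))                      # (T, N, embed)
  dim(dE) <- c(cache$nf, dim(dE3)[3])
  dE <- dE * (cache$E > 0)
  g$fc1 <- list(W = crossprod(cache$Ap, dE), b = colSums(dE))
  dAp <- dE %*% t(params$fc1$W)
  dim(dAp) <- c(cache$nf, cache$P, cache$clast)
  dA <- aperm(dAp, c(2, 1, 3))
  dim(dA) <- c(cache$P * cache$nf, cache$clast)
  g$conv <- vector("list", length(params$conv))
  for (l in rev(seq_along(params$conv))) {
    dZ <- dA * (cache$conv_out[[l]] > 0)
    bk <- conv_backward(cache$conv_in[[l]], params$conv[[l]], cache$idx, dZ)
    g$conv[[l]] <- list(W = bk$dW, b = bk$db)
    dA <- bk$dM
  }
  g
}

sgd_step <- function(params, grads, lr) {
  walk <- function(p, g) {
    if (is.list(p)) {
      keys <- names(p) %||% seq_along(p)
      for (k in keys) p[[k]] <- walk(p[[k]], g[[k]])
      return(p)
    }
    p - lr * g
  }
  walk(params, grads)
}

cross_entropy <- function(prob, y_idx) {
  -mean(log(pmax(prob[cbind(seq_len(nrow(prob)), y_idx)], 1e-12)))
}

stn_param_count <- function(params) {
  length(unlist(params, use.names = FALSE))
}
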