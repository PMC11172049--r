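# Internal numerical engine for the wavelet CNN.  Activations are stored
# in a flat matrix layout: one row per (pixel, image) pair with pixels of
# each image contiguous, one column per channel.  Convolutions become a
# single BLAS matrix product against a gathered patch matrix, and the
# gather/scatter index tables are cached per spatial shape, which keeps
# the whole pass in vectorised C code.  Everything is plain R so the
# forward and backward passes are deterministic for a fixed seed.

# --- layout helpers -------------------------------------------------------

# 4-D (H, W, C, N) array -> (H*W*N) x C matrix; rows ordered i, j, n
to_mat <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1] * d[2] * d[4], d[3])
  attr(m, "hwn") <- c(d[1], d[2], d[4])
  m
}

from_mat <- function(m, hwn = attr(m, "hwn")) {
  ch <- ncol(m)
  aperm(array(m, c(hwn[1], hwn[2], hwn[3], ch)), c(1L, 2L, 4L, 3L))
}

# --- cached gather/scatter indices ---------------------------------------

conv_idx_cache <- new.env(parent = emptyenv())

conv_out_side <- function(side, k, stride, pad) (side + 2L * pad - k) %/% stride + 1L

# index tables for one (shape, kernel) combination:
#   $taps  : (Ho*Wo*N) x k^2 matrix of row indices into the padded matrix
#   $inner : rows of the padded matrix holding the unpadded input
#   $pdim  : padded (Hp, Wp, N)
conv_indices <- function(h, w, n, k, stride, pad) {
  key <- paste(h, w, n, k, stride, pad, sep = "_")
  hit <- conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- conv_out_side(h, k, stride, pad)
  wo <- conv_out_side(w, k, stride, pad)
  n_off <- (seq_len(n) - 1L) * hp * wp
  base_i <- (seq_len(ho) - 1L) * stride
  base_j <- (seq_len(wo) - 1L) * stride
  taps <- matrix(0L, ho * wo * n, k * k)
  t_idx <- 0L
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    t_idx <- t_idx + 1L
    ij <- outer(base_i + di, (base_j + dj - 1L) * hp, "+")
    taps[, t_idx] <- as.integer(outer(as.vector(ij), n_off, "+"))
  }
  inner <- if (pad > 0L) {
    ij <- outer(pad + seq_len(h), (pad + seq_len(w) - 1L) * hp, "+")
    as.integer(outer(as.vector(ij), n_off, "+"))
  } else NULL
  out <- list(taps = taps, inner = inner, pdim = c(hp, wp, n), ho = ho, wo = wo)
  conv_idx_cache[[key]] <- out
  out
}

# --- convolution ----------------------------------------------------------

# weight array (k, k, Cin, Cout) -> (k^2 * Cin) x Cout matrix whose row
# order matches the patch-matrix column blocks (channels inner, taps outer)
weights_to_mat <- function(w) {
  d <- dim(w)
  matrix(aperm(w, c(3L, 1L, 2L, 4L)), d[1] * d[2] * d[3], d[4])
}

conv_forward <- function(xm, hwn, w, b, stride, pad, keep_cache = FALSE) {
  k <- dim(w)[1]; cin <- dim(w)[3]
  ix <- conv_indices(hwn[1], hwn[2], hwn[3], k, stride, pad)
  xp <- if (pad > 0L) {
    tmp <- matrix(0, prod(ix$pdim), cin)
    tmp[ix$inner, ] <- xm
    tmp
  } else xm
  m <- nrow(ix$taps)
  if (k == 1L) {
    cols <- xp
  } else {
    cols <- matrix(0, m, k * k * cin)
    for (t in seq_len(k * k))
      cols[, ((t - 1L) * cin + 1L):(t * cin)] <- xp[ix$taps[, t], , drop = FALSE]
  }
  wm <- weights_to_mat(w)
  out <- cols %*% wm
  out <- out + rep(b, each = m)
  cache <- if (keep_cache) list(cols = cols, wm = wm, hwn = hwn, k = k,
                                stride = stride, pad = pad, ix = ix, cin = cin) else NULL
  list(out = out, hwn = c(ix$ho, ix$wo, hwn[3]), cache = cache)
}

conv_backward <- function(dout, cache) {
  ix <- cache$ix; k <- cache$k; cin <- cache$cin
  dwm <- crossprod(cache$cols, dout)
  db <- colSums(dout)
  dcols <- tcrossprod(dout, cache$wm)
  if (k == 1L && cache$pad == 0L) {
    dxm <- dcols
  } else {
    dxp <- matrix(0, prod(ix$pdim), cin)
    for (t in seq_len(k * k)) {
      blk <- dcols[, ((t - 1L) * cin + 1L):(t * cin), drop = FALSE]
      rows <- ix$taps[, t]
      dxp[rows, ] <- dxp[rows, , drop = FALSE] + blk
    }
    dxm <- if (cache$pad > 0L) dxp[ix$inner, , drop = FALSE] else dxp
  }
  dw <- aperm(array(dwm, c(cin, k, k, ncol(dout))), c(2L, 3L, 1L, 4L))
  list(dx = dxm, dw = dw, db = db)
}

# --- batch normalisation --------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_forward <- function(xm, gamma, beta, training, rmean, rvar, keep_cache = FALSE) {
  m <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    v <- colMeans(xc * xc)
    rmean <- (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu
    rvar <- (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * v
  } else {
    mu <- rmean; v <- rvar
    xc <- xm - rep(mu, each = m)
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(istd, each = m)
  out <- xhat * rep(gamma, each = m)
  out <- out + rep(beta, each = m)
  cache <- if (keep_cache) list(xhat = xhat, istd = istd, gamma = gamma) else NULL
  list(out = out, cache = cache, rmean = rmean, rvar = rvar)
}

bn_backward <- function(dout, cache) {
  m <- nrow(dout)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(cache$gamma, each = m)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dxm <- dxhat * m - rep(s1, each = m) - cache$xhat * rep(s2, each = m)
  dxm <- dxm * rep(cache$istd / m, each = m)
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

# --- pooling, head, loss --------------------------------------------------

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

# matrix layout -> N x C feature matrix of spatial means
gap_forward <- function(xm, hwn) {
  hw <- hwn[1] * hwn[2]
  grp <- rep(seq_len(hwn[3]), each = hw)
  f <- rowsum(xm, grp, reorder = FALSE) / hw
  rownames(f) <- NULL
  f
}

gap_backward <- function(dout, hwn) {
  hw <- hwn[1] * hwn[2]
  dout[rep(seq_len(hwn[3]), each = hw), , drop = FALSE] / hw
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy over integer labels in 1..K; returns loss and dlogits
softmax_xent <- function(logits, y1) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  idx <- cbind(seq_len(n), y1)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dl <- p
  dl[idx] <- dl[idx] - 1
  list(loss = loss, dlogits = dl / n, probs = p)
}

# --- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
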