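# Primitive differentiable layers.
#
# Each `*_fwd` returns `list(out, cache)`; the matching `*_bwd` consumes the
# upstream gradient and the cache and returns the input gradient plus named
# parameter gradients.  Everything is plain base-R matrix code; the test
# suite checks every layer against finite differences.

.idx_memo <- new.env(parent = emptyenv())

im2col_meta <- function(C, H, W, kh, kw) {
  key <- paste("c2", C, H, W, kh, kw, sep = "_")
  hit <- .idx_memo[[key]]
  if (!is.null(hit)) return(hit)
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  Hp <- H + 2L * ph
  Wp <- W + 2L * pw
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  ch <- rep(seq_len(C), times = kh * kw)
  r <- rep(rep(seq_len(kh), each = C), times = kw)
  cc <- rep(seq_len(kw), each = C * kh)
  A <- outer(r - 1L, i, `+`)   # padded row coordinate
  B <- outer(cc - 1L, j, `+`)  # padded col coordinate
  idx <- ch + C * (A - 1L) + C * Hp * (B - 1L)
  meta <- c(list(idx = idx, C = C, H = H, W = W, Hp = Hp, Wp = Wp,
                 ph = ph, pw = pw), scatter_plan(idx))
  .idx_memo[[key]] <- meta
  meta
}

# Precomputed plan for accumulating values at repeated indices: sort once,
# then a cumsum over the sorted values gives per-target sums in O(n).
scatter_plan <- function(idx) {
  v <- as.vector(idx)
  ord <- order(v)
  sorted <- v[ord]
  ends <- c(which(sorted[-1L] != sorted[-length(sorted)]), length(sorted))
  list(ord = ord, ends = ends, targets = sorted[ends])
}

scatter_add <- function(values, plan, n_out) {
  cs <- cumsum(values[plan$ord])
  out <- numeric(n_out)
  out[plan$targets] <- diff(c(0, cs[plan$ends]))
  out
}

pad2d <- function(x, meta) {
  xp <- array(0, dim = c(meta$C, meta$Hp, meta$Wp))
  xp[, meta$ph + seq_len(meta$H), meta$pw + seq_len(meta$W)] <- x
  xp
}

# x: array (C, H, W); Wm: matrix (O, C*kh*kw); b: length O
conv2d_fwd <- function(x, Wm, b, kh, kw) {
  d <- dim(x)
  meta <- im2col_meta(d[1], d[2], d[3], kh, kw)
  cols <- matrix(pad2d(x, meta)[meta$idx], nrow = nrow(meta$idx))
  out <- Wm %*% cols + b
  list(out = array(out, dim = c(nrow(Wm), d[2], d[3])),
       cache = list(cols = cols, meta = meta, Wm = Wm))
}

conv2d_bwd <- function(dout, cache) {
  meta <- cache$meta
  dmat <- matrix(dout, nrow = dim(dout)[1])
  dW <- dmat %*% t(cache$cols)
  db <- rowSums(dmat)
  dcols <- t(cache$Wm) %*% dmat
  dxp <- array(scatter_add(dcols, meta, meta$C * meta$Hp * meta$Wp),
               dim = c(meta$C, meta$Hp, meta$Wp))
  dx <- dxp[, meta$ph + seq_len(meta$H), meta$pw + seq_len(meta$W),
            drop = FALSE]
  list(dx = array(dx, dim = c(meta$C, meta$H, meta$W)), dW = dW, db = db)
}

im1col_meta <- function(C, L, k, stride) {
  key <- paste("c1", C, L, k, stride, sep = "_")
  hit <- .idx_memo[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1L) %/% 2L
  Lp <- L + 2L * p
  Lout <- (L + 2L * p - k) %/% stride + 1L
  pos <- (seq_len(Lout) - 1L) * stride          # 0-based start in padded
  ch <- rep(seq_len(C), times = k)
  r <- rep(seq_len(k), each = C)
  A <- outer(r - 1L, pos, `+`) + 1L             # padded coordinate, 1-based
  idx <- ch + C * (A - 1L)
  meta <- c(list(idx = idx, C = C, L = L, Lp = Lp, Lout = Lout, p = p),
            scatter_plan(idx))
  .idx_memo[[key]] <- meta
  meta
}

# x: matrix (C, L); Wm: (O, C*k)
conv1d_fwd <- function(x, Wm, b, k, stride) {
  d <- dim(x)
  meta <- im1col_meta(d[1], d[2], k, stride)
  xp <- matrix(0, meta$C, meta$Lp)
  xp[, meta$p + seq_len(meta$L)] <- x
  cols <- matrix(xp[meta$idx], nrow = nrow(meta$idx))
  out <- Wm %*% cols + b
  list(out = out, cache = list(cols = cols, meta = meta, Wm = Wm))
}

conv1d_bwd <- function(dout, cache) {
  meta <- cache$meta
  dW <- dout %*% t(cache$cols)
  db <- rowSums(dout)
  dcols <- t(cache$Wm) %*% dout
  dxp <- matrix(scatter_add(dcols, meta, meta$C * meta$Lp),
                meta$C, meta$Lp)
  list(dx = dxp[, meta$p + seq_len(meta$L), drop = FALSE], dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}
relu_bwd <- function(dout, mask) dout * mask

# 3x3 stride-1 average pooling with zero padding (divisor 9 everywhere)
avgpool3_fwd <- function(x) {
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2L, d[3] + 2L))
  xp[, 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- x
  out <- array(0, dim = d)
  for (r in 0:2) for (cc in 0:2) {
    out <- out + xp[, r + seq_len(d[2]), cc + seq_len(d[3]), drop = FALSE]
  }
  list(out = out / 9, cache = d)
}

avgpool3_bwd <- function(dout, d) {
  g <- dout / 9
  dxp <- array(0, dim = c(d[1], d[2] + 2L, d[3] + 2L))
  for (r in 0:2) for (cc in 0:2) {
    dxp[, r + seq_len(d[2]), cc + seq_len(d[3])] <-
      dxp[, r + seq_len(d[2]), cc + seq_len(d[3]), drop = FALSE] + g
  }
  array(dxp[, 1 + seq_len(d[2]), 1 + seq_len(d[3]), drop = FALSE], dim = d)
}

# X: (n x in) batch; W: (in x out)
linear_fwd <- function(X, W, b) {
  list(out = X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE),
       cache = list(X = X, W = W))
}
linear_bwd <- function(dout, cache) {
  list(dx = dout %*% t(cache$W), dW = t(cache$X) %*% dout,
       db = colSums(dout))
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - p), dim = dim(x) %||%
                  length(x)) / (1 - p)
  list(out = x * mask, cache = mask)
}
dropout_bwd <- function(dout, mask) {
  if (is.null(mask)) dout else dout * mask
}

# layer norm over the last (feature) dimension; X: (n x D)
layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- xhat * matrix(g, nrow(X), length(g), byrow = TRUE) +
    matrix(b, nrow(X), length(b), byrow = TRUE)
  list(out = out, cache = list(xhat = xhat, inv = inv, g = g))
}

layernorm_bwd <- function(dout, cache) {
  D <- ncol(dout)
  g <- matrix(cache$g, nrow(dout), D, byrow = TRUE)
  dxhat <- dout * g
  xhat <- cache$xhat
  # standard layer-norm gradient
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dg = colSums(dout * xhat), db = colSums(dout))
}

# softmax attention pooling; Z: (L x D), w: length D
attnpool_fwd <- function(Z, w) {
  e <- as.vector(Z %*% w)
  e <- e - max(e)
  a <- exp(e)
  a <- a / sum(a)
  list(out = as.vector(t(Z) %*% a), cache = list(Z = Z, w = w, a = a))
}

attnpool_bwd <- function(dout, cache) {
  Z <- cache$Z
  a <- cache$a
  dZ <- a %o% dout                       # from the weighted sum
  da <- as.vector(Z %*% dout)
  de <- a * (da - sum(da * a))           # softmax jacobian
  dw <- as.vector(t(Z) %*% de)
  dZ <- dZ + de %o% cache$w
  list(dZ = dZ, dw = dw)
}

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

glorot <- function(nr, nc, fan_in = nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}
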