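# Selective state-space sequence model.
#
# Continuous dynamics h' = A h + b x, y = c h + Dskip x with diagonal A and
# input-dependent (Delta_t, b_t, c_t) are discretized step-by-step with the
# zero-order hold: Abar = exp(Delta A), bbar = (exp(Delta A) - 1) / A * b,
# then scanned as h_t = Abar_t h_{t-1} + bbar_t x_t, y_t = c_t h_t + Dskip x_t.
# The batched forward/backward below is the training path; the exported
# single-sequence functions are the documented user surface.

#' Zero-order-hold discretization of a diagonal SSM
#'
#' Element-wise `Abar = exp(delta * a)` and
#' `bbar = ((exp(delta * a) - 1) / a) * b`, with the analytic limit
#' `bbar -> delta * b` as `a -> 0` (removable singularity).
#'
#' @param a_diag Diagonal entries of the state matrix (any shape, recycled).
#' @param b_t Input projection values.
#' @param delta_t Positive time-scale values.
#' @return List with `Abar` and `bbar`.
#' @examples
#' ssm_discretize(-1, 1, 0.1)   # Abar = exp(-0.1), bbar = (1 - exp(-0.1))
#' @export
ssm_discretize <- function(a_diag, b_t, delta_t) {
  if (any(delta_t <= 0)) abort("`delta_t` must be positive")
  u <- delta_t * a_diag
  Abar <- exp(u)
  e1 <- ifelse(abs(a_diag) < 1e-12, delta_t, expm1(u) / a_diag)
  list(Abar = Abar, bbar = e1 * b_t)
}

#' Parameters for a selective SSM block
#'
#' @param D Channel count.
#' @param N State size per channel.
#' @param seed Seed for the projection initializations.
#' @return Named list: `A` (D x N, negative-real init `-1..-N`), `W_delta`
#'   (D x D), `b_delta` (length D, initialized so that
#'   `softplus(b_delta) ~ 0.05`), `W_b`, `W_c` (D x N), `Dskip` (length D).
#' @export
ssm_params <- function(D, N, seed = NULL) {
  with_local_seed(seed, {
    list(
      A = matrix(rep(-(seq_len(N)), each = D), D, N),
      W_delta = matrix(rnorm(D * D, 0, 0.05 / sqrt(D)), D, D),
      b_delta = rep(log(expm1(0.05)), D),
      W_b = matrix(rnorm(D * N, 0, 1 / sqrt(D)), D, N),
      W_c = matrix(rnorm(D * N, 0, 1 / sqrt(D)), D, N),
      Dskip = rep(1, D)
    )
  })
}

#' Selective SSM scan over one sequence
#'
#' Runs the exact ZOH recurrence over `t = 1..L` from `h_0 = 0`.  By default
#' the per-step time scale, input and output projections are generated from
#' the current input (`Delta_t = softplus(W_delta x_t + b_delta)`,
#' `b_t = W_b' x_t`, `c_t = W_c' x_t`); supplying `fixed` (a list with
#' scalars/vectors `delta`, `b`, `c`) freezes them instead, which reduces the
#' block to a linear time-invariant scan.
#'
#' @param x `L x D` input sequence (a vector is treated as `L x 1`).
#' @param params [ssm_params()] list (only `A` and `Dskip` are used when
#'   `fixed` is given).
#' @param fixed Optional list `list(delta=, b=, c=)` of constant step
#'   parameters.
#' @return `L x D` output sequence.
#' @export
selective_ssm_scan <- function(x, params, fixed = NULL) {
  x <- as.matrix(x)
  L <- nrow(x)
  D <- ncol(x)
  N <- ncol(params$A)
  if (nrow(params$A) != D) abort("params$A must have one row per channel")
  h <- matrix(0, D, N)
  y <- matrix(0, L, D)
  for (t in seq_len(L)) {
    xt <- x[t, ]
    if (is.null(fixed)) {
      delta <- softplus(as.vector(crossprod(params$W_delta, xt)) +
                         params$b_delta)
      bt <- as.vector(crossprod(params$W_b, xt))   # length N
      ct <- as.vector(crossprod(params$W_c, xt))
    } else {
      delta <- rep_len(fixed$delta, D)
      bt <- rep_len(fixed$b, N)
      ct <- rep_len(fixed$c, N)
    }
    stopifnot(all(delta > 0))
    disc <- ssm_discretize(params$A, matrix(bt, D, N, byrow = TRUE),
                           matrix(delta, D, N))
    h <- disc$Abar * h + disc$bbar * xt
    y[t, ] <- as.vector(h %*% ct) + params$Dskip * xt
  }
  y
}

# ---- batched training path -------------------------------------------------

# slice step t from an (L, B, D) array as a B x D matrix without re-wrapping
slice2 <- function(A, t, nr, nc) {
  m <- A[t, , ]
  if (is.matrix(m)) m else matrix(m, nr, nc)
}

ssm_maps <- function(B, D, N) {
  DN <- D * N
  dcol <- rep(seq_len(D), times = N)
  nmap <- rep(seq_len(N), each = D)
  Dmat <- matrix(0, DN, D)
  Dmat[cbind(seq_len(DN), dcol)] <- 1
  Nmat <- matrix(0, DN, N)
  Nmat[cbind(seq_len(DN), nmap)] <- 1
  list(dcol = dcol, nmap = nmap, Dmat = Dmat, Nmat = Nmat, DN = DN)
}

# X: array (L, B, D).  Returns Y (L, B, D) and caches for backward.
ssm_batch_fwd <- function(X, p) {
  L <- dim(X)[1]; B <- dim(X)[2]; D <- dim(X)[3]
  N <- ncol(p$A)
  mp <- ssm_maps(B, D, N)
  A_rep <- matrix(as.vector(p$A), B, mp$DN, byrow = TRUE)
  Dsk <- matrix(p$Dskip, B, D, byrow = TRUE)
  bdel <- matrix(p$b_delta, B, D, byrow = TRUE)
  H <- array(0, dim = c(L, B, mp$DN))
  DeltaS <- array(0, dim = c(L, B, D))
  BtS <- array(0, dim = c(L, B, N))
  CtS <- array(0, dim = c(L, B, N))
  Y <- array(0, dim = c(L, B, D))
  h <- matrix(0, B, mp$DN)
  small <- abs(A_rep) < 1e-12
  for (t in seq_len(L)) {
    xt <- slice2(X, t, B, D)
    delta <- softplus(xt %*% p$W_delta + bdel)
    bt <- xt %*% p$W_b
    ct <- xt %*% p$W_c
    u <- delta[, mp$dcol] * A_rep
    Abar <- exp(u)
    e1 <- expm1(u) / A_rep
    if (any(small)) e1[small] <- delta[, mp$dcol][small]
    h <- Abar * h + e1 * bt[, mp$nmap] * xt[, mp$dcol]
    Y[t, , ] <- (h * ct[, mp$nmap]) %*% mp$Dmat + Dsk * xt
    H[t, , ] <- h
    DeltaS[t, , ] <- delta
    BtS[t, , ] <- bt
    CtS[t, , ] <- ct
  }
  list(out = Y, cache = list(X = X, H = H, Delta = DeltaS, Bt = BtS,
                             Ct = CtS, mp = mp, A_rep = A_rep, p = p,
                             dims = c(L, B, D, N)))
}

ssm_batch_bwd <- function(dY, cache) {
  d <- cache$dims
  L <- d[1]; B <- d[2]; D <- d[3]; N <- d[4]
  mp <- cache$mp
  p <- cache$p
  A_rep <- cache$A_rep
  small <- abs(A_rep) < 1e-12
  Dsk <- matrix(p$Dskip, B, D, byrow = TRUE)
  dh <- matrix(0, B, mp$DN)
  dX <- array(0, dim = c(L, B, D))
  gA <- matrix(0, B, mp$DN)
  gWd <- matrix(0, D, D); gbd <- numeric(D)
  gWb <- matrix(0, D, N); gWc <- matrix(0, D, N)
  gDsk <- numeric(D)
  for (t in rev(seq_len(L))) {
    xt <- slice2(cache$X, t, B, D)
    ht <- slice2(cache$H, t, B, mp$DN)
    hprev <- if (t > 1) slice2(cache$H, t - 1, B, mp$DN) else
      matrix(0, B, mp$DN)
    delta <- slice2(cache$Delta, t, B, D)
    bt <- slice2(cache$Bt, t, B, N)
    ct <- slice2(cache$Ct, t, B, N)
    dyt <- slice2(dY, t, B, D)

    gDsk <- gDsk + colSums(dyt * xt)
    dxt <- dyt * Dsk
    dht <- dh + dyt[, mp$dcol] * ct[, mp$nmap]
    dct <- (dyt[, mp$dcol] * ht) %*% mp$Nmat

    dx_e <- delta[, mp$dcol]
    u <- dx_e * A_rep
    Abar <- exp(u)
    e1 <- expm1(u) / A_rep
    if (any(small)) e1[small] <- dx_e[small]
    bt_e <- bt[, mp$nmap]
    xd <- xt[, mp$dcol]
    bbar <- e1 * bt_e

    dAbar <- dht * hprev
    dbbar <- dht * xd
    dxt <- dxt + (dht * bbar) %*% mp$Dmat
    dbt <- (dbbar * e1) %*% mp$Nmat
    de1 <- dbbar * bt_e
    de1_da <- (dx_e * Abar - e1) / A_rep
    if (any(small)) de1_da[small] <- (dx_e[small]^2) / 2
    gA <- gA + dAbar * dx_e * Abar + de1 * de1_da
    ddelta_e <- dAbar * A_rep * Abar + de1 * Abar
    ddelta <- ddelta_e %*% mp$Dmat
    dh <- dht * Abar

    dzd <- ddelta * (1 - exp(-delta))       # softplus'(z) = sigmoid(z)
    gWd <- gWd + crossprod(xt, dzd)
    gbd <- gbd + colSums(dzd)
    dxt <- dxt + dzd %*% t(p$W_delta)
    gWb <- gWb + crossprod(xt, dbt)
    dxt <- dxt + dbt %*% t(p$W_b)
    gWc <- gWc + crossprod(xt, dct)
    dxt <- dxt + dct %*% t(p$W_c)
    dX[t, , ] <- dxt
  }
  list(dx = dX,
       grads = list(A = matrix(colSums(gA), D, N),
                    W_delta = gWd, b_delta = gbd,
                    W_b = gWb, W_c = gWc, Dskip = gDsk))
}
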