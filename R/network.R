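# Dual-stream classifier.
#
# TFRIM branch: position-encoded CNN (7x7 stem, two multi-branch inception
# blocks, CBAM attention, global average pooling, 128-d projection).
# Temporal branch: strided 1-D conv front-end (9120 -> 1140 steps), pre-norm
# selective-SSM block with residual, attention pooling, 128-d projection.
# Fusion: concatenate (TFRIM first), calibrate with demographics-driven
# affine modulation (scale alpha, shift beta from a 4-d demographic vector),
# then a shared MLP head emitting three subtask logits (FEF25-75, FEF50,
# FEF75) squashed by a sigmoid.  Any branch can be ablated; alternative
# demographic fusion heads (concatenation, gating, additive bias) are kept
# behind a switch for protocol comparisons.

#' Two-channel positional grid
#'
#' Channel 1 encodes the normalized frequency index down the rows, channel 2
#' the normalized time index across the columns; both run 0 to 1 (a
#' single-row/column axis encodes as all zeros).  Concatenated onto the TFRIM
#' so the convolutional branch can use absolute spectral position.
#'
#' @param H,W Grid height (frequency) and width (time).
#' @return Array `(2, H, W)`.
#' @export
positional_grid <- function(H = 24L, W = 48L) {
  if (H < 1 || W < 1) abort("grid dimensions must be >= 1")
  fr <- if (H == 1) rep(0, H) else (seq_len(H) - 1) / (H - 1)
  tm <- if (W == 1) rep(0, W) else (seq_len(W) - 1) / (W - 1)
  g <- array(0, dim = c(2L, H, W))
  g[1, , ] <- matrix(fr, H, W)
  g[2, , ] <- matrix(tm, H, W, byrow = TRUE)
  g
}

#' Attention pooling over a feature sequence
#'
#' Softmax-normalized scores `e_t = w . z_t` weight the time steps; the
#' pooled context vector is the convex combination `sum_t alpha_t z_t`.
#'
#' @param Z `L x D` feature sequence.
#' @param w Length-`D` score vector.
#' @return List with `vcontext` (length `D`) and `alpha` (length `L`,
#'   non-negative, summing to 1).
#' @export
attention_pool <- function(Z, w) {
  Z <- as.matrix(Z)
  fw <- attnpool_fwd(Z, w)
  list(vcontext = fw$out, alpha = fw$cache$a)
}

# ---- parameter initialization ---------------------------------------------

multibranch_params <- function(in_ch, width, seed = NULL) {
  with_local_seed(seed, list(
    pool.W = glorot(width, in_ch), pool.b = numeric(width),
    a1.W = glorot(width, in_ch * 3L), a1.b = numeric(width),
    a2.W = glorot(width, width * 3L), a2.b = numeric(width),
    c33.W = glorot(width, in_ch * 9L), c33.b = numeric(width),
    c11.W = glorot(width, in_ch), c11.b = numeric(width),
    res.W = glorot(4L * width, in_ch), res.b = numeric(4L * width)
  ))
}

prefix_names <- function(lst, pre) {
  names(lst) <- paste0(pre, names(lst))
  lst
}

#' Initialize a dual-stream SAD classifier
#'
#' @param config `network` block of [default_config()].
#' @param seed Seed governing every weight draw.
#' @param use_tfrim,use_time,use_demo Branch ablation flags; at least one of
#'   the signal branches or the demographic branch must remain.
#' @param fusion Demographic fusion head: `"dafm"` (affine modulation,
#'   default), `"concat"`, `"gate"` or `"bias"`.
#' @param tfrim_hw TFRIM grid `(H, W)`.
#' @param wave_len Waveform length (front end reduces it by 8x).
#' @return Object of class `sad_model`.
#' @export
init_sad_model <- function(config = default_config()$network, seed = 1L,
                           use_tfrim = TRUE, use_time = TRUE,
                           use_demo = TRUE,
                           fusion = c("dafm", "concat", "gate", "bias"),
                           tfrim_hw = c(24L, 48L), wave_len = 9120L) {
  fusion <- match.arg(fusion)
  if (!use_tfrim && !use_time && !use_demo) {
    abort("ablation leaves no input branch")
  }
  S <- as.integer(config$stem_channels)
  w1 <- as.integer(config$branch_width1)
  w2 <- as.integer(config$branch_width2)
  Dt <- as.integer(config$temporal_channels)
  Ns <- as.integer(config$state_size)
  dh <- as.integer(config$demo_hidden)
  hh <- as.integer(config$head_hidden)
  C2 <- 4L * w2
  red <- max(C2 %/% as.integer(config$cbam_reduction), 4L)
  c1 <- max(Dt %/% 2L, 4L)
  c2 <- max((3L * Dt) %/% 4L, 4L)
  Fdim <- 128L * (use_tfrim + use_time)

  params <- with_local_seed(seed, {
    p <- list()
    if (use_tfrim) {
      p <- c(p, list(tf.stem.W = glorot(S, 4L * 49L), tf.stem.b = numeric(S)))
      p <- c(p, prefix_names(multibranch_params(S, w1), "tf.mb1."))
      p <- c(p, prefix_names(multibranch_params(4L * w1, w2), "tf.mb2."))
      p <- c(p, list(
        tf.cbam.ca1.W = glorot(C2, red, fan_in = C2),
        tf.cbam.ca1.b = numeric(red),
        tf.cbam.ca2.W = glorot(red, C2, fan_in = red),
        tf.cbam.ca2.b = numeric(C2),
        tf.cbam.sp.W = glorot(1L, 2L * 49L), tf.cbam.sp.b = numeric(1L),
        tf.proj.W = glorot(C2, 128L, fan_in = C2), tf.proj.b = numeric(128L)
      ))
    }
    if (use_time) {
      p <- c(p, list(
        tm.conv1.W = glorot(c1, 2L * 7L), tm.conv1.b = numeric(c1),
        tm.conv2.W = glorot(c2, c1 * 5L), tm.conv2.b = numeric(c2),
        tm.conv3.W = glorot(Dt, c2 * 5L), tm.conv3.b = numeric(Dt),
        tm.ln.g = rep(1, Dt), tm.ln.b = numeric(Dt)
      ))
      p <- c(p, prefix_names(ssm_params(Dt, Ns), "tm.ssm."))
      p <- c(p, list(
        tm.attn.w = rnorm(Dt, 0, 1 / sqrt(Dt)),
        tm.proj.W = glorot(Dt, 128L, fan_in = Dt), tm.proj.b = numeric(128L)
      ))
    }
    head_in <- Fdim
    if (use_demo) {
      p <- c(p, list(
        dm.fc1.W = glorot(4L, dh[1], fan_in = 4L), dm.fc1.b = numeric(dh[1]),
        dm.fc2.W = glorot(dh[1], dh[2], fan_in = dh[1]),
        dm.fc2.b = numeric(dh[2]),
        dm.fc3.W = glorot(dh[2], dh[3], fan_in = dh[2]),
        dm.fc3.b = numeric(dh[3])
      ))
      if (Fdim == 0L) {
        head_in <- dh[3]                    # demographics-only: plain MLP
      } else if (fusion == "dafm") {
        # identity-initialized modulation: alpha = 1, beta = 0
        p <- c(p, list(dm.mod.W = matrix(0, dh[3], 2L * Fdim),
                       dm.mod.b = c(rep(1, Fdim), rep(0, Fdim))))
      } else if (fusion == "gate") {
        p <- c(p, list(dm.mod.W = matrix(0, dh[3], Fdim),
                       dm.mod.b = rep(2, Fdim)))   # sigmoid(2): gate ~ open
      } else if (fusion == "bias") {
        p <- c(p, list(dm.mod.W = matrix(0, dh[3], Fdim),
                       dm.mod.b = numeric(Fdim)))
      } else {                              # concat
        p <- c(p, list(dm.mod.W = glorot(dh[3], dh[3], fan_in = dh[3]),
                       dm.mod.b = numeric(dh[3])))
        head_in <- Fdim + dh[3]
      }
    }
    p <- c(p, list(
      head.fc1.W = glorot(head_in, hh, fan_in = head_in),
      head.fc1.b = numeric(hh),
      head.fc2.W = glorot(hh, 3L, fan_in = hh), head.fc2.b = numeric(3L)
    ))
    p
  })
  structure(list(
    params = params,
    meta = list(use_tfrim = use_tfrim, use_time = use_time,
                use_demo = use_demo, fusion = fusion,
                H = as.integer(tfrim_hw[1]), W = as.integer(tfrim_hw[2]),
                wave_len = as.integer(wave_len), stem = S, w1 = w1, w2 = w2,
                C2 = C2, red = red, Dt = Dt, Ns = Ns, c1 = c1, c2 = c2,
                dh = dh, Fdim = Fdim, dropout = config$dropout)
  ), class = "sad_model")
}

#' @export
print.sad_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  br <- c(if (x$meta$use_tfrim) "TFRIM", if (x$meta$use_time) "time-series",
          if (x$meta$use_demo) "demographics")
  cat(sprintf("<sad_model> branches: %s; fusion: %s; %d parameters\n",
              paste(br, collapse = " + "), x$meta$fusion, np))
  invisible(x)
}

# ---- multibranch block -----------------------------------------------------

#' Multi-branch convolution block
#'
#' Four parallel paths — 3x3 average pooling + 1x1 projection, a 3x1 then
#' 1x3 asymmetric pair, a 3x3 convolution, and a 1x1 convolution — are
#' concatenated along the channel axis and aggregated with a 1x1-projected
#' residual of the input (element-wise addition, stride 1, same padding),
#' then rectified.  Output channels = 4 x path width.
#'
#' @param x Input array `(C, H, W)` with `H, W >= 3`.
#' @param params List from [multibranch_params()].
#' @return Output array `(4 * width, H, W)`.
#' @export
multibranch_block <- function(x, params) {
  if (dim(x)[2] < 3 || dim(x)[3] < 3) {
    abort("multibranch block needs spatial dims >= 3x3")
  }
  mb_fwd(x, params, "")$out
}

#' @rdname multibranch_block
#' @param in_ch,width,seed Input channels, per-path width, seed.
#' @export
multibranch_params

get_p <- function(params, pre, nm) params[[paste0(pre, nm)]]

mb_fwd <- function(x, params, pre) {
  P <- function(nm) get_p(params, pre, nm)
  ap <- avgpool3_fwd(x)
  p1c <- conv2d_fwd(ap$out, P("pool.W"), P("pool.b"), 1L, 1L)
  p1r <- relu_fwd(p1c$out)
  a1c <- conv2d_fwd(x, P("a1.W"), P("a1.b"), 3L, 1L)
  a1r <- relu_fwd(a1c$out)
  a2c <- conv2d_fwd(a1r$out, P("a2.W"), P("a2.b"), 1L, 3L)
  a2r <- relu_fwd(a2c$out)
  c3c <- conv2d_fwd(x, P("c33.W"), P("c33.b"), 3L, 3L)
  c3r <- relu_fwd(c3c$out)
  c1c <- conv2d_fwd(x, P("c11.W"), P("c11.b"), 1L, 1L)
  c1r <- relu_fwd(c1c$out)
  w <- dim(p1r$out)[1]
  H <- dim(x)[2]; W <- dim(x)[3]
  cat <- array(0, dim = c(4L * w, H, W))
  cat[seq_len(w), , ] <- p1r$out
  cat[w + seq_len(w), , ] <- a2r$out
  cat[2L * w + seq_len(w), , ] <- c3r$out
  cat[3L * w + seq_len(w), , ] <- c1r$out
  res <- conv2d_fwd(x, P("res.W"), P("res.b"), 1L, 1L)
  outr <- relu_fwd(cat + res$out)
  list(out = outr$out,
       cache = list(ap = ap, p1c = p1c, p1r = p1r, a1c = a1c, a1r = a1r,
                    a2c = a2c, a2r = a2r, c3c = c3c, c3r = c3r, c1c = c1c,
                    c1r = c1r, res = res, outr = outr, w = w, dims = dim(x)))
}

mb_bwd <- function(dout, cache, pre) {
  g <- list()
  dsum <- relu_bwd(dout, cache$outr$cache)
  w <- cache$w
  bres <- conv2d_bwd(dsum, cache$res$cache)
  g[[paste0(pre, "res.W")]] <- bres$dW
  g[[paste0(pre, "res.b")]] <- bres$db
  dx <- bres$dx
  take <- function(k) {
    array(dsum[(k - 1L) * w + seq_len(w), , , drop = FALSE],
          dim = c(w, dim(dsum)[2], dim(dsum)[3]))
  }
  # pooling path
  b1 <- conv2d_bwd(relu_bwd(take(1), cache$p1r$cache), cache$p1c$cache)
  g[[paste0(pre, "pool.W")]] <- b1$dW
  g[[paste0(pre, "pool.b")]] <- b1$db
  dx <- dx + avgpool3_bwd(b1$dx, cache$ap$cache)
  # asymmetric path
  b2b <- conv2d_bwd(relu_bwd(take(2), cache$a2r$cache), cache$a2c$cache)
  g[[paste0(pre, "a2.W")]] <- b2b$dW
  g[[paste0(pre, "a2.b")]] <- b2b$db
  b2a <- conv2d_bwd(relu_bwd(b2b$dx, cache$a1r$cache), cache$a1c$cache)
  g[[paste0(pre, "a1.W")]] <- b2a$dW
  g[[paste0(pre, "a1.b")]] <- b2a$db
  dx <- dx + b2a$dx
  # 3x3 path
  b3 <- conv2d_bwd(relu_bwd(take(3), cache$c3r$cache), cache$c3c$cache)
  g[[paste0(pre, "c33.W")]] <- b3$dW
  g[[paste0(pre, "c33.b")]] <- b3$db
  dx <- dx + b3$dx
  # 1x1 path
  b4 <- conv2d_bwd(relu_bwd(take(4), cache$c1r$cache), cache$c1c$cache)
  g[[paste0(pre, "c11.W")]] <- b4$dW
  g[[paste0(pre, "c11.b")]] <- b4$db
  dx <- dx + b4$dx
  list(dx = dx, grads = g)
}

# ---- CBAM ------------------------------------------------------------------

cbam_fwd <- function(x, params) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  xm <- matrix(x, nrow = C)
  s_avg <- rowMeans(xm)
  imax <- max.col(xm, ties.method = "first")
  s_max <- xm[cbind(seq_len(C), imax)]
  mlp1 <- function(s) {
    h <- linear_fwd(matrix(s, 1L), params$tf.cbam.ca1.W, params$tf.cbam.ca1.b)
    hr <- relu_fwd(h$out)
    o <- linear_fwd(hr$out, params$tf.cbam.ca2.W, params$tf.cbam.ca2.b)
    list(out = as.vector(o$out), h = h, hr = hr, o = o)
  }
  pa <- mlp1(s_avg)
  pm <- mlp1(s_max)
  catt <- sigmoid(pa$out + pm$out)
  xc <- x * catt
  # spatial attention on the channel-refined map
  xcm <- matrix(xc, nrow = C)
  m_avg <- colMeans(xcm)
  jmax <- max.col(t(xcm), ties.method = "first")
  m_max <- xcm[cbind(jmax, seq_len(H * W))]
  sp_in <- array(0, dim = c(2L, H, W))
  sp_in[1, , ] <- m_avg
  sp_in[2, , ] <- m_max
  spc <- conv2d_fwd(sp_in, params$tf.cbam.sp.W, params$tf.cbam.sp.b, 7L, 7L)
  satt <- sigmoid(as.vector(spc$out))
  out <- xc * array(rep(satt, each = C), dim = dim(x))
  list(out = out,
       cache = list(x = x, xc = xc, catt = catt, satt = satt, pa = pa,
                    pm = pm, imax = imax, jmax = jmax, spc = spc,
                    C = C, H = H, W = W))
}

cbam_bwd <- function(dout, cache, params) {
  C <- cache$C; H <- cache$H; W <- cache$W
  satt_full <- array(rep(cache$satt, each = C), dim = dim(dout))
  dxc <- dout * satt_full
  dsatt <- colSums(matrix(dout * cache$xc, nrow = C))
  dspc <- dsatt * cache$satt * (1 - cache$satt)
  bsp <- conv2d_bwd(array(dspc, dim = c(1L, H, W)), cache$spc$cache)
  g <- list(tf.cbam.sp.W = bsp$dW, tf.cbam.sp.b = bsp$db)
  dsp_in <- bsp$dx
  # back through spatial avg/max summaries
  dxc <- dxc + array(rep(dsp_in[1, , ] / C, each = C), dim = dim(dout))
  dmax_sp <- as.vector(dsp_in[2, , ])
  dxcm <- matrix(0, C, H * W)
  dxcm[cbind(cache$jmax, seq_len(H * W))] <- dmax_sp
  dxc <- dxc + array(dxcm, dim = dim(dout))
  # channel attention
  dcatt <- rowSums(matrix(dxc * cache$x, nrow = C))
  dx <- dxc * cache$catt
  dsig <- dcatt * cache$catt * (1 - cache$catt)
  back_mlp <- function(p, dvec) {
    bo <- linear_bwd(matrix(dvec, 1L), p$o$cache)
    bh <- linear_bwd(relu_bwd(bo$dx, p$hr$cache), p$h$cache)
    list(ds = as.vector(bh$dx),
         g = list(tf.cbam.ca1.W = bh$dW, tf.cbam.ca1.b = bh$db,
                  tf.cbam.ca2.W = bo$dW, tf.cbam.ca2.b = bo$db))
  }
  ba <- back_mlp(cache$pa, dsig)
  bm <- back_mlp(cache$pm, dsig)
  g <- add_grads(g, add_grads(ba$g, bm$g))
  # avg-pool path gradient spreads uniformly; max path to argmax positions
  dx <- dx + array(ba$ds / (H * W), dim = dim(dx))
  dmaxm <- matrix(0, C, H * W)
  dmaxm[cbind(seq_len(C), cache$imax)] <- bm$ds
  dx <- dx + array(dmaxm, dim = dim(dx))
  list(dx = dx, grads = g)
}
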