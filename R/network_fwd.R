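# Full-model forward and backward passes.
#
# A batch is a list with `tfrim` (n x 2 x H x W), `wave` (n x 2 x 9120) and
# `demo` (n x 4), each already normalized; branches absent from the model may
# be NULL.  `forward_sad_model()` returns the three subtask probabilities;
# `backward_sad_model()` takes the logit gradient and returns gradients for
# every parameter, matching `model$params` by name.

tfrim_branch_fwd <- function(model, tfrim, training) {
  p <- model$params
  m <- model$meta
  n <- dim(tfrim)[1]
  if (dim(tfrim)[2] != 2L || dim(tfrim)[3] != m$H || dim(tfrim)[4] != m$W) {
    abort(sprintf("TFRIM batch must be (n, 2, %d, %d)", m$H, m$W))
  }
  pg <- positional_grid(m$H, m$W)
  pooled <- matrix(0, n, m$C2)
  caches <- vector("list", n)
  for (i in seq_len(n)) {
    x <- array(0, dim = c(4L, m$H, m$W))
    x[1:2, , ] <- tfrim[i, , , ]
    x[3:4, , ] <- pg
    st <- conv2d_fwd(x, p$tf.stem.W, p$tf.stem.b, 7L, 7L)
    str <- relu_fwd(st$out)
    b1 <- mb_fwd(str$out, p, "tf.mb1.")
    b2 <- mb_fwd(b1$out, p, "tf.mb2.")
    cb <- cbam_fwd(b2$out, p)
    pooled[i, ] <- rowMeans(matrix(cb$out, nrow = m$C2))
    caches[[i]] <- list(st = st, str = str, b1 = b1, b2 = b2, cb = cb)
  }
  pr <- linear_fwd(pooled, p$tf.proj.W, p$tf.proj.b)
  prr <- relu_fwd(pr$out)
  dr <- dropout_fwd(prr$out, m$dropout, training)
  list(out = dr$out,
       cache = list(caches = caches, pr = pr, prr = prr, dr = dr, n = n))
}

tfrim_branch_bwd <- function(model, dout, cache) {
  m <- model$meta
  g <- list()
  dd <- dropout_bwd(dout, cache$dr$cache)
  dpr <- relu_bwd(dd, cache$prr$cache)
  bl <- linear_bwd(dpr, cache$pr$cache)
  g$tf.proj.W <- bl$dW
  g$tf.proj.b <- bl$db
  HW <- m$H * m$W
  for (i in seq_len(cache$n)) {
    ci <- cache$caches[[i]]
    dpool <- array(rep(bl$dx[i, ] / HW, times = HW),
                   dim = c(m$C2, m$H, m$W))
    bc <- cbam_bwd(dpool, ci$cb$cache, model$params)
    g <- add_grads(g, bc$grads)
    b2 <- mb_bwd(bc$dx, ci$b2$cache, "tf.mb2.")
    g <- add_grads(g, b2$grads)
    b1 <- mb_bwd(b2$dx, ci$b1$cache, "tf.mb1.")
    g <- add_grads(g, b1$grads)
    dst <- relu_bwd(b1$dx, ci$str$cache)
    bs <- conv2d_bwd(dst, ci$st$cache)
    g <- add_grads(g, list(tf.stem.W = bs$dW, tf.stem.b = bs$db))
  }
  g
}

temporal_branch_fwd <- function(model, wave, training) {
  p <- model$params
  m <- model$meta
  n <- dim(wave)[1]
  if (dim(wave)[3] != m$wave_len) {
    abort(sprintf("waveform batch must have length %d", m$wave_len))
  }
  conv_caches <- vector("list", n)
  Lout <- NULL
  seqs <- NULL
  for (i in seq_len(n)) {
    x <- matrix(wave[i, , ], nrow = 2L)
    c1 <- conv1d_fwd(x, p$tm.conv1.W, p$tm.conv1.b, 7L, 2L)
    r1 <- relu_fwd(c1$out)
    c2 <- conv1d_fwd(r1$out, p$tm.conv2.W, p$tm.conv2.b, 5L, 2L)
    r2 <- relu_fwd(c2$out)
    c3 <- conv1d_fwd(r2$out, p$tm.conv3.W, p$tm.conv3.b, 5L, 2L)
    r3 <- relu_fwd(c3$out)
    if (is.null(Lout)) {
      Lout <- ncol(r3$out)
      seqs <- array(0, dim = c(Lout, n, m$Dt))
    }
    seqs[, i, ] <- t(r3$out)
    conv_caches[[i]] <- list(c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                             c3 = c3, r3 = r3)
  }
  # pre-norm residual SSM block: Z = SSM(LN(F)) + F
  flat <- matrix(seqs, nrow = Lout * n)
  ln <- layernorm_fwd(flat, p$tm.ln.g, p$tm.ln.b)
  ssm_in <- array(ln$out, dim = c(Lout, n, m$Dt))
  sc <- ssm_batch_fwd(ssm_in, list(A = p$tm.ssm.A, W_delta = p$tm.ssm.W_delta,
                                   b_delta = p$tm.ssm.b_delta,
                                   W_b = p$tm.ssm.W_b, W_c = p$tm.ssm.W_c,
                                   Dskip = p$tm.ssm.Dskip))
  Z <- sc$out + seqs
  v <- matrix(0, n, m$Dt)
  at_caches <- vector("list", n)
  for (i in seq_len(n)) {
    aw <- attnpool_fwd(matrix(Z[, i, ], Lout, m$Dt), p$tm.attn.w)
    v[i, ] <- aw$out
    at_caches[[i]] <- aw$cache
  }
  pr <- linear_fwd(v, p$tm.proj.W, p$tm.proj.b)
  prr <- relu_fwd(pr$out)
  dr <- dropout_fwd(prr$out, m$dropout, training)
  list(out = dr$out,
       cache = list(conv = conv_caches, ln = ln, sc = sc, at = at_caches,
                    pr = pr, prr = prr, dr = dr, n = n, Lout = Lout))
}

temporal_branch_bwd <- function(model, dout, cache) {
  p <- model$params
  m <- model$meta
  n <- cache$n
  Lout <- cache$Lout
  g <- list()
  dd <- dropout_bwd(dout, cache$dr$cache)
  dpr <- relu_bwd(dd, cache$prr$cache)
  bl <- linear_bwd(dpr, cache$pr$cache)
  g$tm.proj.W <- bl$dW
  g$tm.proj.b <- bl$db
  dZ <- array(0, dim = c(Lout, n, m$Dt))
  dw_attn <- numeric(m$Dt)
  for (i in seq_len(n)) {
    ba <- attnpool_bwd(bl$dx[i, ], cache$at[[i]])
    dZ[, i, ] <- ba$dZ
    dw_attn <- dw_attn + ba$dw
  }
  g$tm.attn.w <- dw_attn
  bs <- ssm_batch_bwd(dZ, cache$sc$cache)
  g <- add_grads(g, prefix_names(bs$grads, "tm.ssm."))
  dflat <- matrix(bs$dx, nrow = Lout * n)
  bln <- layernorm_bwd(dflat, cache$ln$cache)
  g$tm.ln.g <- bln$dg
  g$tm.ln.b <- bln$db
  dseqs <- array(bln$dx, dim = c(Lout, n, m$Dt)) + dZ  # residual path
  for (i in seq_len(n)) {
    ci <- cache$conv[[i]]
    dr3 <- relu_bwd(t(matrix(dseqs[, i, ], Lout, m$Dt)), ci$r3$cache)
    b3 <- conv1d_bwd(dr3, ci$c3$cache)
    b2 <- conv1d_bwd(relu_bwd(b3$dx, ci$r2$cache), ci$c2$cache)
    b1 <- conv1d_bwd(relu_bwd(b2$dx, ci$r1$cache), ci$c1$cache)
    g <- add_grads(g, list(tm.conv3.W = b3$dW, tm.conv3.b = b3$db,
                           tm.conv2.W = b2$dW, tm.conv2.b = b2$db,
                           tm.conv1.W = b1$dW, tm.conv1.b = b1$db))
  }
  g
}

demo_trunk_fwd <- function(model, demo) {
  p <- model$params
  f1 <- linear_fwd(demo, p$dm.fc1.W, p$dm.fc1.b)
  r1 <- relu_fwd(f1$out)
  f2 <- linear_fwd(r1$out, p$dm.fc2.W, p$dm.fc2.b)
  r2 <- relu_fwd(f2$out)
  f3 <- linear_fwd(r2$out, p$dm.fc3.W, p$dm.fc3.b)
  r3 <- relu_fwd(f3$out)
  list(out = r3$out, cache = list(f1 = f1, r1 = r1, f2 = f2, r2 = r2,
                                  f3 = f3, r3 = r3))
}

demo_trunk_bwd <- function(dout, cache) {
  b3 <- linear_bwd(relu_bwd(dout, cache$r3$cache), cache$f3$cache)
  b2 <- linear_bwd(relu_bwd(b3$dx, cache$r2$cache), cache$f2$cache)
  b1 <- linear_bwd(relu_bwd(b2$dx, cache$r1$cache), cache$f1$cache)
  list(dx = b1$dx,
       grads = list(dm.fc3.W = b3$dW, dm.fc3.b = b3$db,
                    dm.fc2.W = b2$dW, dm.fc2.b = b2$db,
                    dm.fc1.W = b1$dW, dm.fc1.b = b1$db))
}

#' Forward pass of the dual-stream classifier
#'
#' @param model A [init_sad_model()].
#' @param batch List with normalized `tfrim` (n x 2 x H x W), `wave`
#'   (n x 2 x L) and `demo` (n x 4); branches the model was built without
#'   may be `NULL`.
#' @param training Enable dropout (training mode).
#' @return List with `prob` (n x 3 subtask probabilities), `logits`, and a
#'   `cache` for [backward_sad_model()].
#' @export
forward_sad_model <- function(model, batch, training = FALSE) {
  p <- model$params
  m <- model$meta
  feats <- NULL
  tf_c <- tm_c <- NULL
  if (m$use_tfrim) {
    tf <- tfrim_branch_fwd(model, batch$tfrim, training)
    feats <- tf$out
    tf_c <- tf$cache
  }
  if (m$use_time) {
    tm <- temporal_branch_fwd(model, batch$wave, training)
    feats <- if (is.null(feats)) tm$out else cbind(feats, tm$out)
    tm_c <- tm$cache
  }
  dm_c <- NULL
  mod_c <- NULL
  if (m$use_demo) {
    dtr <- demo_trunk_fwd(model, batch$demo)
    dm_c <- dtr$cache
    if (m$Fdim == 0L) {
      xmod <- dtr$out                       # demographics-only MLP
    } else {
      mod <- linear_fwd(dtr$out, p$dm.mod.W, p$dm.mod.b)
      mod_c <- mod
      if (m$fusion == "dafm") {
        alpha <- mod$out[, seq_len(m$Fdim), drop = FALSE]
        beta <- mod$out[, m$Fdim + seq_len(m$Fdim), drop = FALSE]
        xmod <- alpha * feats + beta
        mod_c$alpha <- alpha
      } else if (m$fusion == "gate") {
        gt <- sigmoid(mod$out)
        xmod <- feats * gt
        mod_c$gate <- gt
      } else if (m$fusion == "bias") {
        xmod <- feats + mod$out
      } else {
        xmod <- cbind(feats, mod$out)
      }
    }
  } else {
    xmod <- feats
  }
  h1 <- linear_fwd(xmod, p$head.fc1.W, p$head.fc1.b)
  h1r <- relu_fwd(h1$out)
  h2 <- linear_fwd(h1r$out, p$head.fc2.W, p$head.fc2.b)
  prob <- sigmoid(h2$out)
  list(prob = prob, logits = h2$out,
       cache = list(tf = tf_c, tm = tm_c, dm = dm_c, mod = mod_c,
                    feats = feats, h1 = h1, h1r = h1r, h2 = h2))
}

#' Backward pass of the dual-stream classifier
#'
#' @param model A [init_sad_model()].
#' @param dlogits Gradient of the loss with respect to the logits (n x 3).
#' @param cache Cache from [forward_sad_model()].
#' @return Named list of parameter gradients aligned with `model$params`.
#' @export
backward_sad_model <- function(model, dlogits, cache) {
  p <- model$params
  m <- model$meta
  g <- list()
  b2 <- linear_bwd(dlogits, cache$h2$cache)
  g$head.fc2.W <- b2$dW
  g$head.fc2.b <- b2$db
  b1 <- linear_bwd(relu_bwd(b2$dx, cache$h1r$cache), cache$h1$cache)
  g$head.fc1.W <- b1$dW
  g$head.fc1.b <- b1$db
  dxmod <- b1$dx

  dfeats <- NULL
  if (m$use_demo) {
    if (m$Fdim == 0L) {
      bd <- demo_trunk_bwd(dxmod, cache$dm)
      g <- add_grads(g, bd$grads)
    } else {
      if (m$fusion == "dafm") {
        alpha <- cache$mod$alpha
        beta_g <- dxmod
        dalpha <- dxmod * cache$feats
        dfeats <- dxmod * alpha
        dmod <- cbind(dalpha, beta_g)
      } else if (m$fusion == "gate") {
        gt <- cache$mod$gate
        dfeats <- dxmod * gt
        dmod <- dxmod * cache$feats * gt * (1 - gt)
      } else if (m$fusion == "bias") {
        dfeats <- dxmod
        dmod <- dxmod
      } else {
        dfeats <- dxmod[, seq_len(m$Fdim), drop = FALSE]
        dmod <- dxmod[, m$Fdim + seq_len(ncol(cache$mod$out)), drop = FALSE]
      }
      bm <- linear_bwd(dmod, cache$mod$cache)
      g$dm.mod.W <- bm$dW
      g$dm.mod.b <- bm$db
      bd <- demo_trunk_bwd(bm$dx, cache$dm)
      g <- add_grads(g, bd$grads)
    }
  } else {
    dfeats <- dxmod
  }
  if (!is.null(dfeats)) {
    off <- 0L
    if (m$use_tfrim) {
      g <- add_grads(g, tfrim_branch_bwd(
        model, dfeats[, off + seq_len(128L), drop = FALSE], cache$tf))
      off <- off + 128L
    }
    if (m$use_time) {
      g <- add_grads(g, temporal_branch_bwd(
        model, dfeats[, off + seq_len(128L), drop = FALSE], cache$tm))
    }
  }
  g
}

#' Encode a batch of TFRIM tensors to 128-d features
#'
#' Evaluation-mode convenience wrapper around the TFRIM branch.
#'
#' @param model A [init_sad_model()] built with the TFRIM branch.
#' @param tfrim Normalized array `(n, 2, H, W)`.
#' @return `n x 128` feature matrix.
#' @export
tfrim_encode <- function(model, tfrim) {
  if (!model$meta$use_tfrim) abort("model was built without the TFRIM branch")
  tfrim_branch_fwd(model, tfrim, training = FALSE)$out
}

#' Encode a batch of waveform pairs to 128-d features
#'
#' @param model A [init_sad_model()] built with the temporal branch.
#' @param wave Normalized array `(n, 2, L)` (z-scored pressure/flow).
#' @return `n x 128` feature matrix.
#' @export
temporal_encode <- function(model, wave) {
  if (!model$meta$use_time) abort("model was built without the temporal branch")
  temporal_branch_fwd(model, wave, training = FALSE)$out
}

#' Demographics-driven adaptive feature modulation
#'
#' Maps the standardized demographic vector through the three-hidden-layer
#' MLP to a `2F`-dimensional projection split into a scale `alpha` and shift
#' `beta` (each `F`-dimensional, `alpha` unconstrained over the reals), and
#' returns `alpha * xfused + beta`.
#'
#' @param model A [init_sad_model()] with `fusion = "dafm"`.
#' @param xfused `n x F` fused feature matrix.
#' @param demo `n x 4` standardized demographics (age, sex, height, weight).
#' @return `n x F` calibrated features.
#' @export
dafm <- function(model, xfused, demo) {
  m <- model$meta
  if (!m$use_demo || m$fusion != "dafm") {
    abort("model has no DAFM fusion head")
  }
  if (ncol(xfused) != m$Fdim) {
    abort(sprintf("xfused must have %d columns", m$Fdim))
  }
  tr <- demo_trunk_fwd(model, demo)
  mod <- linear_fwd(tr$out, model$params$dm.mod.W, model$params$dm.mod.b)
  alpha <- mod$out[, seq_len(m$Fdim), drop = FALSE]
  beta <- mod$out[, m$Fdim + seq_len(m$Fdim), drop = FALSE]
  alpha * xfused + beta
}

#' Classification head
#'
#' One shared MLP mapping the calibrated feature vector to three logits
#' (ordered FEF25-75, FEF50, FEF75), squashed element-wise by the sigmoid.
#'
#' @param model A [init_sad_model()].
#' @param xmod Calibrated feature matrix (n x head input dim).
#' @return `n x 3` probabilities in (0, 1).
#' @export
classify <- function(model, xmod) {
  p <- model$params
  h <- relu_fwd(linear_fwd(xmod, p$head.fc1.W, p$head.fc1.b)$out)$out
  sigmoid(linear_fwd(h, p$head.fc2.W, p$head.fc2.b)$out)
}
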