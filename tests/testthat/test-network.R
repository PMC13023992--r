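# Network components: positional encoding, multibranch block, selective SSM,
# attention pooling, DAFM, heads, ablation routing and gradient sanity.

test_that("positional grid hits its normalization endpoints and is monotone", {
  g <- positional_grid(24, 48)
  expect_equal(dim(g), c(2, 24, 48))
  expect_equal(g[1, 1, 1], 0)
  expect_equal(g[2, 1, 1], 0)
  expect_equal(g[1, 24, 48], 1)
  expect_equal(g[2, 24, 48], 1)
  expect_true(all(diff(g[1, , 1]) > 0))
  expect_true(all(diff(g[2, 1, ]) > 0))
  expect_true(all(positional_grid(1, 5)[1, , ] == 0))   # single-row convention
})

test_that("multibranch block obeys its shape algebra and linearity at init", {
  set.seed(11)
  pp <- multibranch_params(3L, 4L)
  x <- array(rnorm(3 * 6 * 8), c(3, 6, 8))
  out <- multibranch_block(x, pp)
  expect_equal(dim(out), c(16, 6, 8))               # 4 x per-path width
  # zero input with zero biases -> zero output (paths are linear maps there)
  expect_true(all(multibranch_block(array(0, c(3, 6, 8)), pp) == 0))
  expect_error(multibranch_block(array(0, c(3, 2, 8)), pp), "3x3")
})

test_that("gradient reaches the input through the residual path alone", {
  set.seed(12)
  pp <- multibranch_params(2L, 2L)
  for (nm in c("pool.W", "a1.W", "a2.W", "c33.W", "c11.W")) pp[[nm]][] <- 0
  x <- array(rnorm(2 * 5 * 5), c(2, 5, 5))
  fw <- tfrimsad:::mb_fwd(x, pp, "")
  dout <- array(1, dim(fw$out))
  bw <- tfrimsad:::mb_bwd(dout, fw$cache, "")
  expect_gt(sum(abs(bw$dx)), 0)
  # finite-difference agreement through the residual
  eps <- 1e-6
  i <- 7
  x2 <- x; x2[i] <- x[i] + eps
  x3 <- x; x3[i] <- x[i] - eps
  num <- (sum(tfrimsad:::mb_fwd(x2, pp, "")$out) -
            sum(tfrimsad:::mb_fwd(x3, pp, "")$out)) / (2 * eps)
  expect_equal(num, bw$dx[i], tolerance = 1e-5)
})

test_that("ZOH discretization matches the scalar closed form and its limits", {
  d <- ssm_discretize(-1, 1, 0.1)
  expect_equal(d$Abar, exp(-0.1), tolerance = 1e-12)      # 0.904837
  expect_equal(d$Abar, 0.904837, tolerance = 1e-5)
  expect_equal(d$bbar, (exp(-0.1) - 1) / (-1), tolerance = 1e-12)
  expect_equal(d$bbar, 0.095163, tolerance = 1e-5)
  # removable singularity at a = 0
  d0 <- ssm_discretize(0, 2, 0.5)
  expect_equal(d0$Abar, 1)
  expect_equal(d0$bbar, 1.0)
  # first-order ZOH limit as Delta -> 0
  dl <- ssm_discretize(-1, 1, 1e-8)
  expect_equal(dl$Abar, 1, tolerance = 1e-7)
  expect_equal(dl$bbar, 1e-8, tolerance = 1e-7)
  expect_error(ssm_discretize(-1, 1, 0), "positive")
})

test_that("fixed-parameter scan reproduces the hand recurrence", {
  p <- list(A = matrix(-1, 1, 1), Dskip = 0)
  y <- selective_ssm_scan(matrix(c(1, 0, 0), 3, 1), p,
                          fixed = list(delta = 0.1, b = 1, c = 1))
  # oracle: h1 = bbar = 1 - e^(-0.1); h_{t+1} = e^(-0.1) h_t; y_t = h_t
  h1 <- (exp(-0.1) - 1) / (-1)
  expect_equal(as.vector(y), h1 * exp(-0.1)^(0:2), tolerance = 1e-12)
  expect_equal(as.vector(y), c(0.0951626, 0.0861066, 0.0779124),
               tolerance = 1e-6)
  # zero input stays at zero
  y0 <- selective_ssm_scan(matrix(0, 5, 1), p,
                           fixed = list(delta = 0.1, b = 1, c = 1))
  expect_true(all(y0 == 0))
})

test_that("selective scan agrees with a naive step-by-step loop oracle", {
  set.seed(13)
  D <- 3L; N <- 4L; L <- 32L
  p <- ssm_params(D, N, seed = 99)
  x <- matrix(rnorm(L * D), L, D)
  y_pkg <- selective_ssm_scan(x, p)
  y_orc <- oracle_scan_selective(x, p)
  expect_lt(max(abs(y_pkg - y_orc)), 1e-5)
  # the batched training path matches the single-sequence scan
  X <- array(0, c(L, 2L, D))
  x2 <- matrix(rnorm(L * D), L, D)
  X[, 1, ] <- x
  X[, 2, ] <- x2
  Y <- tfrimsad:::ssm_batch_fwd(X, p)$out
  expect_lt(max(abs(Y[, 1, ] - y_pkg)), 1e-10)
  expect_lt(max(abs(Y[, 2, ] - selective_ssm_scan(x2, p))), 1e-10)
})

test_that("attention pooling is a convex weighting", {
  set.seed(14)
  Z <- matrix(rnorm(20 * 6), 20, 6)
  w <- rnorm(6)
  ap <- attention_pool(Z, w)
  expect_true(all(ap$alpha >= 0))
  expect_equal(sum(ap$alpha), 1, tolerance = 1e-6)
  # constant sequence: pooled vector equals the constant, any w
  cz <- matrix(rep(1:6, each = 20), 20, 6)
  expect_equal(attention_pool(cz, w)$vcontext, 1:6, tolerance = 1e-12,
               ignore_attr = TRUE)
  # zero scores: uniform weights, plain mean
  expect_equal(attention_pool(Z, rep(0, 6))$vcontext, colMeans(Z),
               tolerance = 1e-12)
})

test_that("branch encoders emit 128-d features deterministically in eval mode", {
  cfg <- tiny_network_config()
  model <- init_sad_model(cfg, seed = 3, tfrim_hw = c(24, 48), wave_len = 9120)
  set.seed(15)
  tfr <- array(rnorm(2 * 2 * 24 * 48), c(2, 2, 24, 48))
  xt <- tfrim_encode(model, tfr)
  expect_equal(dim(xt), c(2, 128))
  expect_identical(xt, tfrim_encode(model, tfr))    # eval-mode repeatability
  # swapping resistance and reactance channels changes the encoding
  swapped <- tfr[, 2:1, , , drop = FALSE]
  expect_false(isTRUE(all.equal(xt, tfrim_encode(model, swapped))))
  # shuffling time columns changes the encoding (position encoding active)
  shuf <- tfr[, , , sample(48), drop = FALSE]
  expect_false(isTRUE(all.equal(xt, tfrim_encode(model, shuf))))
})

test_that("temporal front end downsamples 9120 samples to a 1140-step sequence", {
  cfg <- tiny_network_config()
  model <- init_sad_model(cfg, seed = 4, use_tfrim = FALSE, use_demo = FALSE,
                          wave_len = 9120)
  set.seed(16)
  wave <- array(rnorm(1 * 2 * 9120, 0, 1), c(1, 2, 9120))
  fw <- tfrimsad:::temporal_branch_fwd(model, wave, FALSE)
  expect_equal(fw$cache$Lout, 1140)                 # three stride-2 stages
  expect_equal(dim(fw$out), c(1, 128))
  expect_error(temporal_encode(model, array(0, c(1, 2, 1000))), "9120")
})

test_that("DAFM is identity at initialization and affine in the features", {
  cfg <- tiny_network_config()
  model <- init_sad_model(cfg, seed = 5, tfrim_hw = c(6, 8), wave_len = 64)
  Fd <- model$meta$Fdim
  expect_equal(Fd, 256L)
  set.seed(17)
  d <- matrix(rnorm(3 * 4), 3, 4)
  x1 <- matrix(rnorm(3 * Fd), 3, Fd)
  x2 <- matrix(rnorm(3 * Fd), 3, Fd)
  # identity-initialized final layer: alpha = 1, beta = 0
  expect_equal(dafm(model, x1, d), x1, tolerance = 1e-12)
  # affine identity for arbitrary modulation weights
  model$params$dm.mod.W <- matrix(rnorm(length(model$params$dm.mod.W), 0, 0.2),
                                  nrow(model$params$dm.mod.W))
  lhs <- dafm(model, x1 + x2, d) + dafm(model, 0 * x1, d)
  rhs <- dafm(model, x1, d) + dafm(model, x2, d)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_equal(ncol(dafm(model, x1, d)), 256L)
})

test_that("the classification head is a sigmoid over three shared-trunk logits", {
  cfg <- tiny_network_config()
  model <- init_sad_model(cfg, seed = 6, tfrim_hw = c(6, 8), wave_len = 64)
  hd <- model$meta$Fdim
  set.seed(18)
  x <- matrix(rnorm(4 * hd), 4, hd)
  pr <- classify(model, x)
  expect_equal(dim(pr), c(4, 3))
  expect_true(all(pr > 0 & pr < 1))
  # zero logits map to one half
  model$params$head.fc2.W[] <- 0
  model$params$head.fc2.b[] <- 0
  expect_true(all(classify(model, x) == 0.5))
})

test_that("branch ablations route correctly and empty ablation is rejected", {
  cfg <- tiny_network_config()
  set.seed(19)
  demo <- matrix(rnorm(3 * 4), 3, 4)
  wave <- array(rnorm(3 * 2 * 64), c(3, 2, 64))
  tfr <- array(rnorm(3 * 2 * 6 * 8), c(3, 2, 6, 8))
  # demographics only: a plain MLP classifier
  m_demo <- init_sad_model(cfg, seed = 7, use_tfrim = FALSE, use_time = FALSE)
  fw <- forward_sad_model(m_demo, list(demo = demo))
  expect_equal(dim(fw$prob), c(3, 3))
  # signal branches without demographics: fused features go straight to the head
  m_sig <- init_sad_model(cfg, seed = 8, use_demo = FALSE, tfrim_hw = c(6, 8),
                          wave_len = 64)
  expect_false("dm.mod.W" %in% names(m_sig$params))
  fw2 <- forward_sad_model(m_sig, list(tfrim = tfr, wave = wave))
  expect_equal(dim(fw2$prob), c(3, 3))
  expect_error(init_sad_model(cfg, use_tfrim = FALSE, use_time = FALSE,
                              use_demo = FALSE), "no input branch")
  # alternative fusion heads run forward
  for (fus in c("concat", "gate", "bias")) {
    mf <- init_sad_model(cfg, seed = 9, fusion = fus, tfrim_hw = c(6, 8),
                         wave_len = 64)
    fwf <- forward_sad_model(mf, list(tfrim = tfr, wave = wave, demo = demo))
    expect_equal(dim(fwf$prob), c(3, 3))
  }
})

test_that("seeded initialization is reproducible", {
  cfg <- tiny_network_config()
  a <- init_sad_model(cfg, seed = 21, tfrim_hw = c(6, 8), wave_len = 64)
  b <- init_sad_model(cfg, seed = 21, tfrim_hw = c(6, 8), wave_len = 64)
  expect_identical(a$params, b$params)
  c <- init_sad_model(cfg, seed = 22, tfrim_hw = c(6, 8), wave_len = 64)
  expect_false(identical(a$params, c$params))
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_network_config()
  model <- init_sad_model(cfg, seed = 2, tfrim_hw = c(6, 8), wave_len = 64)
  # jitter parameters away from exact ReLU kinks created by zero-init biases
  set.seed(23)
  model$params <- lapply(model$params,
                         function(p) p + rnorm(length(p), 0, 0.01))
  n <- 2
  batch <- list(tfrim = array(rnorm(n * 2 * 6 * 8), c(n, 2, 6, 8)),
                wave = array(rnorm(n * 2 * 64), c(n, 2, 64)),
                demo = matrix(rnorm(n * 4), n, 4))
  y <- matrix(runif(n * 3), n, 3)
  lossfn <- function(m) bce_loss(forward_sad_model(m, batch)$prob, y)
  fw <- forward_sad_model(model, batch)
  grads <- backward_sad_model(model, (fw$prob - y) / (3 * n), fw$cache)
  eps <- 1e-5
  set.seed(24)
  for (nm in names(grads)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      m2 <- model; m2$params[[nm]][i] <- p[i] + eps
      m3 <- model; m3$params[[nm]][i] <- p[i] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      ana <- grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})
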