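# Normalization, loss, folds, metrics and the training loop.

# small in-memory cohort shared by the tests below (built once per file)
local_cohort <- local({
  env <- new.env()
  function(n = 14, seed = 33) {
    key <- paste(n, seed)
    if (is.null(env[[key]])) {
      coh <- generate_cohort(n, sad_fraction = 0.5, seed = seed)
      env[[key]] <- prepare_dataset(coh$manifest,
                                    recordings = coh$recordings)
    }
    env[[key]]
  }
})

test_that("z-score statistics come from the training portion only", {
  ds <- local_cohort()
  train_idx <- 1:10
  stats <- zscore_fit(ds, train_idx)
  norm <- zscore_apply(stats, ds, train_idx)
  # self-normalization of the training portion
  for (c in 1:2) {
    expect_lt(abs(mean(norm$wave[, c, ])), 1e-6)
    expect_equal(sd(as.vector(norm$wave[, c, ])), 1, tolerance = 1e-2)
    expect_lt(abs(mean(norm$tfrim[, c, , ])), 1e-6)
  }
  expect_true(all(abs(colMeans(norm$demo)) < 1e-9))
  # freeze contract: mutating held-out subjects never changes the statistics
  ds_mut <- ds
  ds_mut$wave[11:14, , ] <- ds_mut$wave[11:14, , ] * 100 + 5
  ds_mut$tfrim[11:14, , , ] <- -99
  ds_mut$demo[11:14, ] <- 1e6
  stats_mut <- zscore_fit(ds_mut, train_idx)
  expect_identical(stats, stats_mut)
  # and the normalized training values are untouched
  norm_mut <- zscore_apply(stats_mut, ds_mut, train_idx)
  expect_identical(norm, norm_mut)
})

test_that("constant channels are floored with a warning", {
  ds <- local_cohort()
  ds$demo[, 2] <- 1   # constant sex column
  expect_warning(stats <- zscore_fit(ds, 1:10), "floored")
  norm <- zscore_apply(stats, ds, 1:10)
  expect_true(all(is.finite(norm$demo)))
  expect_true(all(abs(norm$demo[, 2]) < 1e-6))
})

test_that("BCE loss reproduces its closed forms", {
  expect_equal(bce_loss(c(0.5, 0.5, 0.5), c(0.1, 0.7, 0.9)), log(2),
               tolerance = 1e-12)
  expect_equal(bce_loss(c(1, 1, 1), c(1, 1, 1)), 0, tolerance = 1e-6)
  # perfect soft prediction attains the binary entropy of the target
  y <- 1 / (1 + exp(-3))                      # 0.952574
  H <- -(y * log(y) + (1 - y) * log(1 - y))   # 0.190865
  expect_equal(bce_loss(rep(y, 3), rep(y, 3)), H, tolerance = 1e-9)
  expect_equal(H, 0.190865, tolerance = 1e-6)
  expect_gt(bce_loss(c(0.9, 0.9, 0.9), c(0.1, 0.1, 0.1)), 0)
  expect_error(bce_loss(matrix(0.5, 2, 3), matrix(0.5, 3, 3)), "shapes")
})

test_that("stratified folds are balanced, exhaustive and reproducible", {
  y <- rep(c(0L, 1L), c(58, 42))
  f <- kfold_split(y, k = 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 100)                     # every subject exactly once
  expect_true(all(abs(table(f) - 20) <= 1))
  # per-fold SAD fraction within one subject of 42%
  sad_per_fold <- tapply(y, f, sum)
  expect_true(all(abs(sad_per_fold - 42 / 5) <= 1))
  expect_identical(f, kfold_split(y, k = 5, seed = 3))
  expect_false(identical(f, kfold_split(y, k = 5, seed = 4)))
  # n = 10, k = 5: every fold has exactly two subjects
  f10 <- kfold_split(rep(0:1, 5), k = 5, seed = 1)
  expect_true(all(table(f10) == 2))
  # a stratum smaller than k falls back with a warning
  expect_warning(kfold_split(c(rep(0L, 9), 1L), k = 5, seed = 1), "stratum")
  expect_error(kfold_split(1:3, k = 5), "at least")
})

test_that("metric suite matches direct confusion-matrix arithmetic", {
  # TP=3, FN=1, TN=4, FP=2 over ten subjects
  y <- c(rep(1L, 4), rep(0L, 6))
  pred_main <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  prob <- cbind(pred_main, pred_main, pred_main) * 0.8 + 0.1
  abn <- cbind(y, y, y)
  mt <- evaluate_predictions(prob, y, abn)
  sad <- mt[mt$task == "SAD", ]
  expect_equal(sad$sensitivity, 0.75)
  expect_equal(sad$specificity, 2 / 3, tolerance = 1e-9)
  expect_equal(sad$precision, 0.6)
  expect_equal(sad$accuracy, 0.7)
  expect_equal(sad$f1, 2 / 3, tolerance = 1e-9)
  # F1 consistency with precision/recall recomputed independently
  expect_equal(sad$f1, 2 * sad$precision * sad$sensitivity /
                 (sad$precision + sad$sensitivity))
  # perfect predictions
  perf <- evaluate_predictions(cbind(y, y, y) * 0.98 + 0.01, y, abn)
  expect_true(all(perf[perf$task == "SAD",
                       c("accuracy", "sensitivity", "specificity",
                         "precision", "f1")] == 1))
  # all-negative predictions: sensitivity 0, precision undefined
  neg <- evaluate_predictions(matrix(0.1, 10, 3), y, abn)
  expect_equal(neg$sensitivity[neg$task == "SAD"], 0)
  expect_true(is.na(neg$precision[neg$task == "SAD"]))
})

test_that("a tiny model overfits a fixed batch (loss decreases over 50 steps)", {
  cfg <- tiny_network_config()
  model <- init_sad_model(cfg, seed = 41, use_tfrim = FALSE, use_time = FALSE)
  set.seed(42)
  demo <- matrix(rnorm(8 * 4), 8, 4)
  y <- matrix(rep(c(0.9, 0.1), each = 4 * 3), 8, 3)
  state <- tfrimsad:::adam_init(model$params)
  loss0 <- bce_loss(forward_sad_model(model, list(demo = demo))$prob, y)
  for (step in 1:50) {
    fw <- forward_sad_model(model, list(demo = demo), training = TRUE)
    dlog <- (fw$prob - y) / (3 * nrow(y))
    g <- backward_sad_model(model, dlog, fw$cache)
    upd <- tfrimsad:::adam_step(model$params, g, state, 1e-2)
    model$params <- upd$params
    state <- upd$state
  }
  loss1 <- bce_loss(forward_sad_model(model, list(demo = demo))$prob, y)
  expect_lt(loss1, loss0 * 0.5)
})

test_that("train_fold runs a smoke fit, returns history and is seed-deterministic", {
  ds <- local_cohort()
  cfg <- reduced_pipeline_config()
  cfg$training$max_epochs <- 2L   # configured batch exceeds the cohort: warns
  model <- init_sad_model(tiny_network_config(), seed = 51,
                          tfrim_hw = dim(ds$tfrim)[3:4],
                          wave_len = dim(ds$wave)[3])
  expect_warning(
    fit <- train_fold(ds, 1:12, model, cfg$training, seed = 5),
    "batch size")
  expect_s3_class(fit$history, "tbl_df")
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$train_loss)))
  # identical seed and data give identical weights
  model2 <- init_sad_model(tiny_network_config(), seed = 51,
                           tfrim_hw = dim(ds$tfrim)[3:4],
                           wave_len = dim(ds$wave)[3])
  suppressWarnings(fit2 <- train_fold(ds, 1:12, model2, cfg$training, seed = 5))
  expect_identical(fit$model$params, fit2$model$params)
  # prediction surface: one row per subject with votes and decision
  pred <- predict(fit$model, ds, fit$stats, idx = 13:14)
  expect_equal(nrow(pred), 2)
  expect_true(all(c("p_fef2575", "vote1", "decision", "S_pred") %in%
                    names(pred)))
  expect_true(all(pred$S_pred >= 0 & pred$S_pred <= 1))
})
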