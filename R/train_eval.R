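# Training protocol and evaluation.
#
# Soft-label multi-label BCE, Adam (initial lr 1e-4) with cosine annealing,
# early stopping on an inner validation split, and stratified k-fold
# cross-validation with fold-local (leakage-safe) z-score normalization.

#' Assemble a model-ready dataset from a cohort
#'
#' Builds the TFRIM tensors, crops/stacks the raw waveform pairs, extracts
#' the demographic matrix and constructs hard/soft labels from the manifest.
#'
#' @param manifest Manifest tibble ([read_manifest()] schema).
#' @param recordings Optional in-memory recording list (manifest order);
#'   otherwise `recording_path` is read.
#' @param config Full pipeline configuration ([default_config()]).
#' @return Object of class `sad_dataset`: arrays `tfrim` (n,2,H,W), `wave`
#'   (n,2,L), matrix `demo` (n,4: age, sex, height, weight), `y_hard`,
#'   `y_soft` (n,3), `abnormal` (n,3 hard per-index abnormality), manifest.
#' @export
prepare_dataset <- function(manifest, recordings = NULL,
                            config = default_config()) {
  n <- nrow(manifest)
  store <- build_cohort_tfrim(manifest, recordings, config$tfrim)
  L <- as.integer(config$tfrim$crop_samples)
  wave <- array(0, dim = c(n, 2L, L))
  for (i in seq_len(n)) {
    rec <- if (!is.null(recordings)) recordings[[i]] else {
      read_recording(manifest$recording_path[i])
    }
    wave[i, 1, ] <- rec$pressure[seq_len(L)]
    wave[i, 2, ] <- rec$flow[seq_len(L)]
  }
  v <- cbind(manifest$fef2575_ratio, manifest$fef50_ratio,
             manifest$fef75_ratio)
  vth <- config$labels$vth
  structure(list(
    tfrim = store$tfrim, wave = wave,
    demo = cbind(age = manifest$age_years, sex = manifest$sex,
                 height = manifest$height_cm, weight = manifest$weight_kg),
    y_hard = hard_label(v[, 1], v[, 2], v[, 3], vth = vth),
    y_soft = soft_labels(v[, 1], v[, 2], v[, 3], vth = vth,
                         lam = config$labels$lam),
    abnormal = (v < vth) * 1L,
    manifest = manifest, store = store, config = config
  ), class = "sad_dataset")
}

# ---- normalization ---------------------------------------------------------

#' Fit and apply leakage-safe z-score normalization
#'
#' `zscore_fit()` computes per-channel means and standard deviations from the
#' training subjects only (pressure and flow channels, the two TFRIM
#' channels, and the four demographic features); `zscore_apply()` applies
#' frozen statistics to any subject set.  Constant channels get a floored
#' sigma (1e-8) with a warning.
#'
#' @param dataset A `sad_dataset`.
#' @param train_idx Integer indices of the training subjects.
#' @return `zscore_fit()`: a `sad_norm_stats` list of `mu`/`sigma` per block.
#' @export
zscore_fit <- function(dataset, train_idx = seq_len(length(dataset$y_hard))) {
  if (length(train_idx) == 0) abort("training portion is empty")
  floor_sd <- function(s, what) {
    if (any(s < 1e-8)) {
      warn(sprintf("constant %s channel: sigma floored at 1e-8", what))
      s <- pmax(s, 1e-8)
    }
    s
  }
  ch_stats <- function(x) {                 # x: (n, C, ...) array
    C <- dim(x)[2]
    mu <- numeric(C); sg <- numeric(C)
    for (c in seq_len(C)) {
      v <- x[train_idx, c, , drop = FALSE]
      mu[c] <- mean(v); sg[c] <- sd(as.vector(v))
    }
    list(mu = mu, sigma = sg)
  }
  wv <- ch_stats(array(dataset$wave, dim = c(dim(dataset$wave)[1], 2L,
                                             prod(dim(dataset$wave)[-(1:2)]))))
  tfd <- dim(dataset$tfrim)
  tf <- ch_stats(array(dataset$tfrim, dim = c(tfd[1], 2L, tfd[3] * tfd[4])))
  dm <- list(mu = colMeans(dataset$demo[train_idx, , drop = FALSE]),
             sigma = apply(dataset$demo[train_idx, , drop = FALSE], 2, sd))
  structure(list(
    wave = list(mu = wv$mu, sigma = floor_sd(wv$sigma, "waveform")),
    tfrim = list(mu = tf$mu, sigma = floor_sd(tf$sigma, "TFRIM")),
    demo = list(mu = dm$mu, sigma = floor_sd(dm$sigma, "demographic"))
  ), class = "sad_norm_stats")
}

#' @rdname zscore_fit
#' @param stats Frozen `sad_norm_stats`.
#' @param idx Subjects to normalize.
#' @return `zscore_apply()`: list with normalized `tfrim`, `wave`, `demo`.
#' @export
zscore_apply <- function(stats, dataset, idx = seq_len(length(dataset$y_hard))) {
  tf <- dataset$tfrim[idx, , , , drop = FALSE]
  wv <- dataset$wave[idx, , , drop = FALSE]
  dm <- dataset$demo[idx, , drop = FALSE]
  for (c in 1:2) {
    tf[, c, , ] <- (tf[, c, , ] - stats$tfrim$mu[c]) / stats$tfrim$sigma[c]
    wv[, c, ] <- (wv[, c, ] - stats$wave$mu[c]) / stats$wave$sigma[c]
  }
  dm <- sweep(sweep(dm, 2, stats$demo$mu), 2, stats$demo$sigma, "/")
  list(tfrim = tf, wave = wv, demo = dm)
}

#' Multi-label binary cross-entropy against soft labels
#'
#' `L = -1/K sum_k [y_k log p_k + (1 - y_k) log(1 - p_k)]` with `K = 3`,
#' averaged over the batch; probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before the logs.
#'
#' @param prob Predicted probabilities (n x 3 or length 3).
#' @param y_soft Soft labels, same shape.
#' @return Scalar loss.
#' @export
bce_loss <- function(prob, y_soft) {
  p <- if (is.matrix(prob)) prob else matrix(prob, ncol = 3)
  y <- if (is.matrix(y_soft)) y_soft else matrix(y_soft, ncol = 3)
  if (!all(dim(p) == dim(y))) abort("prob and y_soft shapes differ")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Stratified k-fold assignment
#'
#' Random mutually exclusive folds whose sizes differ by at most one within
#' each stratum; stratification by the hard label keeps the SAD fraction of
#' every fold within one subject of the cohort fraction.  Falls back to an
#' unstratified split (with a warning) when a stratum is smaller than `k`.
#'
#' @param y Hard labels (or any stratification factor); its length sets the
#'   number of subjects.
#' @param k Number of folds.
#' @param seed Seed.
#' @param stratify Stratify on `y` (default) or split purely at random.
#' @return Integer vector of fold ids in `1..k`.
#' @export
kfold_split <- function(y, k = 5L, seed = 1L, stratify = TRUE) {
  n <- length(y)
  if (n < k) abort(sprintf("need at least k=%d subjects, got %d", k, n))
  if (stratify && min(table(y)) < k) {
    warn("a stratum is smaller than k; falling back to unstratified folds")
    stratify <- FALSE
  }
  with_local_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      for (lv in unique(y)) {
        ids <- which(y == lv)
        fold[ids] <- sample(rep_len(seq_len(k), length(ids)))
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

# ---- optimizer -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

cosine_lr <- function(lr0, epoch, max_epochs, lr_min = 1e-6) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (epoch - 1) / max_epochs))
}

make_batch <- function(norm, idx, model) {
  list(
    tfrim = if (model$meta$use_tfrim) {
      norm$tfrim[idx, , , , drop = FALSE]
    },
    wave = if (model$meta$use_time) norm$wave[idx, , , drop = FALSE],
    demo = if (model$meta$use_demo) norm$demo[idx, , drop = FALSE]
  )
}

eval_loss <- function(model, norm, idx, y_soft, chunk = 64L) {
  tot <- 0
  for (s in split(idx, ceiling(seq_along(idx) / chunk))) {
    fw <- forward_sad_model(model, make_batch(norm, s, model),
                            training = FALSE)
    tot <- tot + bce_loss(fw$prob, y_soft[s, , drop = FALSE]) * length(s)
  }
  tot / length(idx)
}

#' Train one fold of the classifier
#'
#' Adam at the configured learning rate with cosine annealing, mini-batches,
#' and early stopping when the validation loss (an inner stratified split of
#' the training portion — never the test fold) has not improved for
#' `patience` epochs; the best-validation weights are returned.  Batch size
#' is reduced automatically (with a warning) for cohorts smaller than the
#' configured batch.
#'
#' @param dataset A `sad_dataset`.
#' @param train_idx Training subjects for this fold.
#' @param model A freshly initialized [init_sad_model()].
#' @param training Config block (`lr`, `batch_size`, `patience`,
#'   `max_epochs`, `val_fraction`).
#' @param seed Seed for shuffling/dropout.
#' @param verbose Log per-epoch lines to stderr.
#' @return List: trained `model`, frozen `stats`, `history` tibble
#'   (epoch, lr, train_loss, val_loss), `best_epoch`.
#' @export
train_fold <- function(dataset, train_idx, model,
                       training = default_config()$training, seed = 1L,
                       verbose = FALSE) {
  stats <- zscore_fit(dataset, train_idx)
  norm <- zscore_apply(stats, dataset)      # full cohort, frozen train stats
  y <- dataset$y_soft
  split_seed <- (as.integer(seed) %% 100000L) + 17L
  val_idx <- with_local_seed(split_seed, {
    yh <- dataset$y_hard[train_idx]
    unlist(lapply(unique(yh), function(lv) {
      ids <- train_idx[yh == lv]
      sample(ids, max(1L, round(length(ids) * training$val_fraction)))
    }))
  })
  fit_idx <- setdiff(train_idx, val_idx)
  bs <- training$batch_size
  if (bs > length(fit_idx)) {
    warn(sprintf("batch size %d reduced to cohort size %d", bs,
                 length(fit_idx)))
    bs <- length(fit_idx)
  }
  state <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- list()
  wait <- 0L
  with_local_seed(seed, {
    for (epoch in seq_len(training$max_epochs)) {
      lr <- cosine_lr(training$lr, epoch, training$max_epochs)
      ord <- sample(fit_idx)
      tr_loss <- 0
      for (s in split(ord, ceiling(seq_along(ord) / bs))) {
        fw <- forward_sad_model(model, make_batch(norm, s, model),
                                training = TRUE)
        yb <- y[s, , drop = FALSE]
        tr_loss <- tr_loss + bce_loss(fw$prob, yb) * length(s)
        if (!is.finite(tr_loss)) {
          abort(sprintf("training diverged (non-finite loss) at epoch %d",
                        epoch))
        }
        dlogits <- (fw$prob - yb) / (3 * length(s))
        grads <- backward_sad_model(model, dlogits, fw$cache)
        upd <- adam_step(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
      }
      tr_loss <- tr_loss / length(fit_idx)
      vl <- eval_loss(model, norm, val_idx, y)
      hist[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                      train_loss = tr_loss, val_loss = vl)
      if (verbose) {
        message(sprintf("[train] epoch %3d lr %.2e train %.4f val %.4f",
                        epoch, lr, tr_loss, vl))
      }
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = model$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= training$patience) break
      }
    }
  })
  model$params <- best$params
  list(model = model, stats = stats, history = dplyr::bind_rows(hist),
       best_epoch = best$epoch)
}

# ---- metrics ---------------------------------------------------------------

metrics_from_counts <- function(tp, fn, tn, fp) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sens <- div(tp, tp + fn)
  prec <- div(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || (prec + sens) == 0) {
    NA_real_
  } else {
    2 * prec * sens / (prec + sens)
  }
  tibble::tibble(
    accuracy = div(tp + tn, tp + tn + fp + fn),
    sensitivity = sens, specificity = div(tn, tn + fp),
    precision = prec, f1 = f1
  )
}

binary_metrics <- function(pred, truth) {
  metrics_from_counts(tp = sum(pred == 1 & truth == 1),
                      fn = sum(pred == 0 & truth == 1),
                      tn = sum(pred == 0 & truth == 0),
                      fp = sum(pred == 1 & truth == 0))
}

#' Metric suite for subtask and voted predictions
#'
#' Subtask rows compare each binarized head against the hard per-index
#' abnormality (`v_k < vth`); the `SAD` row compares the majority vote with
#' the subject-level hard label.  Sensitivity is TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), F1 the harmonic mean of precision and
#' sensitivity; metrics whose denominator is empty are `NA`.
#'
#' @param prob `n x 3` subtask probabilities.
#' @param y_hard Subject-level hard labels.
#' @param abnormal `n x 3` per-index hard abnormality.
#' @param tau Binarization threshold.
#' @return Tibble with rows `fef2575, fef50, fef75, SAD`.
#' @export
evaluate_predictions <- function(prob, y_hard, abnormal, tau = 0.5) {
  vt <- vote(prob, tau = tau)
  votes <- cbind(vt$vote1, vt$vote2, vt$vote3)
  rows <- lapply(1:3, function(k) binary_metrics(votes[, k], abnormal[, k]))
  rows[[4]] <- binary_metrics(vt$decision, y_hard)
  dplyr::bind_cols(
    tibble::tibble(task = c("fef2575", "fef50", "fef75", "SAD")),
    dplyr::bind_rows(rows)
  )
}

#' Cross-validated training and evaluation
#'
#' Stratified k-fold protocol: for every fold, normalization statistics are
#' fitted on the training portion only and frozen, a fresh model is trained
#' with [train_fold()], the held-out fold is scored, and the per-fold metric
#' tables are averaged.
#'
#' @param dataset A `sad_dataset`.
#' @param config Full pipeline configuration.
#' @param k Folds (default from config).
#' @param seed Protocol seed (fold split, initialization, shuffling).
#' @param model_opts List passed to [init_sad_model()] (ablation flags,
#'   fusion choice).
#' @param verbose Log progress.
#' @return Object of class `sad_cv`: `per_fold` metrics tibble, `average`
#'   tibble, `predictions` tibble, fold assignment and history list.
#' @export
run_cv <- function(dataset, config = default_config(), k = NULL, seed = 1L,
                   model_opts = list(), verbose = FALSE) {
  k <- k %||% config$training$folds
  n <- length(dataset$y_hard)
  fold <- kfold_split(dataset$y_hard, k = k, seed = seed)
  per_fold <- list()
  preds <- list()
  hists <- list()
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    if (verbose) message(sprintf("[cv] fold %d: %d train / %d test",
                                 f, length(train_idx), length(test_idx)))
    model <- do.call(init_sad_model, c(list(
      config = config$network, seed = seed + 1000L * f,
      tfrim_hw = dim(dataset$tfrim)[3:4],
      wave_len = dim(dataset$wave)[3]), model_opts))
    fit <- tryCatch(
      train_fold(dataset, train_idx, model, config$training,
                 seed = seed + 1000L * f, verbose = verbose),
      error = function(e) abort(sprintf("fold %d failed: %s", f,
                                        conditionMessage(e))))
    norm <- zscore_apply(fit$stats, dataset)
    prob <- NULL
    for (s in split(test_idx, ceiling(seq_along(test_idx) / 64L))) {
      fw <- forward_sad_model(fit$model, make_batch(norm, s, fit$model))
      prob <- rbind(prob, fw$prob)
    }
    mt <- evaluate_predictions(prob, dataset$y_hard[test_idx],
                               dataset$abnormal[test_idx, , drop = FALSE],
                               tau = config$labels$tau)
    per_fold[[f]] <- dplyr::mutate(mt, fold = f)
    vt <- vote(prob, tau = config$labels$tau)
    preds[[f]] <- tibble::tibble(
      subject_id = dataset$manifest$subject_id[test_idx], fold = f,
      p1 = prob[, 1], p2 = prob[, 2], p3 = prob[, 3],
      decision = vt$decision, y_hard = dataset$y_hard[test_idx],
      S_pred = impairment_index(prob)
    )
    hists[[f]] <- fit$history
  }
  per_fold <- dplyr::bind_rows(per_fold)
  average <- per_fold |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "sensitivity", "specificity", "precision", "f1"),
      ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  structure(list(per_fold = per_fold, average = average,
                 predictions = dplyr::bind_rows(preds), fold = fold,
                 history = hists, k = k, seed = seed),
            class = "sad_cv")
}

#' @export
print.sad_cv <- function(x, ...) {
  cat(sprintf("<sad_cv> %d folds\n", x$k))
  print(x$average)
  invisible(x)
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x A `sad_cv`.
#' @param ... Unused.
#' @return Long tibble: task, fold, metric, value.
#' @method tidy sad_cv
#' @export
tidy.sad_cv <- function(x, ...) {
  tidyr::pivot_longer(x$per_fold,
                      c("accuracy", "sensitivity", "specificity",
                        "precision", "f1"),
                      names_to = "metric", values_to = "value")
}

#' One-row cross-validation summary (voted main task)
#'
#' @param x A `sad_cv`.
#' @param ... Unused.
#' @method glance sad_cv
#' @export
glance.sad_cv <- function(x, ...) {
  dplyr::filter(x$average, .data$task == "SAD")
}

#' Plot cross-validation metrics by fold
#'
#' @param object A `sad_cv`.
#' @param ... Unused.
#' @method autoplot sad_cv
#' @export
autoplot.sad_cv <- function(object, ...) {
  df <- tidy.sad_cv(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$metric, .data$value,
                                   fill = factor(.data$fold))) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~task) +
    ggplot2::labs(fill = "fold", y = "score")
}

#' Predict on new subjects with a trained model
#'
#' @param object Trained `sad_model`.
#' @param dataset A `sad_dataset`.
#' @param stats Frozen normalization statistics from [train_fold()].
#' @param idx Subjects to score.
#' @param tau Vote threshold.
#' @param ... Unused.
#' @return Tibble: subject id, three probabilities, votes, decision, and the
#'   impairment index computed from the predicted probabilities.
#' @export
predict.sad_model <- function(object, dataset, stats,
                              idx = seq_len(length(dataset$y_hard)),
                              tau = 0.5, ...) {
  norm <- zscore_apply(stats, dataset)
  prob <- NULL
  for (s in split(idx, ceiling(seq_along(idx) / 64L))) {
    fw <- forward_sad_model(object, make_batch(norm, s, object))
    prob <- rbind(prob, fw$prob)
  }
  vt <- vote(prob, tau = tau)
  tibble::tibble(
    subject_id = dataset$manifest$subject_id[idx],
    p_fef2575 = prob[, 1], p_fef50 = prob[, 2], p_fef75 = prob[, 3],
    vote1 = vt$vote1, vote2 = vt$vote2, vote3 = vt$vote3,
    decision = vt$decision, S_pred = impairment_index(prob)
  )
}
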