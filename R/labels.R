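# Label construction from spirometry ratios, decision voting, and the
# impairment index.  `v_k` is the measured/predicted ratio of FEF25-75,
# FEF50 and FEF75 (k = 1, 2, 3); a ratio is abnormal when strictly below the
# clinical cutoff `vth = 0.65`.

#' Hard SAD label from spirometry ratios
#'
#' A subject is labelled SAD (1) when at least two of the three ratios are
#' strictly below `vth`; ratios exactly at the threshold count as normal.
#'
#' @param v1,v2,v3 Spirometry ratios (measured/predicted), vectorized.
#' @param vth Abnormality threshold (default 0.65).
#' @return Integer vector in `{0, 1}`.
#' @export
hard_label <- function(v1, v2, v3, vth = 0.65) {
  if (any(c(v1, v2, v3) <= 0)) abort("spirometry ratios must be > 0")
  as.integer((v1 < vth) + (v2 < vth) + (v3 < vth) >= 2)
}

#' Soft labels from spirometry ratios
#'
#' `y_soft(k) = sigmoid(lam * (vth - v_k))`: 0.5 exactly at the threshold,
#' approaching 1 well below it and 0 well above it, retaining uncertainty
#' near the clinical cutoff during training.
#'
#' @param v1,v2,v3 Spirometry ratios, vectorized.
#' @param vth Threshold (default 0.65).
#' @param lam Smoothness scale (default 20).
#' @return Matrix with columns `y1, y2, y3` (one row per subject).
#' @export
soft_labels <- function(v1, v2, v3, vth = 0.65, lam = 20) {
  v <- cbind(v1, v2, v3)
  if (any(!is.finite(v))) abort("spirometry ratios must be finite")
  out <- sigmoid(lam * (vth - v))
  colnames(out) <- c("y1", "y2", "y3")
  out
}

#' Binarize head probabilities and vote
#'
#' Each of the three subtask probabilities is binarized at `tau` (the closed
#' side belongs to SAD: a probability exactly at `tau` votes abnormal) and
#' the subject-level decision is the majority of the three votes.
#'
#' @param prob Numeric vector of 3 probabilities, or an `n x 3` matrix.
#' @param tau Binarization threshold (default 0.5).
#' @return Tibble with `vote1, vote2, vote3, decision`.
#' @export
vote <- function(prob, tau = 0.5) {
  p <- if (is.matrix(prob)) prob else matrix(prob, ncol = 3)
  if (ncol(p) != 3) abort("`prob` must have three subtask probabilities")
  if (any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  v <- p >= tau
  tibble::tibble(
    vote1 = as.integer(v[, 1]), vote2 = as.integer(v[, 2]),
    vote3 = as.integer(v[, 3]),
    decision = as.integer(rowSums(v) >= 2)
  )
}

#' Small airway impairment index
#'
#' Multilinear fusion of the three soft labels,
#' `S = y1 y2 + y2 y3 + y1 y3 - 2 y1 y2 y3`.  On binary corners it equals the
#' majority-vote indicator; on the unit cube it stays in `[0, 1]` and is
#' symmetric in its arguments.  Used for reporting and embedding analysis
#' only, never in the training loss.
#'
#' @param y_soft Length-3 vector or `n x 3` matrix of values in `[0, 1]`.
#' @return Numeric vector of `S` values.
#' @export
impairment_index <- function(y_soft) {
  y <- if (is.matrix(y_soft)) y_soft else matrix(y_soft, ncol = 3)
  if (ncol(y) != 3) abort("`y_soft` must have three components")
  if (any(y < 0 | y > 1)) abort("soft-label components must lie in [0, 1]")
  y1 <- y[, 1]; y2 <- y[, 2]; y3 <- y[, 3]
  y1 * y2 + y2 * y3 + y1 * y3 - 2 * y1 * y2 * y3
}

#' Append label columns to a manifest
#'
#' Adds `y_hard`, `y_soft_1..3` and `S` computed from the three spirometry
#' ratio columns.
#'
#' @param manifest Manifest tibble.
#' @param vth,lam Label parameters.
#' @return The manifest with label columns appended.
#' @export
label_manifest <- function(manifest, vth = 0.65, lam = 20) {
  ys <- soft_labels(manifest$fef2575_ratio, manifest$fef50_ratio,
                    manifest$fef75_ratio, vth = vth, lam = lam)
  dplyr::mutate(
    manifest,
    y_hard = hard_label(manifest$fef2575_ratio, manifest$fef50_ratio,
                        manifest$fef75_ratio, vth = vth),
    y_soft_1 = ys[, 1], y_soft_2 = ys[, 2], y_soft_3 = ys[, 3],
    S = impairment_index(ys)
  )
}
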