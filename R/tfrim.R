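# Time-Frequency Respiratory Impedance Map (TFRIM) construction.
#
# Pipeline: crop to the fixed 9120-sample analysis length -> 4-s Hamming
# windows hopped by 0.4 s -> Welch-averaged cross-spectral impedance and
# coherence inside each window -> coherence screening at gamma_th -> top-24
# channel selection -> (2, 24, 48) tensor.  Coherence is only informative for
# averaged spectral estimates (a single-segment estimate is identically 1),
# so each 4-s window is internally Welch-averaged over 0.8-s half-overlapping
# Hamming-tapered sub-segments; 0.8 s gives a 1.25 Hz grid on which every
# harmonic of the 2.5 Hz excitation falls exactly on a bin.

detrend_linear <- function(x) {
  n <- length(x)
  if (n < 3) return(x - mean(x))
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

hamming_window <- function(n) as.numeric(signal::hamming(n))

#' Global (whole-recording) impedance spectrum
#'
#' One-sided DFT ratio `Z[k] = P[k] / F[k]` over bins `k = 0..floor(N/2)`.
#' This is the classical stationary estimate; bins where the flow spectrum
#' carries essentially no energy (auto-power below `floor_rel` of the band
#' maximum) are flagged undefined rather than divided.
#'
#' @param rec An [ios_recording()].
#' @param floor_rel Relative flow-power floor below which a bin is undefined.
#' @return Tibble with `freq_hz`, `resistance`, `reactance`, `impedance`
#'   (complex) and `defined`.
#' @export
global_impedance <- function(rec, floor_rel = 1e-12) {
  stopifnot(inherits(rec, "ios_recording"))
  if (rec$n < 1) abort("empty recording")
  if (all(rec$flow == 0)) abort("flow is identically zero; impedance undefined")
  P <- fft(rec$pressure)
  F <- fft(rec$flow)
  keep <- seq_len(floor(rec$n / 2) + 1L)
  P <- P[keep]
  F <- F[keep]
  Sff <- Mod(F)^2
  defined <- Sff > floor_rel * max(Sff)
  Z <- complex(real = rep(NA_real_, length(keep)),
               imaginary = rep(NA_real_, length(keep)))
  Z[defined] <- P[defined] / F[defined]
  tibble::tibble(
    freq_hz = (keep - 1L) * rec$fs / rec$n,
    resistance = Re(Z), reactance = Im(Z), impedance = Z, defined = defined
  )
}

#' Classical scalar IOS indices from an impedance spectrum
#'
#' Linear interpolation of resistance/reactance onto 5, 20 and 35 Hz, plus
#' `Z5 = sqrt(R5^2 + X5^2)` and the resonant frequency (linearly interpolated
#' zero crossing of reactance).  Indices whose target frequency lies outside
#' the measured band, and `Fres` when the reactance never crosses zero in
#' band, come back `NA` with `fres_defined = FALSE` rather than failing.
#'
#' @param spectrum Data frame with `freq_hz`, `resistance`, `reactance` and
#'   optionally `defined` (as returned by [global_impedance()] or
#'   [tidy.tfrim_tensor()]).
#' @return One-row tibble `R5, R20, R35, X5, Z5, Fres, fres_defined`.
#' @export
scalar_ios_parameters <- function(spectrum) {
  df <- as.data.frame(spectrum)
  if (!is.null(df$defined)) df <- df[df$defined, ]
  df <- df[is.finite(df$resistance) & is.finite(df$reactance), ]
  df <- df[order(df$freq_hz), ]
  interp <- function(y, f0) {
    if (nrow(df) < 2 || f0 < min(df$freq_hz) || f0 > max(df$freq_hz)) {
      return(NA_real_)
    }
    stats::approx(df$freq_hz, y, xout = f0)$y
  }
  R5 <- interp(df$resistance, 5)
  X5 <- interp(df$reactance, 5)
  fres <- NA_real_
  if (nrow(df) >= 2) {
    s <- sign(df$reactance)
    cross <- which(s[-1] != s[-nrow(df)] & s[-nrow(df)] < 0)
    if (length(cross) > 0) {
      i <- cross[1]
      x1 <- df$reactance[i]; x2 <- df$reactance[i + 1]
      f1 <- df$freq_hz[i]; f2 <- df$freq_hz[i + 1]
      fres <- f1 + (0 - x1) * (f2 - f1) / (x2 - x1)
    } else if (all(s >= 0)) {
      fres <- NA_real_  # reactance positive across the band: no resonance
    }
  }
  tibble::tibble(
    R5 = R5, R20 = interp(df$resistance, 20), R35 = interp(df$resistance, 35),
    X5 = X5, Z5 = sqrt(R5^2 + X5^2), Fres = fres,
    fres_defined = is.finite(fres)
  )
}

#' Short-time windowing of a recording
#'
#' Optionally removes the breathing band with a zero-phase high-pass common
#' to both channels (impedance is a pressure/flow ratio, so a filter applied
#' identically to numerator and denominator cancels exactly while killing
#' breathing leakage into the lowest excitation harmonics), then slices the
#' recording into `window_s`-second windows hopped by `hop_s` seconds.  Each
#' window is linearly detrended and Hamming-tapered before its
#' full-resolution one-sided spectrum is taken; the (filtered) window samples
#' are kept for the Welch cross-spectral stage.
#'
#' @param rec An [ios_recording()].
#' @param window_s Window length, s (default 4, i.e. 0.25 Hz resolution).
#' @param hop_s Hop, s.
#' @param highpass_hz Zero-phase Butterworth high-pass cutoff, Hz (default
#'   1.2, below the lowest excitation harmonic and above any plausible
#'   breathing rate); `0` disables the filter.
#' @return Object of class `ios_windowed_spectra`.
#' @export
stft_windows <- function(rec, window_s = 4.0, hop_s = 0.4, highpass_hz = 1.2) {
  stopifnot(inherits(rec, "ios_recording"))
  win <- as.integer(round(window_s * rec$fs))
  hop <- as.integer(round(hop_s * rec$fs))
  if (rec$n < win) {
    abort(sprintf("recording (%d samples) shorter than one %d-sample window",
                  rec$n, win))
  }
  pr <- rec$pressure
  fl <- rec$flow
  if (highpass_hz > 0) {
    bf <- signal::butter(4, highpass_hz / (rec$fs / 2), type = "high")
    pr <- as.numeric(signal::filtfilt(bf, pr))
    fl <- as.numeric(signal::filtfilt(bf, fl))
  }
  n_win <- (rec$n - win) %/% hop + 1L
  starts <- (seq_len(n_win) - 1L) * hop
  idx <- outer(seq_len(win), starts, `+`)
  Pw <- matrix(pr[idx], nrow = win)
  Fw <- matrix(fl[idx], nrow = win)
  taper <- hamming_window(win)
  Pd <- apply(Pw, 2, detrend_linear) * taper
  Fd <- apply(Fw, 2, detrend_linear) * taper
  keep <- seq_len(win %/% 2 + 1L)
  structure(list(
    P = stats::mvfft(Pd)[keep, , drop = FALSE],
    F = stats::mvfft(Fd)[keep, , drop = FALSE],
    pressure_windows = Pw, flow_windows = Fw,
    freqs = (keep - 1L) * rec$fs / win,
    window_times = (starts + win / 2) / rec$fs,
    fs = rec$fs, window_s = window_s, hop_s = hop_s,
    subject_id = rec$subject_id
  ), class = "ios_windowed_spectra")
}

#' Windowed cross-spectral impedance with coherence
#'
#' Within each short-time window, the cross-power density `S_PF`, and the
#' auto-power densities `S_FF`, `S_PP`, are Welch-averaged over
#' `subsegment_s`-second Hamming-tapered sub-segments overlapping by
#' `subsegment_overlap`; the impedance is `Z_t[k] = S_PF / S_FF` and the
#' magnitude-squared coherence `gamma^2_t[k] = |S_PF|^2 / (S_PP S_FF)`.
#' Averaging over several sub-segments is what makes `gamma^2 < 1` possible
#' at contaminated bins.  Bins with flow auto-power below `floor_rel` of the
#' map maximum are undefined (coherence 0, excluded from division).
#'
#' @param ws An `ios_windowed_spectra` from [stft_windows()].
#' @param subsegment_s Sub-segment length, s (default 0.8: the 1.25 Hz grid
#'   puts every harmonic of a 2.5 Hz excitation on-bin).
#' @param subsegment_overlap Fractional overlap between sub-segments.
#' @param floor_rel Relative flow-power floor for undefined bins.
#' @return Object of class `ios_raw_tfrim` with matrices `R`, `X`,
#'   `coherence`, logical `mask` (frequency x window), `freqs`, `times`.
#' @export
window_impedance <- function(ws, subsegment_s = 0.8, subsegment_overlap = 0.5,
                             floor_rel = 1e-12) {
  stopifnot(inherits(ws, "ios_windowed_spectra"))
  win <- nrow(ws$pressure_windows)
  n_win <- ncol(ws$pressure_windows)
  seg <- as.integer(round(subsegment_s * ws$fs))
  step <- as.integer(round(seg * (1 - subsegment_overlap)))
  if (step < 1L) abort("subsegment overlap too large")
  if (seg > win) abort("sub-segment longer than the window")
  n_seg <- (win - seg) %/% step + 1L
  if (n_seg < 2L) {
    abort(sprintf(
      "only %d sub-segment fits the window; >= 2 averages are required for coherence",
      n_seg))
  }
  offs <- (seq_len(n_seg) - 1L) * step
  taper <- hamming_window(seg)
  keep <- seq_len(seg %/% 2 + 1L)
  n_bin <- length(keep)
  # segment index matrix: seg x (n_seg * n_win)
  seg_idx <- outer(seq_len(seg), offs, `+`)  # seg x n_seg within one window
  col_of <- rep(seq_len(n_win), each = n_seg)
  idx_full <- matrix(0L, nrow = seg, ncol = n_seg * n_win)
  for (w in seq_len(n_win)) {
    idx_full[, (w - 1L) * n_seg + seq_len(n_seg)] <-
      seg_idx + (w - 1L) * win
  }
  # no per-sub-segment detrend: removing slightly different linear
  # projections from pressure and flow biases the cross-spectral ratio;
  # the common high-pass in stft_windows() handles the breathing band
  Pseg <- matrix(ws$pressure_windows[idx_full], nrow = seg) * taper
  Fseg <- matrix(ws$flow_windows[idx_full], nrow = seg) * taper
  Pf <- stats::mvfft(Pseg)[keep, , drop = FALSE]
  Ff <- stats::mvfft(Fseg)[keep, , drop = FALSE]
  cross <- Pf * Conj(Ff)
  autoF <- Mod(Ff)^2
  autoP <- Mod(Pf)^2
  group_mean <- function(M) {
    # average the n_seg consecutive columns belonging to each window
    out <- matrix(0, nrow = n_bin, ncol = n_win)
    for (w in seq_len(n_win)) {
      cols <- (w - 1L) * n_seg + seq_len(n_seg)
      out[, w] <- rowMeans(M[, cols, drop = FALSE])
    }
    out
  }
  Spf_re <- group_mean(Re(cross))
  Spf_im <- group_mean(Im(cross))
  Sff <- group_mean(autoF)
  Spp <- group_mean(autoP)
  defined <- Sff > floor_rel * max(Sff)
  Zr <- matrix(0, n_bin, n_win)
  Zx <- matrix(0, n_bin, n_win)
  Zr[defined] <- Spf_re[defined] / Sff[defined]
  Zx[defined] <- Spf_im[defined] / Sff[defined]
  coh <- matrix(0, n_bin, n_win)
  ok <- defined & Spp > 0
  coh[ok] <- (Spf_re[ok]^2 + Spf_im[ok]^2) / (Spp[ok] * Sff[ok])
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(
    R = Zr, X = Zx, coherence = coh, mask = defined,
    freqs = (keep - 1L) * ws$fs / seg, times = ws$window_times,
    gamma_th = NA_real_, screened = FALSE, subject_id = ws$subject_id
  ), class = "ios_raw_tfrim")
}

#' Coherence screening
#'
#' Applies the piecewise quality-control rule: impedance entries whose
#' coherence falls below `gamma_th` are set to zero and their mask cleared.
#'
#' @param raw An `ios_raw_tfrim` from [window_impedance()].
#' @param gamma_th Coherence threshold (default 0.90).
#' @export
coherence_screen <- function(raw, gamma_th = 0.90) {
  stopifnot(inherits(raw, "ios_raw_tfrim"))
  drop <- raw$coherence < gamma_th
  raw$R[drop] <- 0
  raw$X[drop] <- 0
  raw$mask <- raw$mask & !drop
  raw$gamma_th <- gamma_th
  raw$screened <- TRUE
  raw
}

#' Retain the highest-coherence frequency channels
#'
#' Ranks frequency bins by their time-mean screened coherence (zeros where
#' the mask is cleared), keeps the top `n_channels`, and re-sorts the kept
#' bins by frequency ascending.  The ranking uses only this sample's own
#' signals.  Ties at the cutoff go to the lower frequency (the low-frequency
#' band is the physiologically informative one).  Bins below `f_min` are not
#' candidates: the DC/breathing-band bin is trivially coherent but carries no
#' oscillometric impedance.
#'
#' @param raw A screened `ios_raw_tfrim`.
#' @param n_channels Number of channels to keep (default 24).
#' @param f_min Lowest candidate frequency, Hz.
#' @return Object of class `tfrim_tensor`: `values` array
#'   `(2, n_channels, n_windows)` (channel 1 resistance, channel 2 reactance),
#'   `freqs`, `times`, `mean_coherence`.
#' @export
select_channels <- function(raw, n_channels = 24L, f_min = 2.0) {
  stopifnot(inherits(raw, "ios_raw_tfrim"))
  if (!isTRUE(raw$screened)) {
    warn("channel selection on unscreened map; applying default screening")
    raw <- coherence_screen(raw)
  }
  mean_coh <- rowMeans(raw$coherence * raw$mask)
  cand <- which(raw$freqs >= f_min & mean_coh > 0)
  if (length(cand) < n_channels) {
    abort(sprintf(
      "quality failure: only %d frequency bins are eligible after coherence screening (need %d)",
      length(cand), n_channels))
  }
  # round before ranking so numerically-identical coherences tie cleanly,
  # letting the lower-frequency tie-break act
  score <- round(mean_coh[cand], 10)
  ord <- cand[order(-score, raw$freqs[cand])]
  keep <- sort(ord[seq_len(n_channels)])
  vals <- array(0, dim = c(2L, n_channels, ncol(raw$R)))
  vals[1, , ] <- raw$R[keep, , drop = FALSE]
  vals[2, , ] <- raw$X[keep, , drop = FALSE]
  structure(list(
    values = vals, freqs = raw$freqs[keep], times = raw$times,
    mean_coherence = mean_coh[keep], gamma_th = raw$gamma_th,
    subject_id = raw$subject_id
  ), class = "tfrim_tensor")
}

#' Build the TFRIM tensor for one recording
#'
#' End-to-end composition: crop to the first 9120 samples, short-time
#' windowing, Welch cross-spectral impedance with coherence, coherence
#' screening, channel selection.  Default configuration gives a
#' `(2, 24, 48)` tensor.  Stage failures are re-raised with the stage name.
#'
#' @param rec An [ios_recording()].
#' @param config `tfrim` block of [default_config()] (or compatible list).
#' @return A `tfrim_tensor`.
#' @export
build_tfrim <- function(rec, config = default_config()$tfrim) {
  stopifnot(inherits(rec, "ios_recording"))
  crop <- as.integer(config$crop_samples %||% 9120L)
  if (rec$n < crop) {
    abort(sprintf(
      "[crop] recording has %d samples; the fixed analysis length is %d",
      rec$n, crop))
  }
  rec <- ios_recording(rec$pressure[seq_len(crop)], rec$flow[seq_len(crop)],
                       fs = rec$fs, subject_id = rec$subject_id)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)))
    })
  }
  ws <- stage("stft", stft_windows(rec, config$window_s, config$hop_s,
                                   config$highpass_hz %||% 1.2))
  raw <- stage("welch", window_impedance(ws, config$subsegment_s,
                                         config$subsegment_overlap))
  raw <- stage("screen", coherence_screen(raw, config$gamma_th))
  stage("select", select_channels(raw, config$n_channels, config$f_min))
}

#' Build TFRIM tensors for a whole cohort
#'
#' @param manifest Manifest tibble ([read_manifest()] schema); recordings are
#'   read from `recording_path` unless an in-memory `recordings` list (in
#'   manifest order) is supplied.
#' @param recordings Optional list of [ios_recording()] objects.
#' @param config `tfrim` configuration block.
#' @return Cohort store list: `tfrim` array `(n, 2, H, W)`, per-subject
#'   `freqs` and `mean_coherence` matrices, `times`, `subject_ids`, `params`.
#' @export
build_cohort_tfrim <- function(manifest, recordings = NULL,
                               config = default_config()$tfrim) {
  n <- nrow(manifest)
  H <- as.integer(config$n_channels)
  first <- NULL
  tensors <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- if (!is.null(recordings)) recordings[[i]] else {
      read_recording(manifest$recording_path[i])
    }
    tensors[[i]] <- build_tfrim(rec, config)
    if (is.null(first)) first <- tensors[[i]]
  }
  W <- dim(first$values)[3]
  arr <- array(0, dim = c(n, 2L, H, W))
  freqs <- matrix(0, n, H)
  mcoh <- matrix(0, n, H)
  for (i in seq_len(n)) {
    arr[i, , , ] <- tensors[[i]]$values
    freqs[i, ] <- tensors[[i]]$freqs
    mcoh[i, ] <- tensors[[i]]$mean_coherence
  }
  list(tfrim = arr, freqs = freqs, mean_coherence = mcoh,
       times = first$times, subject_ids = manifest$subject_id,
       params = config)
}

#' Tidy a TFRIM tensor into long format
#'
#' @param x A `tfrim_tensor`.
#' @param ... Unused.
#' @return Tibble `freq_hz, time_s, resistance, reactance`, one row per
#'   retained frequency-time cell; convenient for plotting and for
#'   [scalar_ios_parameters()] after time-averaging.
#' @method tidy tfrim_tensor
#' @export
tidy.tfrim_tensor <- function(x, ...) {
  H <- dim(x$values)[2]
  W <- dim(x$values)[3]
  tibble::tibble(
    freq_hz = rep(x$freqs, times = W),
    time_s = rep(x$times, each = H),
    resistance = as.vector(x$values[1, , ]),
    reactance = as.vector(x$values[2, , ])
  )
}

#' Time-averaged impedance spectrum of a TFRIM tensor
#'
#' Averages each retained channel over the windows where it passed screening,
#' yielding a spectrum suitable for [scalar_ios_parameters()].
#'
#' @param x A `tfrim_tensor`.
#' @export
tfrim_spectrum <- function(x) {
  stopifnot(inherits(x, "tfrim_tensor"))
  nz <- x$values[1, , ] != 0 | x$values[2, , ] != 0
  cnt <- pmax(rowSums(nz), 1)
  tibble::tibble(
    freq_hz = x$freqs,
    resistance = rowSums(x$values[1, , ]) / cnt,
    reactance = rowSums(x$values[2, , ]) / cnt
  )
}

#' @export
print.tfrim_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tfrim_tensor> %s: (%d x %d x %d), %g-%g Hz, gamma_th=%.2f\n",
              x$subject_id, d[1], d[2], d[3], min(x$freqs), max(x$freqs),
              x$gamma_th))
  invisible(x)
}

#' Plot a TFRIM tensor
#'
#' @param object A `tfrim_tensor`.
#' @param ... Unused.
#' @return A ggplot with resistance and reactance facets.
#' @method autoplot tfrim_tensor
#' @export
autoplot.tfrim_tensor <- function(object, ...) {
  df <- tidy.tfrim_tensor(object)
  df <- tidyr::pivot_longer(df, c("resistance", "reactance"),
                            names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, factor(.data$freq_hz),
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel, ncol = 1) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "kPa/(L/s)")
}
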