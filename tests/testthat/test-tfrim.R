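# TFRIM construction: spectral identities, closed-form impedance recovery,
# coherence behaviour, channel selection and tensor geometry.

test_that("global impedance reproduces identity and scaling cases", {
  set.seed(1)
  x <- rnorm(4000)
  rec1 <- ios_recording(x, x, fs = 400)
  gi <- global_impedance(rec1)
  ok <- gi$defined
  expect_true(all(abs(gi$resistance[ok] - 1) < 1e-9))
  expect_true(all(abs(gi$reactance[ok]) < 1e-9))
  rec2 <- ios_recording(2 * x, x, fs = 400)
  gi2 <- global_impedance(rec2)
  expect_true(all(abs(gi2$resistance[gi2$defined] - 2) < 1e-9))
  expect_error(global_impedance(ios_recording(x, numeric(4000))), "zero")
})

test_that("global impedance recovers the closed-form RIC value at harmonics", {
  rec <- synthesize_recording(ref_model(), duration = 24)
  gi <- global_impedance(rec)
  for (f0 in c(2.5, 5, 20, 60)) {
    k <- which.min(abs(gi$freq_hz - f0))
    truth <- oracle_ric(0.35, 0.00065, 0.20, f0)
    expect_rel_error(gi$resistance[k], Re(truth), 0.02)
    expect_rel_error(gi$reactance[k], Im(truth), 0.02)
  }
})

test_that("scalar IOS indices interpolate correctly and flag missing resonance", {
  rec <- synthesize_recording(ref_model(), duration = 24)
  gi <- global_impedance(rec)
  sp <- gi[gi$defined & gi$freq_hz %in% (2.5 * (1:24)), ]
  par <- scalar_ios_parameters(sp)
  expect_rel_error(par$X5, Im(oracle_ric(0.35, 0.00065, 0.20, 5)), 0.02)
  expect_equal(par$Fres, oracle_fres(0.00065, 0.20), tolerance = 0.25)
  expect_equal(par$Z5, sqrt(par$R5^2 + par$X5^2))
  # reactance positive everywhere: no zero crossing in band
  pos <- tibble::tibble(freq_hz = c(5, 10, 20, 35),
                        resistance = 0.3, reactance = c(0.1, 0.2, 0.3, 0.4))
  expect_false(scalar_ios_parameters(pos)$fres_defined)
  # band too narrow for R35: flagged NA, not an error
  narrow <- tibble::tibble(freq_hz = c(5, 10, 20), resistance = 0.3,
                           reactance = c(-0.1, 0, 0.1))
  expect_true(is.na(scalar_ios_parameters(narrow)$R35))
})

test_that("short-time windowing yields the documented geometry", {
  rec <- synthesize_recording(ref_model(), duration = 24)
  rec48 <- ios_recording(rec$pressure[1:9120], rec$flow[1:9120], 400)
  ws <- stft_windows(rec48)
  expect_equal(ncol(ws$P), 48)                     # 9120 samples -> 48 windows
  expect_equal(ws$freqs[2] - ws$freqs[1], 0.25)    # 4-s window -> 0.25 Hz
  expect_equal(which(ws$freqs == 2.5), 11)         # 0-based bin index 10
  one <- ios_recording(rec$pressure[1:1600], rec$flow[1:1600], 400)
  expect_equal(ncol(stft_windows(one)$P), 1)       # exactly one window
  short <- ios_recording(rec$pressure[1:1000], rec$flow[1:1000], 400)
  expect_error(stft_windows(short), "shorter")
})

test_that("windowed impedance is exact for proportional channels", {
  set.seed(2)
  x <- rnorm(9120)
  ws <- stft_windows(ios_recording(x, x, 400), highpass_hz = 0)
  raw <- window_impedance(ws)
  ok <- raw$mask
  expect_true(all(abs(raw$R[ok] - 1) < 1e-9))
  expect_true(all(abs(raw$X[ok]) < 1e-9))
  expect_true(all(abs(raw$coherence[ok] - 1) < 1e-9))
})

test_that("sub-segment configuration must allow at least two averages", {
  rec <- synthesize_recording(ref_model(), duration = 24)
  ws <- stft_windows(ios_recording(rec$pressure[1:9120], rec$flow[1:9120], 400))
  expect_error(window_impedance(ws, subsegment_s = 4.0), ">= 2")
})

test_that("coherence stays within [0, 1] on arbitrary noise inputs", {
  set.seed(3)
  for (i in 1:5) {
    p <- rnorm(9120)
    f <- rnorm(9120)
    raw <- window_impedance(stft_windows(ios_recording(p, f, 400)))
    expect_true(all(raw$coherence >= 0 & raw$coherence <= 1))
  }
})

test_that("independent flow noise at an unexcited bin suppresses its coherence", {
  m <- ref_model()
  rec <- synthesize_recording(m, duration = 24)
  set.seed(4)
  # band-limited independent noise centred on two unexcited bins
  contaminate <- function(flow, f0, sd, fs = 400) {
    bp <- signal::butter(2, c(f0 - 0.5, f0 + 0.5) / (fs / 2), type = "pass")
    nb <- as.numeric(signal::filtfilt(bp, rnorm(length(flow))))
    flow + nb * sd / stats::sd(nb)
  }
  flow <- contaminate(rec$flow[1:9120], 8.75, 0.05)
  flow <- contaminate(flow, 21.25, 0.05)
  noisy <- ios_recording(rec$pressure[1:9120], flow, 400)
  raw <- window_impedance(stft_windows(noisy))
  for (f0 in c(8.75, 21.25)) {
    k <- which(raw$freqs == f0)
    expect_lt(median(raw$coherence[k, ]), 0.9)
  }
  # neighbouring excited harmonics keep their coherence
  for (f0 in c(5, 30)) {
    k <- which(raw$freqs == f0)
    expect_gt(median(raw$coherence[k, ]), 0.95)
  }
})

test_that("coherence screening zeroes exactly the sub-threshold entries", {
  set.seed(5)
  raw <- window_impedance(stft_windows(
    ios_recording(rnorm(9120), rnorm(9120), 400)))
  raw$coherence[3, 1] <- 0.95
  raw$coherence[3, 2] <- 0.89
  raw$R[3, 1:2] <- 0.5
  raw$X[3, 1:2] <- -0.1
  raw$mask[3, 1:2] <- TRUE
  scr <- coherence_screen(raw, gamma_th = 0.90)
  expect_equal(scr$R[3, 1], 0.5)                   # 0.95 retained
  expect_true(scr$mask[3, 1])
  expect_equal(scr$R[3, 2], 0)                     # 0.89 zeroed
  expect_false(scr$mask[3, 2])
  expect_true(all(!scr$mask[scr$coherence < 0.9]))
})

test_that("channel selection reproduces a brute-force ranking with the stated tie-break", {
  m <- sad_phenotype("nonSAD", seed = 10)
  rec <- synthesize_recording(m, seed = 10)
  raw <- coherence_screen(window_impedance(stft_windows(
    ios_recording(rec$pressure[1:9120], rec$flow[1:9120], 400))))
  tensor <- select_channels(raw, n_channels = 24, f_min = 2)
  # independent brute-force re-ranking
  mean_coh <- rowMeans(raw$coherence * raw$mask)
  cand <- which(raw$freqs >= 2 & mean_coh > 0)
  ord <- cand[order(-round(mean_coh[cand], 10), raw$freqs[cand])]
  expect_setequal(tensor$freqs, raw$freqs[sort(ord[1:24])])
  expect_equal(tensor$freqs, sort(tensor$freqs))   # ascending
  # exact ties go to the lower frequency
  raw2 <- raw
  raw2$coherence[] <- 0
  raw2$mask[] <- FALSE
  hi <- 10:40
  raw2$coherence[hi, ] <- 0.95
  raw2$mask[hi, ] <- TRUE
  raw2$R[hi, ] <- 1
  t2 <- select_channels(raw2, n_channels = 24, f_min = 2)
  expect_equal(t2$freqs, raw$freqs[hi][1:24])
  # shortfall raises a quality error naming the count
  raw3 <- raw2
  raw3$mask[30:40, ] <- FALSE
  raw3$coherence[30:40, ] <- 0
  expect_error(select_channels(raw3, n_channels = 24, f_min = 2),
               "quality failure")
})

test_that("the end-to-end TFRIM tensor has the documented geometry", {
  m <- sad_phenotype("SAD", seed = 2)
  rec <- synthesize_recording(m, seed = 2)
  tensor <- build_tfrim(rec)
  expect_equal(dim(tensor$values), c(2, 24, 48))
  expect_equal(length(tensor$freqs), 24)
  expect_equal(length(tensor$times), 48)
  # crop policy: only the first 9120 samples matter
  rec_crop <- ios_recording(rec$pressure[1:9120], rec$flow[1:9120], 400,
                            subject_id = rec$subject_id)
  expect_equal(build_tfrim(rec_crop)$values, tensor$values)
  # too-short recordings are rejected, not padded
  short <- ios_recording(rec$pressure[1:9000], rec$flow[1:9000], 400)
  expect_error(build_tfrim(short), "9120")
})

test_that("TFRIM scales linearly in the pressure channel", {
  m <- sad_phenotype("nonSAD", seed = 6)
  rec <- synthesize_recording(m, seed = 6)
  t1 <- build_tfrim(rec)
  rec3 <- ios_recording(3 * rec$pressure, rec$flow, 400)
  t3 <- build_tfrim(rec3)
  expect_equal(t3$freqs, t1$freqs)
  expect_equal(t3$values, 3 * t1$values, tolerance = 1e-8)
})

test_that("windowed estimates resolve within-breath expiratory resistance elevation", {
  # slow breathing (8-s cycle) so a 4-s window sits inside one phase
  wins <- 0L
  for (s in 1:20) {
    m <- ios_impedance_model(0.3, 0.00065, 0.20, dR_exp = 0.2,
                             noise_sd_p = 0.003, noise_sd_f = 0.005)
    br <- breathing_pattern(breath_rate = 7.5)
    rec <- synthesize_recording(m, breathing = br, seed = s, duration = 24)
    rec <- ios_recording(rec$pressure[1:9120], rec$flow[1:9120], 400)
    raw <- window_impedance(stft_windows(rec))
    k5 <- which(raw$freqs == 5)
    phase <- sin(2 * pi * raw$times / 8) > 0   # expiratory window centres
    r_exp <- mean(raw$R[k5, phase])
    r_ins <- mean(raw$R[k5, !phase])
    wins <- wins + (r_exp > r_ins)
  }
  expect_gt(wins, 10)   # direction holds for a clear majority of seeds
})
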