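# Synthetic IOS cohort generator.
#
# Forward model: quiet tidal breathing plus a 2.5 Hz pulse-train excitation is
# pushed through a slowly time-varying resistance-inertance-compliance (RIC)
# impedance.  Because the impedance varies on the breathing timescale (~4 s),
# far slower than any excitation period (<= 0.4 s), pressure is synthesized
# quasi-statically: each excitation harmonic is scaled by |Z(f, t)| and phase
# shifted by arg Z(f, t) sample-by-sample.  This keeps the generating impedance
# available in closed form, so every downstream estimator has an exact oracle.

# Group-conditional parameter anchors (means, sds).  Impedance entries follow
# published cohort statistics for R5, X5 and resonant frequency; the
# within-breath expiratory increment and the frequency-dependence slope of
# resistance are set from the printed R5-R20 gradient and the requirement that
# obstructed phenotypes carry a within-breath signature.
.phenotype_table <- list(
  SAD = list(
    R5   = c(0.47, 0.20), X5 = c(-0.16, 0.12), Fres = c(17.56, 6.25),
    dR_exp = c(0.08, 0.03), fdep = c(0.008, 0.003),
    v = list(c(0.43, 0.17), c(0.49, 0.20), c(0.35, 0.14)),
    age = c(50.42, 18.32), height = c(163.21, 11.38), weight = c(66.94, 16.00),
    male_frac = 0.4863
  ),
  nonSAD = list(
    R5   = c(0.37, 0.14), X5 = c(-0.10, 0.05), Fres = c(13.63, 3.96),
    dR_exp = c(0.015, 0.01), fdep = c(0.004, 0.002),
    v = list(c(0.88, 0.18), c(0.94, 0.19), c(0.77, 0.25)),
    age = c(41.04, 17.49), height = c(164.94, 12.38), weight = c(68.80, 19.30),
    male_frac = 0.4803
  )
)

.min_tfrim_samples <- 9120L

#' Ground-truth respiratory impedance model
#'
#' A single-compartment resistance-inertance-compliance (RIC) description of
#' the respiratory system, extended with a within-breath expiratory resistance
#' increment and a negative frequency dependence of resistance.  The resistance
#' at frequency `f` (Hz) during phase `phi` (0 = inspiration, 1 = expiration)
#' is `max(R0 + dR_exp * phi - fdep * (f - 5), 0.05)`; the reactance is the
#' usual `2*pi*f*I - 1/(2*pi*f*C)`.
#'
#' @param R0 Baseline resistance at 5 Hz, kPa/(L/s).
#' @param I Inertance, kPa s^2/L.
#' @param C Compliance, L/kPa.
#' @param fdep Resistance slope against frequency, kPa/(L/s) per Hz (>= 0
#'   gives the clinically typical fall of R with frequency).
#' @param dR_exp Expiratory resistance increment, kPa/(L/s).
#' @param noise_sd_p,noise_sd_f Additive white-noise standard deviations on
#'   the pressure (kPa) and flow (L/s) channels.
#' @return An object of class `ios_impedance_model`.
#' @examples
#' m <- ios_impedance_model(R0 = 0.35, I = 0.00065, C = 0.20)
#' ric_impedance(m, f = 5)       # 0.35 - 0.1387i
#' ric_resonant_frequency(m)     # 13.96 Hz
#' @export
ios_impedance_model <- function(R0, I, C, fdep = 0, dR_exp = 0,
                                noise_sd_p = 0, noise_sd_f = 0) {
  stopifnot_scalar(R0, "R0", positive = TRUE)
  stopifnot_scalar(I, "I", positive = TRUE)
  stopifnot_scalar(C, "C", positive = TRUE)
  stopifnot_scalar(fdep, "fdep")
  stopifnot_scalar(dR_exp, "dR_exp")
  if (noise_sd_p < 0 || noise_sd_f < 0) abort("noise sds must be >= 0")
  structure(
    list(R0 = R0, I = I, C = C, fdep = fdep, dR_exp = dR_exp,
         noise_sd_p = noise_sd_p, noise_sd_f = noise_sd_f),
    class = "ios_impedance_model"
  )
}

#' Closed-form impedance of a generating model
#'
#' @param model An [ios_impedance_model()].
#' @param f Frequencies in Hz.
#' @param expiratory Phase indicator in `[0, 1]` (1 adds the expiratory
#'   resistance increment).
#' @return Complex impedance `Z(f)` in kPa/(L/s).
#' @export
ric_impedance <- function(model, f, expiratory = 0) {
  R <- pmax(model$R0 + model$dR_exp * expiratory - model$fdep * (f - 5), 0.05)
  X <- 2 * pi * f * model$I - 1 / (2 * pi * f * model$C)
  complex(real = R, imaginary = X)
}

#' @rdname ric_impedance
#' @export
ric_resonant_frequency <- function(model) {
  1 / (2 * pi * sqrt(model$I * model$C))
}

#' Tidal breathing pattern
#'
#' Expiration is the positive-flow half of the cycle (expiration-positive
#' convention, matching the recording format).  With
#' `expiratory_fraction != 0.5` the two half-waves are stretched so that
#' expiration occupies that fraction of each cycle while flow stays continuous.
#'
#' @param breath_rate Breaths per minute, in `[6, 30]`.
#' @param tidal_flow_amp Peak tidal flow, L/s.
#' @param expiratory_fraction Fraction of the cycle spent in expiration,
#'   strictly inside (0, 1).
#' @export
breathing_pattern <- function(breath_rate = 15, tidal_flow_amp = 0.5,
                              expiratory_fraction = 0.5) {
  if (breath_rate < 6 || breath_rate > 30) {
    abort("`breath_rate` must lie in [6, 30] breaths/min")
  }
  stopifnot_scalar(tidal_flow_amp, "tidal_flow_amp", positive = TRUE)
  if (expiratory_fraction <= 0 || expiratory_fraction >= 1) {
    abort("`expiratory_fraction` must be strictly inside (0, 1)")
  }
  structure(list(breath_rate = breath_rate, tidal_flow_amp = tidal_flow_amp,
                 expiratory_fraction = expiratory_fraction),
            class = "ios_breathing_pattern")
}

#' Pulse-train excitation
#'
#' The oscillometric pulse train is represented by its first `n_harmonics`
#' cosine components at multiples of the fundamental, with `1/m` amplitude
#' decay by default (the excitation energy is concentrated at the fundamental
#' and its harmonics).  24 harmonics of 2.5 Hz span 2.5-60 Hz.
#'
#' @param f0 Fundamental frequency, Hz.
#' @param n_harmonics Number of harmonics.
#' @param amplitudes Per-harmonic flow amplitudes, L/s.
#' @param phases Per-harmonic phases, radians.
#' @export
excitation_spec <- function(f0 = 2.5, n_harmonics = 24,
                            amplitudes = 0.15 / seq_len(n_harmonics),
                            phases = rep(0, n_harmonics)) {
  stopifnot_scalar(f0, "f0", positive = TRUE)
  if (length(amplitudes) != n_harmonics || length(phases) != n_harmonics) {
    abort("`amplitudes` and `phases` must have length `n_harmonics`")
  }
  structure(list(f0 = f0, n_harmonics = as.integer(n_harmonics),
                 amplitudes = amplitudes, phases = phases),
            class = "ios_excitation_spec")
}

tidal_flow_wave <- function(breathing, t) {
  T_cycle <- 60 / breathing$breath_rate
  e <- breathing$expiratory_fraction
  s <- t %% T_cycle
  amp <- breathing$tidal_flow_amp
  ifelse(s < e * T_cycle,
         amp * sin(pi * s / (e * T_cycle)),
         -amp * sin(pi * (s - e * T_cycle) / ((1 - e) * T_cycle)))
}

#' Synthesize one IOS recording from a known impedance model
#'
#' Flow is the tidal wave plus the excitation harmonics plus white noise.
#' Pressure is built quasi-statically: each harmonic is multiplied by the
#' instantaneous `|Z(f, t)|` and phase-shifted by `arg Z(f, t)` where the
#' resistance carries the expiratory increment, plus the breathing-band
#' pressure `R(t) * tidal flow`, plus white noise.  Identical seeds give
#' bit-identical recordings.
#'
#' @param model An [ios_impedance_model()].
#' @param breathing A [breathing_pattern()].
#' @param excitation An [excitation_spec()].
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, s; `duration * fs` must be at least 9120
#'   samples (the fixed analysis length).
#' @param seed Integer seed for the noise draws (`NULL` for unseeded).
#' @param subject_id Identifier stored with the recording.
#' @return An [ios_recording()].
#' @export
synthesize_recording <- function(model, breathing = breathing_pattern(),
                                 excitation = excitation_spec(),
                                 fs = 400, duration = 24, seed = NULL,
                                 subject_id = "sim") {
  stopifnot(inherits(model, "ios_impedance_model"),
            inherits(breathing, "ios_breathing_pattern"),
            inherits(excitation, "ios_excitation_spec"))
  n <- as.integer(round(duration * fs))
  if (n < .min_tfrim_samples) {
    abort(sprintf(
      "recording too short: %d samples; at least %d samples (%.2f s at %g Hz) are required",
      n, .min_tfrim_samples, .min_tfrim_samples / fs, fs))
  }
  freqs <- excitation$f0 * seq_len(excitation$n_harmonics)
  if (any(freqs > fs / 2)) {
    abort(sprintf("excitation harmonic above Nyquist (%g Hz): %g Hz",
                  fs / 2, max(freqs)))
  }
  t <- (0:(n - 1)) / fs
  tidal <- tidal_flow_wave(breathing, t)
  expir <- as.numeric(tidal > 0)

  flow <- tidal
  pressure <- (model$R0 + model$dR_exp * expir) * tidal
  for (m in seq_len(excitation$n_harmonics)) {
    fm <- freqs[m]
    a <- excitation$amplitudes[m]
    ph <- excitation$phases[m]
    flow <- flow + a * cos(2 * pi * fm * t + ph)
    Rm <- pmax(model$R0 + model$dR_exp * expir - model$fdep * (fm - 5), 0.05)
    Xm <- 2 * pi * fm * model$I - 1 / (2 * pi * fm * model$C)
    mag <- sqrt(Rm^2 + Xm^2)
    arg <- atan2(Xm, Rm)
    pressure <- pressure + a * mag * cos(2 * pi * fm * t + ph + arg)
  }
  if (model$noise_sd_p > 0 || model$noise_sd_f > 0) {
    noise <- with_local_seed(seed, list(p = rnorm(n, 0, model$noise_sd_p),
                                        f = rnorm(n, 0, model$noise_sd_f)))
    pressure <- pressure + noise$p
    flow <- flow + noise$f
  }
  ios_recording(pressure, flow, fs = fs, subject_id = subject_id)
}

demographic_multiplier <- function(age, height) {
  # small baseline shifts (<= 15% of R0): resistance rises with age, falls
  # with height, so demographic calibration carries weak but real signal
  mult <- (1 + 0.10 * (age - 45) / 30) * (1 - 0.08 * (height - 165) / 20)
  pmin(pmax(mult, 0.85), 1.15)
}

#' Draw a group-conditional impedance phenotype
#'
#' Draws `R0`, `X5`, `Fres`, `dR_exp` and `fdep` from group-specific
#' distributions anchored to the published cohort statistics, solves the RIC
#' pair `(I, C)` that realises the drawn `X5` and `Fres`, and applies a small
#' multiplicative demographic baseline shift to `R0` (up with age, down with
#' height).  A latent severity scalar couples the impedance draw to the
#' spirometry ratios drawn by [assign_spirometry_ratios()].
#'
#' Bounded draws are truncated symmetrically about the group mean so that the
#' truncation leaves the target means untouched.
#'
#' @param group `"SAD"` or `"nonSAD"`.
#' @param demographics Optional list/row with `age` (years) and `height` (cm).
#' @param seed Integer seed.
#' @param separation Group-separation factor: within-group spreads (sds of
#'   R5, X5, Fres, dR_exp, fdep) are divided by it.  1 reproduces the
#'   published cohort spreads; larger values give cleaner, easier cohorts
#'   for controlled learnability studies.
#' @return An `ios_impedance_model` with attributes `severity` and `group`.
#' @export
sad_phenotype <- function(group = c("SAD", "nonSAD"), demographics = NULL,
                          seed = NULL, separation = 1) {
  group <- match.arg(group)
  par <- .phenotype_table[[group]]
  par <- scale_spreads(par, separation)
  draw <- with_local_seed(seed, {
    sever <- rnorm(1)
    # R0 shares 70% of its variance with the latent severity
    z <- 0.7 * sever + sqrt(1 - 0.49) * rnorm(1)
    guard <- 0L
    lo <- 0.08
    hi <- 2 * par$R5[1] - lo
    R0 <- par$R5[1] + par$R5[2] * z
    while ((R0 < lo || R0 > hi) && guard < 1000L) {
      z <- 0.7 * sever + sqrt(1 - 0.49) * rnorm(1)
      R0 <- par$R5[1] + par$R5[2] * z
      guard <- guard + 1L
    }
    X5 <- rnorm_trunc(1, par$X5[1], par$X5[2],
                      lo = 2 * par$X5[1] + 0.02, hi = -0.02)
    Fres <- rnorm_trunc(1, par$Fres[1], par$Fres[2],
                        lo = 8.5, hi = 2 * par$Fres[1] - 8.5)
    dR_exp <- rnorm_trunc(1, par$dR_exp[1], par$dR_exp[2], lo = 0)
    fdep <- rnorm_trunc(1, par$fdep[1], par$fdep[2],
                        lo = 0, hi = max((R0 - 0.06) / 55, 0.001))
    list(sever = sever, R0 = R0, X5 = X5, Fres = Fres,
         dR_exp = dR_exp, fdep = fdep)
  })
  if (!is.null(demographics)) {
    draw$R0 <- draw$R0 * demographic_multiplier(demographics$age,
                                                demographics$height)
  }
  # invert X5 = 2*pi*5*I - 1/(2*pi*5*C) and Fres = 1/(2*pi*sqrt(I*C))
  C <- (5 / (2 * pi * draw$Fres^2) - 1 / (10 * pi)) / draw$X5
  I <- 1 / ((2 * pi * draw$Fres)^2 * C)
  model <- ios_impedance_model(R0 = draw$R0, I = I, C = C,
                               fdep = draw$fdep, dR_exp = draw$dR_exp,
                               noise_sd_p = 0.003, noise_sd_f = 0.005)
  attr(model, "severity") <- draw$sever
  attr(model, "group") <- group
  model
}

#' Draw spirometry ratios coupled to phenotype severity
#'
#' The three measured/predicted ratios (FEF25-75, FEF50, FEF75) are drawn from
#' group-conditional normals with published means and sds, truncated to
#' (0.05, 2.0) by resampling, and shifted by the phenotype's latent severity
#' (higher severity, hence higher `R0`, pulls every ratio down) so that
#' waveforms and labels are statistically linked without being deterministic.
#'
#' @param model Phenotype from [sad_phenotype()] (its `severity` attribute is
#'   used; 0 if absent).
#' @param group `"SAD"` or `"nonSAD"`.
#' @param seed Integer seed.
#' @param separation Group-separation factor (see [sad_phenotype()]); spreads
#'   of the ratio draws are divided by it.
#' @return Named numeric vector `c(v1, v2, v3)`.
#' @export
assign_spirometry_ratios <- function(model, group = c("SAD", "nonSAD"),
                                     seed = NULL, separation = 1) {
  group <- match.arg(group)
  par <- .phenotype_table[[group]]
  par <- scale_spreads(par, separation)
  sever <- attr(model, "severity") %||% 0
  w <- 0.6
  with_local_seed(seed, {
    v <- vapply(1:3, function(k) {
      mu <- par$v[[k]][1] - w * par$v[[k]][2] * sever
      rnorm_trunc(1, mu, par$v[[k]][2] * sqrt(1 - w^2), lo = 0.05, hi = 2.0)
    }, numeric(1))
    setNames(v, c("v1", "v2", "v3"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scale_spreads <- function(par, separation) {
  if (separation == 1) return(par)
  if (separation <= 0) abort("`separation` must be > 0")
  for (nm in c("R5", "X5", "Fres", "dR_exp", "fdep")) {
    par[[nm]][2] <- par[[nm]][2] / separation
  }
  par$v <- lapply(par$v, function(x) c(x[1], x[2] / separation))
  par
}

draw_demographics <- function(group) {
  par <- .phenotype_table[[group]]
  list(
    age = round(rnorm_trunc(1, par$age[1], par$age[2], 18, 90), 1),
    sex = as.integer(runif(1) < par$male_frac),
    height = round(rnorm_trunc(1, par$height[1], par$height[2], 140, 195), 1),
    weight = round(rnorm_trunc(1, par$weight[1], par$weight[2], 40, 130), 1)
  )
}

#' Generate a synthetic IOS cohort
#'
#' Writes `n` recording CSV files and a manifest to `out_dir` (when given) and
#' returns the manifest together with the generating ground truth.  Exactly
#' `round(n * sad_fraction)` subjects use the SAD phenotype; the default
#' fraction 0.423 mirrors a 1061/2510 case mix.
#'
#' @param n Number of subjects (>= 2).
#' @param sad_fraction Proportion of SAD phenotypes, strictly inside (0, 1).
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, s.
#' @param seed Cohort seed; every per-subject draw derives from it.
#' @param separation Group-separation factor forwarded to [sad_phenotype()]
#'   and [assign_spirometry_ratios()]; 1 = published spreads.
#' @param out_dir Output directory, or `NULL` to keep recordings in memory.
#' @return A list with `manifest` (tibble, one row per subject, spirometry
#'   ratios included), `truth` (tibble of generating parameters, the test
#'   oracle), and `recordings` (list of [ios_recording()] objects, only when
#'   `out_dir` is `NULL`).
#' @export
generate_cohort <- function(n, sad_fraction = 0.423, fs = 400, duration = 24,
                            seed = 1L, separation = 1, out_dir = NULL) {
  if (n < 2) abort("`n` must be at least 2")
  if (sad_fraction <= 0 || sad_fraction >= 1) {
    abort("`sad_fraction` must be strictly inside (0, 1)")
  }
  n_sad <- as.integer(round(n * sad_fraction))
  plan <- with_local_seed(seed, {
    groups <- sample(c(rep("SAD", n_sad), rep("nonSAD", n - n_sad)))
    subject_seeds <- sample.int(.Machine$integer.max - 10L, 3L * n)
    demos <- lapply(groups, draw_demographics)
    list(groups = groups, seeds = matrix(subject_seeds, ncol = 3L),
         demos = demos)
  })
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  rows <- vector("list", n)
  truth <- vector("list", n)
  recs <- if (is.null(out_dir)) vector("list", n) else NULL
  for (i in seq_len(n)) {
    grp <- plan$groups[i]
    demo <- plan$demos[[i]]
    sid <- sprintf("S%04d", i)
    model <- sad_phenotype(grp, demographics = demo, seed = plan$seeds[i, 1],
                           separation = separation)
    v <- assign_spirometry_ratios(model, grp, seed = plan$seeds[i, 2],
                                  separation = separation)
    rec <- synthesize_recording(model, fs = fs, duration = duration,
                                seed = plan$seeds[i, 3], subject_id = sid)
    path <- NA_character_
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, paste0(sid, ".csv"))
      write_recording(rec, path)
    } else {
      recs[[i]] <- rec
    }
    rows[[i]] <- tibble::tibble(
      subject_id = sid, age_years = demo$age, sex = demo$sex,
      height_cm = demo$height, weight_kg = demo$weight,
      fef2575_ratio = v[["v1"]], fef50_ratio = v[["v2"]],
      fef75_ratio = v[["v3"]], recording_path = path
    )
    truth[[i]] <- tibble::tibble(
      subject_id = sid, group = grp, R0 = model$R0, I = model$I, C = model$C,
      fdep = model$fdep, dR_exp = model$dR_exp,
      severity = attr(model, "severity"),
      Fres_true = ric_resonant_frequency(model)
    )
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }
  out <- list(manifest = manifest, truth = dplyr::bind_rows(truth))
  if (is.null(out_dir)) out$recordings <- recs
  out
}
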