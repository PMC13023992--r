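# File formats.
#
# Recording: 2-column CSV `pressure_kpa,flow_lps` preceded by `#`-prefixed
# header lines carrying `fs_hz` and `subject_id`.  Manifest: CSV with one row
# per subject (demographics, spirometry ratios, recording path).  Cohort-level
# TFRIM tensors are stored as a single RDS container at run time.

#' Two-channel IOS recording
#'
#' @param pressure Oral pressure samples, kPa.
#' @param flow Airflow samples, L/s (expiration positive).
#' @param fs Sampling rate, Hz.
#' @param subject_id Identifier.
#' @return Object of class `ios_recording` with fields `pressure`, `flow`,
#'   `fs`, `n`, `subject_id`.
#' @export
ios_recording <- function(pressure, flow, fs = 400, subject_id = "anon") {
  if (length(pressure) != length(flow)) {
    abort("pressure and flow must have equal length")
  }
  if (!all(is.finite(pressure)) || !all(is.finite(flow))) {
    abort("recording contains non-finite values")
  }
  stopifnot_scalar(fs, "fs", positive = TRUE)
  structure(list(pressure = as.numeric(pressure), flow = as.numeric(flow),
                 fs = fs, n = length(pressure),
                 subject_id = as.character(subject_id)),
            class = "ios_recording")
}

#' @export
print.ios_recording <- function(x, ...) {
  cat(sprintf("<ios_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$n, x$fs, x$n / x$fs))
  invisible(x)
}

#' Read / write recording CSV files
#'
#' The on-disk format is a plain CSV with columns `pressure_kpa,flow_lps` and
#' `#`-prefixed header lines `# fs_hz=<rate>` and `# subject_id=<id>`.
#' Round-tripping preserves samples to float32-like precision (8 significant
#' digits) and metadata exactly.
#'
#' @param path File path.
#' @return [read_recording()] returns an [ios_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("recording file not found: '%s'", path))
  head_lines <- readLines(path, n = 10L)
  hdr <- grep("^#", head_lines, value = TRUE)
  get_field <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*([^,\\s]+)"), hdr))
    hit <- vapply(m, length, integer(1)) == 2L
    if (!any(hit)) return(NA_character_)
    m[hit][[1]][2]
  }
  fs <- suppressWarnings(as.numeric(get_field("fs_hz")))
  if (is.na(fs)) abort(sprintf("'%s': missing `# fs_hz=` header", path))
  sid <- get_field("subject_id")
  if (is.na(sid)) sid <- "anon"
  df <- utils::read.csv(path, comment.char = "#", header = TRUE)
  if (!identical(names(df), c("pressure_kpa", "flow_lps"))) {
    abort(sprintf(
      "'%s': expected columns `pressure_kpa,flow_lps`, found `%s`",
      path, paste(names(df), collapse = ",")))
  }
  if (!all(vapply(df, is.numeric, logical(1))) ||
      !all(is.finite(df$pressure_kpa)) || !all(is.finite(df$flow_lps))) {
    abort(sprintf("'%s': non-finite or non-numeric samples", path))
  }
  ios_recording(df$pressure_kpa, df$flow_lps, fs = fs, subject_id = sid)
}

#' @rdname read_recording
#' @param rec An [ios_recording()].
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ios_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%g, subject_id=%s", rec$fs, rec$subject_id), con)
  writeLines("pressure_kpa,flow_lps", con)
  writeLines(paste(formatC(rec$pressure, format = "g", digits = 8),
                   formatC(rec$flow, format = "g", digits = 8), sep = ","), con)
  invisible(path)
}

.manifest_cols <- c("subject_id", "age_years", "sex", "height_cm", "weight_kg",
                    "fef2575_ratio", "fef50_ratio", "fef75_ratio",
                    "recording_path")

#' Read / write a cohort manifest
#'
#' Schema: `subject_id,age_years,sex,height_cm,weight_kg,fef2575_ratio,
#' fef50_ratio,fef75_ratio,recording_path`.  Sex is accepted as `{M,F}` or
#' `{1,0}` and normalized to male = 1.  Rows with non-positive spirometry
#' ratios, non-positive anthropometrics, or duplicated subject ids (only one
#' eligible record per subject) are rejected with the offending line.
#'
#' @param path Manifest CSV path.
#' @return A tibble of typed subject records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: '%s'", path))
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(.manifest_cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("manifest '%s' is missing columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  df <- df[, .manifest_cols]
  sex_raw <- as.character(df$sex)
  sex <- ifelse(sex_raw %in% c("M", "m", "1"), 1L,
                ifelse(sex_raw %in% c("F", "f", "0"), 0L, NA_integer_))
  if (any(is.na(sex))) {
    abort(sprintf("manifest row %d: unrecognized sex code '%s'",
                  which(is.na(sex))[1], sex_raw[is.na(sex)][1]))
  }
  df$sex <- sex
  for (col in c("age_years", "height_cm", "weight_kg",
                "fef2575_ratio", "fef50_ratio", "fef75_ratio")) {
    bad <- !is.finite(df[[col]]) | df[[col]] <= 0
    if (any(bad)) {
      abort(sprintf("manifest row %d: `%s` must be a positive number (got %s)",
                    which(bad)[1], col, df[[col]][which(bad)[1]]))
    }
  }
  dup <- duplicated(df$subject_id)
  if (any(dup)) {
    abort(sprintf(
      "manifest row %d: duplicate subject_id '%s' (one record per subject)",
      which(dup)[1], df$subject_id[which(dup)[1]]))
  }
  tibble::as_tibble(df)
}

#' @rdname read_manifest
#' @param manifest Tibble/data frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(.manifest_cols, names(manifest))
  if (length(missing) > 0) {
    abort(sprintf("manifest is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  utils::write.csv(manifest[, .manifest_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Save / load a cohort TFRIM store
#'
#' A single-file container holding the stacked `n x 2 x 24 x 48` TFRIM array,
#' the retained frequency axes, window times, per-channel mean coherence,
#' subject ids and the construction parameters.
#'
#' @param store List as produced by [build_cohort_tfrim()].
#' @param path Destination path (`.rds`).
#' @export
write_tfrim_store <- function(store, path) {
  stopifnot(is.list(store), !is.null(store$tfrim))
  saveRDS(store, path)
  invisible(path)
}

#' @rdname write_tfrim_store
#' @export
read_tfrim_store <- function(path) {
  if (!file.exists(path)) abort(sprintf("TFRIM store not found: '%s'", path))
  readRDS(path)
}

# ---- configuration ---------------------------------------------------------

#' Default pipeline configuration
#'
#' Nested configuration for every stage.  Defaults match the published
#' pipeline constants where one exists: fs 400 Hz, 4-s Hamming window, 0.4-s
#' hop, coherence threshold 0.90, 24 retained channels, soft-label scale 20,
#' abnormality threshold 0.65, probability threshold 0.5, Adam at 1e-4,
#' batch 256, 5 folds.
#'
#' @return Nested list with blocks `simulate`, `tfrim`, `network`, `labels`,
#'   `training`.
#' @export
default_config <- function() {
  list(
    simulate = list(fs = 400, duration = 24, sad_fraction = 0.423),
    tfrim = list(window_s = 4.0, hop_s = 0.4, subsegment_s = 0.8,
                 subsegment_overlap = 0.5, gamma_th = 0.90, n_channels = 24L,
                 f_min = 2.0, highpass_hz = 1.2, crop_samples = 9120L),
    network = list(stem_channels = 32L, branch_width1 = 32L,
                   branch_width2 = 64L, cbam_reduction = 8L,
                   temporal_channels = 64L, state_size = 16L,
                   demo_hidden = c(32L, 64L, 64L), head_hidden = 64L,
                   dropout = 0.3),
    labels = list(vth = 0.65, lam = 20, tau = 0.5),
    training = list(lr = 1e-4, batch_size = 256L, patience = 10L,
                    max_epochs = 200L, folds = 5L, val_fraction = 0.1,
                    seed = 1L)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (when given), overlays it on [default_config()], and
#' schema-checks the values that have hard constraints.
#'
#' @param path YAML path or `NULL` for the defaults.
#' @param overrides Optional nested list applied after the file.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: '%s'", path))
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  tf <- cfg$tfrim
  if (tf$gamma_th <= 0 || tf$gamma_th > 1) {
    abort("tfrim$gamma_th must lie in (0, 1]")
  }
  if (tf$window_s <= 0 || tf$hop_s <= 0 || tf$subsegment_s <= 0) {
    abort("tfrim window/hop/subsegment lengths must be positive")
  }
  if (tf$subsegment_s > tf$window_s) {
    abort("tfrim$subsegment_s cannot exceed tfrim$window_s")
  }
  lb <- cfg$labels
  if (lb$vth <= 0) abort("labels$vth must be > 0")
  if (lb$lam <= 0) abort("labels$lam must be > 0")
  if (lb$tau <= 0 || lb$tau >= 1) abort("labels$tau must be inside (0, 1)")
  tr <- cfg$training
  if (tr$lr <= 0) abort("training$lr must be > 0")
  if (tr$folds < 2) abort("training$folds must be >= 2")
  invisible(cfg)
}

#' @rdname load_config
#' @param cfg Configuration list.
#' @param path Destination YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
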