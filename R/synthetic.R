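#' Configuration for the synthetic paired-recording generator
#'
#' Describes one simulated exercise record: a periodic limb motion repeated
#' `n_reps` times, sampled by a 3-axis accelerometer. The waveform template
#' per axis is a fundamental at `rep_freq` plus a second harmonic at half
#' amplitude, Hann-windowed per repetition so each repetition starts and ends
#' at rest; white Gaussian sensor noise and an optional slow (0.05 Hz)
#' baseline drift are added on top. The right-side record carries the
#' template with amplitude scaled by `1 + asym_amp` and frequency scaled by
#' `1 + asym_freq`, so the generated pair has a known, controllable degree of
#' left/right asymmetry.
#'
#' @param fs sampling rate, Hz (default 100).
#' @param n_reps repetitions per record (default 10).
#' @param rep_freq dominant motion frequency, Hz (default 0.5, i.e. one
#'   repetition every 2 s; typical exercise cadence lies in 0.3--2 Hz).
#' @param amp base motion amplitude, m/s^2 (default 2).
#' @param asym_amp fractional right/left amplitude difference, >= 0.
#' @param asym_freq fractional right/left frequency shift, >= 0.
#' @param noise_sd additive white-noise standard deviation, m/s^2.
#' @param drift amplitude of a 0.05 Hz baseline sinusoid common to both
#'   sides (default 0 = off).
#' @param seed RNG seed; identical seed and config reproduce every sample.
#' @param duration_s record length in seconds; defaults to
#'   `n_reps / rep_freq` so the record holds exactly `n_reps` repetitions.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(fs = 100, n_reps = 10, rep_freq = 0.5, amp = 2,
                         asym_amp = 0, asym_freq = 0, noise_sd = 0.2,
                         drift = 0, seed = 1, duration_s = n_reps / rep_freq) {
  cfg <- list(fs = fs, n_reps = n_reps, rep_freq = rep_freq, amp = amp,
              asym_amp = asym_amp, asym_freq = asym_freq, noise_sd = noise_sd,
              drift = drift, seed = seed, duration_s = duration_s)
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!num1(fs) || fs <= 0) stop_field("fs", "must be a positive number")
  if (!num1(n_reps) || n_reps < 1) stop_field("n_reps", "must be >= 1")
  if (!num1(rep_freq) || rep_freq <= 0) stop_field("rep_freq", "must be positive")
  if (rep_freq >= fs / 4) stop_field("rep_freq", "must be below fs/4 to resolve the 2nd harmonic")
  if (!num1(amp) || amp <= 0) stop_field("amp", "must be positive")
  if (!num1(asym_amp) || asym_amp < 0) stop_field("asym_amp", "must be >= 0")
  if (!num1(asym_freq) || asym_freq < 0) stop_field("asym_freq", "must be >= 0")
  if (!num1(noise_sd) || noise_sd < 0) stop_field("noise_sd", "must be >= 0")
  if (!num1(drift) || drift < 0) stop_field("drift", "must be >= 0")
  if (!num1(duration_s) || duration_s <= 0) stop_field("duration_s", "must be positive")
  structure(cfg, class = "synth_config")
}

# Per-axis weights and phases of the motion template: the three axes see the
# same limb motion projected differently, so they share frequency content
# but differ in amplitude and phase.
axis_weights <- c(1, 0.8, 0.6)
axis_phases <- c(0, 2 * pi / 3, 4 * pi / 3)

# Deterministic (noise-free) motion template for one side.
synth_template <- function(t, freq, amp) {
  env <- sin(pi * freq * t)^2  # Hann window per repetition period 1/freq
  vapply(1:3, function(ax) {
    ph <- axis_phases[ax]
    amp * axis_weights[ax] * env *
      (sin(2 * pi * freq * t + ph) + 0.5 * sin(4 * pi * freq * t + 2 * ph))
  }, numeric(length(t)))
}

#' Generate one synthetic left/right recording pair
#'
#' Both sides share the same repetition-windowed waveform template; the right
#' side's template is scaled in amplitude by `1 + asym_amp` and in frequency
#' by `1 + asym_freq`. Noise realizations are independent between sides. With
#' `asym_amp = asym_freq = 0` and `noise_sd = 0` the two traces are identical
#' sample-by-sample; with `noise_sd = 0` the right/left RMS ratio equals
#' `1 + asym_amp` exactly.
#'
#' @param config a [synth_config()].
#' @param individual_id,exercise_id labels attached to both recordings.
#' @return A list with elements `L` and `R`, each an [accel_recording()].
#' @export
generate_pair <- function(config = synth_config(), individual_id = NA_character_,
                          exercise_id = NA_character_) {
  stopifnot(inherits(config, "synth_config"))
  n <- floor(config$duration_s * config$fs)
  t <- (seq_len(n) - 1L) / config$fs
  f_l <- config$rep_freq
  f_r <- config$rep_freq * (1 + config$asym_freq)
  base_l <- synth_template(t, f_l, config$amp)
  base_r <- synth_template(t, f_r, config$amp * (1 + config$asym_amp))
  drift_term <- if (config$drift > 0) config$drift * sin(2 * pi * 0.05 * t) else 0
  with_seed(config$seed, {
    noise_l <- matrix(rnorm(3L * n, sd = config$noise_sd), n, 3L)
    noise_r <- matrix(rnorm(3L * n, sd = config$noise_sd), n, 3L)
    list(
      L = accel_recording(t, base_l + drift_term + noise_l, config$fs, side = "L",
                          exercise_id = exercise_id, individual_id = individual_id),
      R = accel_recording(t, base_r + drift_term + noise_r, config$fs, side = "R",
                          exercise_id = exercise_id, individual_id = individual_id)
    )
  })
}

#' Generate a labeled synthetic cohort
#'
#' Produces one left/right pair per (individual, exercise) cell with
#' per-individual asymmetry, mirroring a study design of several individuals
#' each performing a catalogue of exercises. Per-cell seeds are drawn
#' deterministically from the master seed in `config$seed`, so the same
#' master seed reproduces the entire cohort exactly.
#'
#' @param n_individuals number of individuals (0 allowed: empty cohort).
#' @param asymmetry list of length `n_individuals`; each element a numeric
#'   pair `c(asym_amp, asym_freq)` for that individual.
#' @param config base [synth_config()]; its `asym_*` fields are overridden
#'   per individual.
#' @param exercises character vector of exercise labels (default E1--E8).
#' @return A list of class `synth_cohort`: elements with fields
#'   `individual_id`, `exercise_id`, `asym_amp`, `asym_freq`, `pair`.
#' @export
generate_cohort <- function(n_individuals, asymmetry,
                            config = synth_config(),
                            exercises = paste0("E", 1:8)) {
  if (n_individuals == 0L) return(structure(list(), class = "synth_cohort"))
  if (length(asymmetry) != n_individuals) {
    stop_field("asymmetry", sprintf("length %d does not match n_individuals = %d",
                                    length(asymmetry), n_individuals))
  }
  n_cells <- n_individuals * length(exercises)
  seeds <- with_seed(config$seed, sample.int(2147483646L, n_cells))
  out <- vector("list", n_cells)
  k <- 0L
  for (i in seq_len(n_individuals)) {
    delta <- asymmetry[[i]]
    if (length(delta) != 2L || any(delta < 0)) {
      stop_field("asymmetry", sprintf("element %d must be a non-negative pair", i))
    }
    for (ex in exercises) {
      k <- k + 1L
      cfg <- config
      cfg$asym_amp <- delta[[1L]]
      cfg$asym_freq <- delta[[2L]]
      cfg$seed <- seeds[[k]]
      ind <- sprintf("S%02d", i)
      out[[k]] <- list(individual_id = ind, exercise_id = ex,
                       asym_amp = delta[[1L]], asym_freq = delta[[2L]],
                       pair = generate_pair(cfg, individual_id = ind, exercise_id = ex))
    }
  }
  structure(out, class = "synth_cohort")
}

#' Write a synthetic cohort to disk as recording files plus a manifest
#'
#' Uses the same delimited-text format as [write_recording()], so synthetic
#' cohorts are indistinguishable from imported data downstream.
#'
#' @param cohort a `synth_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(cell) {
    do.call(rbind, lapply(c("L", "R"), function(s) {
      fname <- sprintf("%s_%s_%s.csv", cell$individual_id, cell$exercise_id, s)
      write_recording(cell$pair[[s]], file.path(dir, fname))
      data.frame(individual_id = cell$individual_id, exercise_id = cell$exercise_id,
                 side = s, path = fname, stringsAsFactors = FALSE)
    }))
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  write.table(manifest, manifest_path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}
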