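# Synthetic vibroacoustic data generator. The bone-implant transfer path is
# emulated as a small set of damped resonant modes; loosening is modeled as
# (i) downshifted, less-damped modes, (ii) odd-harmonic "rattle" distortion
# from intermittent screw-bone contact, and (iii) added broadband
# high-frequency content -- together reproducing the empirical signature
# that loose recordings carry more high-frequency and more distributed
# spectral energy than fixed ones. All magnitudes are free parameters with
# documented defaults; they are stand-ins, not cadaver-validated values.

#' Resonant mode set
#'
#' @param center_frequency numeric vector of mode frequencies in Hz, each in
#'   (20, 4000).
#' @param damping_ratio numeric vector of damping ratios in (0.005, 0.2).
#' @param gain numeric vector of modal gains (dimensionless).
#' @return an object of class `mode_set`.
#' @export
mode_set <- function(center_frequency, damping_ratio, gain) {
  if (length(center_frequency) < 3)
    vs_stop("a mode set needs at least 3 modes", "vibroscrew_config_error")
  if (length(damping_ratio) != length(center_frequency) ||
      length(gain) != length(center_frequency))
    vs_stop("mode set fields must have equal length",
            "vibroscrew_config_error")
  if (any(center_frequency <= 20 | center_frequency >= 4000))
    vs_stop("mode frequencies must lie in (20, 4000) Hz",
            "vibroscrew_config_error")
  if (any(damping_ratio <= 0.005 | damping_ratio >= 0.2))
    vs_stop("damping ratios must lie in (0.005, 0.2)",
            "vibroscrew_config_error")
  structure(list(center_frequency = center_frequency,
                 damping_ratio = damping_ratio, gain = gain),
            class = "mode_set")
}

# nominal transfer path shared by all specimens before per-specimen jitter:
# a handful of low/mid resonances reachable by the 10-500 Hz sweep plus
# weaker high modes
default_mode_set <- function() {
  mode_set(center_frequency = c(90, 180, 320, 520, 900, 1500),
           damping_ratio   = c(0.03, 0.035, 0.04, 0.05, 0.06, 0.07),
           gain            = c(1.0, 0.8, 0.6, 0.5, 0.35, 0.25))
}

#' Sample a specimen's transfer-path profile
#'
#' Perturbs the nominal mode set deterministically per (specimen, master
#' seed): mode frequencies jittered by up to +/-8%, damping scaled by a
#' bone-quality factor, gains jittered by up to +/-20%. Distinct specimens
#' receive distinct perturbations, emulating inter-specimen anatomical and
#' bone-quality variation.
#'
#' @param specimen_id integer specimen identifier (0-3 in the default
#'   design).
#' @param master_seed integer master seed.
#' @param base optional [mode_set()] to perturb.
#' @return an object of class `specimen_profile`.
#' @export
sample_specimen_profile <- function(specimen_id, master_seed,
                                    base = default_mode_set()) {
  seed <- derive_seed(master_seed, 101L, specimen_id)
  k <- length(base$center_frequency)
  with_seed(seed, {
    freq_jit <- runif(k, -0.08, 0.08)
    damp_fac <- runif(1, 0.8, 1.25)
    gain_jit <- runif(k, 0.8, 1.2)
  })
  modes <- mode_set(base$center_frequency * (1 + freq_jit),
                    pmin(pmax(base$damping_ratio * damp_fac, 0.006), 0.19),
                    base$gain * gain_jit)
  structure(list(specimen_id = specimen_id, modes = modes,
                 bone_quality_factor = damp_fac, rng_seed = seed),
            class = "specimen_profile")
}

#' Loosening condition effect
#'
#' Parameterizes how the loose condition differs from fixed. All contrasts
#' scale linearly with `separation`: at 0 the two conditions are
#' distributionally identical, at 1 the default contrasts apply.
#'
#' @param mode_shift fractional mode-frequency change in the loose
#'   condition (negative = downshift).
#' @param damping_scale multiplier (< 1) on damping ratios when loose
#'   (sharper, longer-ringing resonances).
#' @param rattle_gain amplitude of odd-harmonic waveshaping distortion.
#' @param broadband_hf_gain gain of added high-passed broadband noise,
#'   relative to the RMS of the propagated signal.
#' @param separation scalar in `[0, 1]` scaling all loose-vs-fixed
#'   contrasts.
#' @return an object of class `condition_effect`.
#' @export
condition_effect <- function(mode_shift = -0.12, damping_scale = 0.7,
                             rattle_gain = 0.1, broadband_hf_gain = 0.15,
                             separation = 1) {
  if (separation < 0 || separation > 1)
    vs_stop("separation must lie in [0, 1]", "vibroscrew_config_error")
  structure(list(mode_shift = mode_shift, damping_scale = damping_scale,
                 rattle_gain = rattle_gain,
                 broadband_hf_gain = broadband_hf_gain,
                 separation = separation),
            class = "condition_effect")
}

#' Study design
#'
#' Defaults reproduce the cadaveric study counts: 4 specimens x 2 screws x
#' 2 conditions x 50 sweeps = 800 recordings, 200 per specimen. One sensor
#' per screw (`sensor_id == screw_id`).
#'
#' @param n_specimens number of specimens.
#' @param screws_per_specimen screws (and sensors) per specimen.
#' @param sweeps_per_screw sweeps recorded per screw and condition.
#' @param noise_snr_db measurement signal-to-noise ratio in dB.
#' @param master_seed integer master seed for all randomness.
#' @return an object of class `study_design`.
#' @export
study_design <- function(n_specimens = 4L, screws_per_specimen = 2L,
                         sweeps_per_screw = 50L, noise_snr_db = 30,
                         master_seed = 20240101L) {
  if (n_specimens < 1 || screws_per_specimen < 1 || sweeps_per_screw < 1)
    vs_stop("study design counts must be positive",
            "vibroscrew_config_error")
  structure(list(n_specimens = as.integer(n_specimens),
                 screws_per_specimen = as.integer(screws_per_specimen),
                 sweeps_per_screw = as.integer(sweeps_per_screw),
                 conditions = c("fixed", "loose"),
                 noise_snr_db = noise_snr_db,
                 master_seed = as.integer(master_seed)),
            class = "study_design")
}

#' Impulse response of a mode set
#'
#' Sum of exponentially damped sinusoids, one per mode: mode `j`
#' contributes `gain_j * exp(-zeta_j w_j t) * sin(w_j sqrt(1-zeta_j^2) t)`.
#'
#' @param modes a [mode_set()].
#' @param sample_rate sampling rate in Hz.
#' @param length_samples response length in samples (> 0).
#' @return numeric waveform of `length_samples` samples.
#' @export
impulse_response <- function(modes, sample_rate, length_samples) {
  if (length_samples <= 0)
    vs_stop("length must be > 0", "vibroscrew_config_error")
  if (!inherits(modes, "mode_set"))
    vs_stop("modes must be a mode_set", "vibroscrew_config_error")
  t <- (seq_len(length_samples) - 1) / sample_rate
  h <- numeric(length_samples)
  for (j in seq_along(modes$center_frequency)) {
    wn <- 2 * pi * modes$center_frequency[j]
    z <- modes$damping_ratio[j]
    wd <- wn * sqrt(1 - z^2)
    h <- h + modes$gain[j] * exp(-z * wn * t) * sin(wd * t)
  }
  h
}

# FFT-based linear convolution, truncated to length(x)
fft_convolve_same <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- 2^ceiling(log2(n))
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
                fft(c(h, numeric(nfft - length(h)))), inverse = TRUE)) / nfft
  y[seq_along(x)]
}

# apply the condition effect to a specimen's modes
condition_modes <- function(modes, condition, effect) {
  if (condition == "fixed") return(modes)
  s <- effect$separation
  mode_set(modes$center_frequency * (1 + s * effect$mode_shift),
           pmin(pmax(modes$damping_ratio *
                       (1 + s * (effect$damping_scale - 1)), 0.006), 0.19),
           modes$gain)
}

#' Simulate the sensor response to a sweep
#'
#' Convolves the excitation with the condition-adjusted impulse response of
#' the specimen's transfer path; in the loose condition adds odd-harmonic
#' waveshaping (scaled by `rattle_gain`) and high-passed broadband noise
#' (scaled by `broadband_hf_gain`), then measurement noise at `snr_db`.
#' The output is trimmed to the sweep length and peak-limited to full
#' scale.
#'
#' @param sweep a [recording()] holding the excitation.
#' @param profile a [sample_specimen_profile()] result.
#' @param condition `"fixed"` or `"loose"`.
#' @param effect a [condition_effect()].
#' @param snr_db measurement SNR in dB (`Inf` for noiseless).
#' @param seed integer seed for this record's noise draws.
#' @param meta optional metadata list attached to the output recording.
#' @param ir optional explicit impulse response overriding the profile
#'   (used to probe the linear path in isolation, e.g. `ir = 1` for an
#'   identity system).
#' @return a [recording()] of the same length as the sweep.
#' @export
simulate_recording <- function(sweep, profile, condition, effect,
                               snr_db = 30, seed = 1L, meta = NULL,
                               ir = NULL) {
  if (!inherits(sweep, "recording"))
    vs_stop("sweep must be a recording", "vibroscrew_input_error")
  if (!condition %in% c("fixed", "loose"))
    vs_stop("condition must be 'fixed' or 'loose'", "vibroscrew_input_error")
  x <- sweep$samples
  sr <- sweep$sample_rate
  n <- length(x)
  if (is.null(ir)) {
    modes <- condition_modes(profile$modes, condition, effect)
    ir_len <- min(n, round(sr * 1.0))
    h <- impulse_response(modes, sr, ir_len)
    h <- h / sum(abs(h)) * 20 # normalize path gain
    y <- fft_convolve_same(x, h)
  } else {
    y <- fft_convolve_same(x, ir)
  }
  s <- effect$separation
  with_seed(seed, {
    if (condition == "loose" && s > 0) {
      peak <- max(abs(y))
      if (peak > 0) {
        yn <- y / peak
        y <- y + s * effect$rattle_gain * peak * yn^3
      }
      if (effect$broadband_hf_gain > 0) {
        bf <- signal::butter(4, min(0.95, 800 / (sr / 2)), type = "high")
        hf <- signal::filtfilt(bf, rnorm(n))
        hf <- hf / sqrt(mean(hf^2))
        y <- y + s * effect$broadband_hf_gain * sqrt(mean(y^2)) * hf
      }
    }
    if (is.finite(snr_db)) {
      noise <- rnorm(n)
      y <- y + sqrt(mean(y^2) / 10^(snr_db / 10)) * noise
    }
  })
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak * 0.99
  recording(y, sr, sweep$bit_depth, meta = meta)
}

#' Generate a complete synthetic dataset
#'
#' Writes one WAV per (specimen, screw, condition, sweep) cell of the
#' design plus a `manifest.csv` with provenance. Per-sweep shaker
#' replacement variability is emulated by a small random gain (+/-5%) and
#' onset-delay (0-3 ms) jitter on the excitation. Everything derives
#' deterministically from `design$master_seed`; fixed and loose records of
#' the same (specimen, screw, sweep) share their noise seed, so at
#' `separation = 0` they are identical.
#'
#' @param design a [study_design()].
#' @param effect a [condition_effect()].
#' @param out_dir output directory (created if missing).
#' @param excitation an [excitation_config()].
#' @param write_audio if `FALSE`, skip the WAV writes and return the
#'   manifest with in-memory recordings attached as the `"recordings"`
#'   attribute (used for fast in-memory analysis).
#' @return the manifest `data.frame` (invisibly also written to
#'   `out_dir/manifest.csv` when `write_audio` is `TRUE`).
#' @export
generate_dataset <- function(design = study_design(),
                             effect = condition_effect(),
                             out_dir,
                             excitation = excitation_config(),
                             write_audio = TRUE) {
  if (write_audio) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  }
  sweep0 <- generate_sweep(excitation)
  n <- length(sweep0$samples)
  rows <- list()
  recs <- list()
  i <- 0L
  for (sp in seq_len(design$n_specimens) - 1L) {
    profile <- sample_specimen_profile(sp, design$master_seed)
    for (sc in seq_len(design$screws_per_specimen)) {
      for (sw in seq_len(design$sweeps_per_screw)) {
        # shaker lift-and-replace jitter: shared by both conditions of a
        # sweep so the condition contrast is the only systematic difference
        jseed <- derive_seed(design$master_seed, 202L, sp, sc, sw)
        jit <- with_seed(jseed, list(gain = runif(1, 0.95, 1.05),
                                     delay = runif(1, 0, 0.003)))
        d <- round(jit$delay * sweep0$sample_rate)
        x <- c(numeric(d), sweep0$samples * jit$gain)[seq_len(n)]
        sweep <- recording(x, sweep0$sample_rate, sweep0$bit_depth)
        for (cond in design$conditions) {
          i <- i + 1L
          meta <- list(specimen_id = sp, screw_id = sc, sensor_id = sc,
                       condition = cond, sweep_index = sw)
          rseed <- derive_seed(design$master_seed, 303L, sp, sc, sw)
          rec <- simulate_recording(sweep, profile, cond, effect,
                                    snr_db = design$noise_snr_db,
                                    seed = rseed, meta = meta)
          fname <- recording_filename(meta)
          path <- if (write_audio) file.path(out_dir, fname) else fname
          if (write_audio) {
            ok <- tryCatch({ write_recording(rec, path); TRUE },
                           error = function(e) e)
            if (!isTRUE(ok)) {
              unlink(file.path(out_dir,
                               vapply(rows, function(r) basename(r$path),
                                      character(1))))
              vs_stop(sprintf("I/O failure writing %s: %s", path,
                              conditionMessage(ok)),
                      "vibroscrew_io_error")
            }
          } else {
            recs[[i]] <- rec
          }
          rows[[i]] <- data.frame(path = path, specimen_id = sp,
                                  screw_id = sc, sensor_id = sc,
                                  condition = cond, sweep_index = sw,
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  check_manifest_unique(manifest)
  if (write_audio) {
    write_manifest(manifest, file.path(out_dir, "manifest.csv"),
                   provenance = c(master_seed = design$master_seed,
                                  config_digest = config_digest(
                                    list(unclass(design), unclass(effect),
                                         unclass(excitation)))))
  } else {
    attr(manifest, "recordings") <- recs
  }
  manifest
}

#' Trajectory simulation configuration
#'
#' Emulates the flexion-extension validation protocol: cyclic motion at 5
#' degrees/s, 30 cycles by default, with the rods following vertebra L2
#' plus a cyclic relative micro-motion whose amplitude is multiplied by
#' `loosening_gain` in the loose condition.
#'
#' @param n_cycles number of flexion-extension cycles (30-50 typical).
#' @param angular_speed degrees per second of the applied motion.
#' @param range_of_motion total angular excursion per half-cycle, degrees.
#' @param base_relative_amplitude implant-vertebra relative movement
#'   amplitude in mm in the fixed condition.
#' @param loosening_gain multiplier (> 1) on the relative amplitude when
#'   loose.
#' @param tracking_noise_sd tracking noise standard deviation in mm per
#'   coordinate.
#' @param sample_rate tracking sampling rate in Hz.
#' @return an object of class `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(n_cycles = 30L, angular_speed = 5,
                                  range_of_motion = 40,
                                  base_relative_amplitude = 1,
                                  loosening_gain = 3,
                                  tracking_noise_sd = 0.05,
                                  sample_rate = 20) {
  if (loosening_gain <= 0)
    vs_stop("loosening_gain must be > 0", "vibroscrew_config_error")
  structure(list(n_cycles = as.integer(n_cycles),
                 angular_speed = angular_speed,
                 range_of_motion = range_of_motion,
                 base_relative_amplitude = base_relative_amplitude,
                 loosening_gain = loosening_gain,
                 tracking_noise_sd = tracking_noise_sd,
                 sample_rate = sample_rate),
            class = "trajectory_sim_config")
}

#' Simulate tracked flexion-extension trajectories
#'
#' Returns synchronized reference-point trajectories for vertebra L2 and
#' both rods. Each rod sits at a fixed offset from the L2 reference point
#' along its micro-motion axis and oscillates along that axis with the load
#' cycle; the oscillation amplitude is `base_relative_amplitude`
#' (times `loosening_gain` when `condition = "loose"`). Because the offset
#' is collinear with the motion, the implant-vertebra distance is the
#' offset plus the scalar micro-motion, so the downstream centered mean
#' absolute movement scales exactly linearly with the amplitude -- in the
#' noiseless case the loose/fixed ratio recovers `loosening_gain` to
#' machine precision.
#'
#' @param config a [trajectory_sim_config()].
#' @param condition `"fixed"` or `"loose"`.
#' @param seed integer seed (tracking noise only).
#' @return named list of three `tracked_trajectory` objects: `L2`, `rod1`,
#'   `rod2`.
#' @export
simulate_trajectories <- function(config = trajectory_sim_config(),
                                  condition = c("fixed", "loose"),
                                  seed = 1L) {
  condition <- match.arg(condition)
  # one full cycle spans 2 * range_of_motion degrees of travel
  cycle_period <- 2 * config$range_of_motion / config$angular_speed
  duration <- config$n_cycles * cycle_period
  t <- seq(0, duration, by = 1 / config$sample_rate)
  ang <- config$range_of_motion / 2 * pi / 180 *
    sin(2 * pi * t / cycle_period)
  # L2 reference point rides on the flexing segment: an arc of radius
  # ~150 mm about the potting fixture
  radius <- 150
  l2 <- cbind(x = radius * sin(ang),
              y = numeric(length(t)),
              z = radius * (1 - cos(ang)))
  amp <- config$base_relative_amplitude *
    if (condition == "loose") config$loosening_gain else 1
  make_rod <- function(axis, offset_mm, phase, noise_seed) {
    u <- axis / sqrt(sum(axis^2))
    s <- amp * sin(2 * pi * t / cycle_period + phase)
    pos <- l2 + outer(offset_mm + s, u)
    if (config$tracking_noise_sd > 0) {
      pos <- pos + with_seed(noise_seed,
                             matrix(rnorm(length(pos), 0,
                                          config$tracking_noise_sd),
                                    ncol = 3))
    }
    pos
  }
  rod1 <- make_rod(c(0, 1, 0.2), 25, 0, derive_seed(seed, 1L))
  rod2 <- make_rod(c(0, -1, 0.2), 25, pi / 6, derive_seed(seed, 2L))
  if (config$tracking_noise_sd > 0) {
    l2 <- l2 + with_seed(derive_seed(seed, 3L),
                         matrix(rnorm(length(l2), 0,
                                      config$tracking_noise_sd), ncol = 3))
  }
  list(L2 = tracked_trajectory(t, l2, "L2"),
       rod1 = tracked_trajectory(t, rod1, "rod1"),
       rod2 = tracked_trajectory(t, rod2, "rod2"))
}
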