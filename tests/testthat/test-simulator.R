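# Synthetic transfer-path, recording and trajectory generators.

test_that("specimen profiles are deterministic and pairwise distinct", {
  p1 <- sample_specimen_profile(0, 42)
  p2 <- sample_specimen_profile(0, 42)
  expect_identical(p1, p2)

  profs <- lapply(0:3, sample_specimen_profile, master_seed = 42)
  freqs <- lapply(profs, function(p) p$modes$center_frequency)
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(isTRUE(all.equal(freqs[[i]], freqs[[j]])))

  expect_false(isTRUE(all.equal(
    sample_specimen_profile(0, 42)$modes$center_frequency,
    sample_specimen_profile(0, 43)$modes$center_frequency)))
})

test_that("impulse response peaks at the damped natural frequency", {
  m <- mode_set(c(100, 300, 900), c(0.05, 0.05, 0.05), c(1, 0, 0))
  h <- impulse_response(m, 44100, 44100)
  fd <- 100 * sqrt(1 - 0.05^2)
  expect_lt(abs(dominant_freq(h, 44100) - fd), 2)
})

test_that("impulse response is linear in the gains and decays", {
  m <- mode_set(c(90, 180, 320), c(0.03, 0.04, 0.05), c(1, 0.5, 0.2))
  m2 <- mode_set(m$center_frequency, m$damping_ratio, 2 * m$gain)
  h1 <- impulse_response(m, 8000, 8000)
  h2 <- impulse_response(m2, 8000, 8000)
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
  # decays below 1% of peak well within 5 time constants
  tail_max <- max(abs(h1[6000:8000]))
  expect_lt(tail_max, 0.01 * max(abs(h1)))
  expect_error(mode_set(c(100, 200), c(0.05, 0.05), c(1, 1)),
               class = "vibroscrew_config_error") # < 3 modes
  expect_error(impulse_response(m, 8000, 0),
               class = "vibroscrew_config_error")
})

test_that("zero separation nulls the condition contrast", {
  sw <- generate_sweep(tiny_excitation())
  prof <- sample_specimen_profile(1, 9)
  e0 <- condition_effect(separation = 0)
  a <- simulate_recording(sw, prof, "fixed", e0, seed = 5)
  b <- simulate_recording(sw, prof, "loose", e0, seed = 5)
  expect_identical(a$samples, b$samples)
})

test_that("rattle distortion adds a third harmonic to a pure tone", {
  sr <- 44100
  tone <- recording(0.8 * sin(2 * pi * 100 * (0:sr) / sr), sr)
  prof <- sample_specimen_profile(0, 1)
  eff <- condition_effect(rattle_gain = 0.2, broadband_hf_gain = 0)
  out <- simulate_recording(tone, prof, "loose", eff, snr_db = Inf,
                            seed = 1, ir = 1)
  p <- Mod(stats::fft(out$samples))^2
  f <- (seq_along(p) - 1) * sr / length(p)
  band <- function(f0) sum(p[f > f0 - 5 & f < f0 + 5])
  # third harmonic well above the (empty) noise floor around it
  expect_gt(band(300), 1e4 * sum(p[f > 350 & f < 450]))
})

test_that("a unit-impulse path with no noise is the identity system", {
  sw <- generate_sweep(tiny_excitation())
  prof <- sample_specimen_profile(0, 1)
  out <- simulate_recording(sw, prof, "fixed", condition_effect(),
                            snr_db = Inf, seed = 1, ir = 1)
  expect_equal(out$samples, sw$samples, tolerance = 1e-9)
})

test_that("generate_dataset reproduces the design counts", {
  d <- withr::local_tempdir()
  design <- study_design(n_specimens = 1L, screws_per_specimen = 1L,
                         sweeps_per_screw = 2L, master_seed = 3L)
  man <- generate_dataset(design, condition_effect(), d,
                          excitation = tiny_excitation())
  expect_equal(nrow(man), 4) # 1 x 1 x 2 conditions x 2 sweeps
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  rescan <- build_manifest(d)
  expect_equal(nrow(rescan), 4)

  # bit-identical reruns from the same master seed
  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(design, condition_effect(), d2,
                           excitation = tiny_excitation())
  r1 <- read_recording(man$path[1])
  r2 <- read_recording(man2$path[1])
  expect_identical(r1$samples, r2$samples)
})

test_that("loose recordings carry more high-band energy than fixed", {
  sw <- generate_sweep(tiny_excitation())
  eff <- condition_effect()
  wins <- 0
  n_pairs <- 20
  for (i in seq_len(n_pairs)) {
    prof <- sample_specimen_profile(i %% 4, 77)
    seed <- derive_seed(77, i)
    fx <- simulate_recording(sw, prof, "fixed", eff, seed = seed)
    lo <- simulate_recording(sw, prof, "loose", eff, seed = seed)
    hf_f <- high_band_fraction(fx$samples, sw$sample_rate)
    hf_l <- high_band_fraction(lo$samples, sw$sample_rate)
    wins <- wins + (hf_l > hf_f)
  }
  p <- stats::binom.test(wins, n_pairs, 0.5, alternative = "greater")$p.value
  expect_lt(p, 0.01)
})

test_that("trajectories are deterministic and recover the loosening gain", {
  cfg <- trajectory_sim_config(tracking_noise_sd = 0, loosening_gain = 3)
  a <- simulate_trajectories(cfg, "loose", seed = 4)
  b <- simulate_trajectories(cfg, "loose", seed = 4)
  expect_identical(a, b)

  fx <- simulate_trajectories(cfg, "fixed", seed = 4)
  lo <- simulate_trajectories(cfg, "loose", seed = 4)
  xf <- centered_mean_abs(relative_movement(fx$L2, fx$rod1))
  xl <- centered_mean_abs(relative_movement(lo$L2, lo$rod1))
  expect_equal(xl / xf, 3, tolerance = 1e-6)

  # zero relative amplitude and zero noise -> constant distance -> x_hat 0
  cfg0 <- trajectory_sim_config(base_relative_amplitude = 0,
                                tracking_noise_sd = 0)
  z <- simulate_trajectories(cfg0, "fixed", seed = 1)
  expect_equal(centered_mean_abs(relative_movement(z$L2, z$rod1)), 0,
               tolerance = 1e-9)
})

test_that("noisy trajectories recover the gain within 10%", {
  cfg <- trajectory_sim_config(tracking_noise_sd = 0.05,
                               base_relative_amplitude = 1,
                               loosening_gain = 3)
  ratios <- vapply(1:10, function(i) {
    fx <- simulate_trajectories(cfg, "fixed", seed = i)
    lo <- simulate_trajectories(cfg, "loose", seed = i + 1000)
    centered_mean_abs(relative_movement(lo$L2, lo$rod1)) /
      centered_mean_abs(relative_movement(fx$L2, fx$rod1))
  }, numeric(1))
  expect_true(all(abs(ratios - 3) / 3 < 0.1))
})
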