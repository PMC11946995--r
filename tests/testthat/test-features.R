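# Log-mel frontend: STFT against a direct-summation oracle, mel scale,
# filterbank geometry, normalization and waveform augmentation.

test_that("stft matches the direct-summation DFT oracle", {
  set.seed(101)
  cfg <- feature_config(n_fft = 256L, hop = 128L, n_mels = 32L)
  for (i in 1:10) {
    x <- rnorm(512)
    fast <- stft(x, cfg)
    slow <- naive_stft(x, 256L, 128L)
    expect_equal(dim(fast), dim(slow))
    expect_lt(max(Mod(fast - slow)) / max(Mod(slow)), 1e-9)
  }
})

test_that("stft of a constant signal concentrates in the DC bin", {
  cfg <- feature_config(n_fft = 256L, hop = 128L, n_mels = 32L)
  X <- stft(rep(1, 2048), cfg)
  hann_sum <- sum(0.5 - 0.5 * cos(2 * pi * (0:255) / 256))
  interior <- 3:(ncol(X) - 2)
  expect_equal(Mod(X[1, interior]), rep(hann_sum, length(interior)),
               tolerance = 1e-10)
  expect_lt(max(Mod(X[3:nrow(X), interior])), 1e-8 * hann_sum)
})

test_that("canonical-length input yields exactly 218 frames", {
  cfg <- feature_config()
  X <- stft(numeric(cfg$canonical_length), cfg)
  expect_equal(ncol(X), 218)
  expect_equal(nrow(X), cfg$n_fft / 2 + 1)
})

test_that("decibel mapping follows 10 log10 of squared amplitude", {
  expect_equal(power_to_db(1), 0)
  expect_equal(power_to_db(10), 20)
  expect_equal(power_to_db(0), 20 * log10(1e-10)) # floored, finite
  expect_true(is.finite(power_to_db(0)))
})

test_that("mel scale is exact, invertible and monotone", {
  expect_equal(hz_to_mel(0), 0)
  expect_equal(hz_to_mel(700), 2595 * log10(2), tolerance = 1e-12)
  for (f in c(10, 500, 11025))
    expect_equal(mel_to_hz(hz_to_mel(f)), f, tolerance = 1e-9)
  f <- seq(0, 22050, length.out = 2000)
  expect_true(all(diff(hz_to_mel(f)) > 0))
  expect_error(hz_to_mel(-1), class = "vibroscrew_domain_error")
})

test_that("mel filterbank has evenly spaced peaks and no empty filters", {
  cfg <- feature_config()
  fb <- mel_filterbank(cfg)
  expect_equal(dim(fb), c(256, 1025))
  expect_true(all(fb >= 0))
  expect_false(any(rowSums(fb) == 0))
  centers_mel <- hz_to_mel(attr(fb, "center_freqs"))
  expect_equal(diff(centers_mel), rep(diff(centers_mel)[1], 255),
               tolerance = 1e-9)
  # each row is unimodal: one contiguous run of positive weights, rising
  # then falling
  for (i in c(1, 64, 128, 256)) {
    row <- fb[i, ]
    pos <- which(row > 0)
    expect_true(all(diff(pos) == 1)) # contiguous support
    vals <- row[pos]
    pk <- which.max(vals)
    expect_true(all(diff(vals[seq_len(pk)]) >= 0))       # rising flank
    expect_true(all(diff(vals[pk:length(vals)]) <= 0))   # falling flank
  }
  expect_error(
    mel_filterbank(feature_config(n_fft = 64L, n_mels = 256L)),
    class = "vibroscrew_config_error")
})

test_that("logmel produces the canonical 256 x 218 feature matrix", {
  sw <- generate_sweep()
  sp <- logmel(sw)
  expect_equal(dim(sp), c(256L, 218L))
  expect_true(all(is.finite(sp)))

  # silence maps to the constant floor
  quiet <- logmel(numeric(1000), sample_rate = 44100)
  expect_equal(dim(quiet), c(256L, 218L))
  expect_lt(diff(range(quiet)), 1e-6)

  expect_error(logmel(numeric(0), sample_rate = 44100),
               class = "vibroscrew_input_error")
})

test_that("a pure tone localizes to the right mel bin", {
  sr <- 44100
  tone <- recording(0.5 * sin(2 * pi * 440 * (0:110249) / sr), sr)
  cfg <- feature_config()
  sp <- logmel(tone, cfg)
  fb <- mel_filterbank(cfg)
  centers <- attr(fb, "center_freqs")
  interior <- 5:100 # frames covering the tone before any padding region
  peaks <- apply(unclass(sp)[, interior], 2, which.max)
  bin_width <- diff(centers)[peaks[1]]
  expect_true(all(abs(centers[peaks] - 440) <= 2 * bin_width))
})

test_that("normalization statistics standardize a collection", {
  a <- matrix(0, 4, 4); b <- matrix(2, 4, 4)
  st <- compute_norm_stats(list(a, b))
  expect_equal(st$mu, 1)
  expect_equal(st$sigma, 1)
  expect_true(all(normalize_spectrogram(a, st) == -1))
  expect_true(all(normalize_spectrogram(b, st) == 1))

  set.seed(7)
  specs <- lapply(1:5, function(i) matrix(rnorm(64, i, 2), 8, 8))
  st <- compute_norm_stats(specs)
  normed <- lapply(specs, normalize_spectrogram, stats = st)
  v <- unlist(normed)
  expect_equal(mean(v), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-6)

  # un-normalize recovers the input
  back <- normalize_spectrogram(normed[[1]],
                                list(mu = -st$mu / st$sigma,
                                     sigma = 1 / st$sigma))
  expect_equal(unclass(back), specs[[1]], tolerance = 1e-9)

  expect_error(compute_norm_stats(list(matrix(3, 4, 4))),
               class = "vibroscrew_input_error") # zero variance
})

test_that("identity augmentation parameters return the input", {
  set.seed(3)
  x <- runif(8000, -0.9, 0.9)
  y <- augment_waveform(x, 22050, semitones = 0, stretch = 1)
  expect_lt(sqrt(sum((y - x)^2) / sum(x^2)), 1e-3)
})

test_that("time stretching changes length by the stretch factor", {
  set.seed(4)
  x <- rnorm(20000)
  for (rate in c(0.9, 1.1)) {
    y <- time_stretch(x, rate)
    expect_length(y, round(length(x) / rate))
  }
})

test_that("a +12 semitone shift doubles the dominant frequency", {
  sr <- 22050
  tone <- sin(2 * pi * 100 * (0:(2 * sr - 1)) / sr)
  up <- pitch_shift(tone, 12, sr)
  expect_length(up, length(tone))
  expect_lt(abs(dominant_freq(up, sr) - 200), 2)
})

test_that("random augmentation preserves length and amplitude bounds", {
  set.seed(9)
  x <- 0.8 * sin(2 * pi * 150 * (0:15999) / 22050)
  for (i in 1:3) {
    y <- augment_waveform(x, 22050)
    expect_length(y, length(x))
    expect_lte(max(abs(y)), 1)
  }
})
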