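# Sine-sweep generation and the WAV/manifest capture format.

test_that("default sweep has the standardized length, onset and endpoints", {
  sw <- generate_sweep()
  expect_length(sw$samples, 110250) # 2.5 s at 44.1 kHz
  expect_identical(sw$samples[1], 0) # zero initial phase
  expect_equal(max(abs(sw$samples)), 0.8, tolerance = 1e-6)

  # instantaneous frequency at the ends, estimated from zero-crossing
  # spacing: half a period separates successive crossings
  inst_freq <- function(x, sr, window) {
    z <- which(diff(sign(x[window])) != 0)
    sr / (2 * mean(diff(z)))
  }
  f0 <- inst_freq(sw$samples, sw$sample_rate, 1:22050)        # first 0.5 s
  f1 <- inst_freq(sw$samples, sw$sample_rate, 88201:110250)   # last 0.5 s
  # linear chirp: mean frequency over [0, .5]s is 10 + 490/2.5 * 0.25
  expect_equal(f0, 10 + 490 / 2.5 * 0.25, tolerance = 0.05 * f0)
  expect_equal(f1, 500 - 490 / 2.5 * 0.25, tolerance = 0.05 * f1)
})

test_that("sweep energy is confined below 600 Hz", {
  for (law in c("linear", "exponential")) {
    sw <- generate_sweep(excitation_config(law = law))
    expect_lt(high_band_fraction(sw$samples, sw$sample_rate, 600), 0.01)
  }
})

test_that("exponential sweep rises monotonically between the endpoints", {
  sw <- generate_sweep(excitation_config(law = "exponential"))
  z <- which(diff(sign(sw$samples)) != 0)
  gaps <- diff(z)
  # zero-crossing spacing shrinks as the instantaneous frequency rises:
  # the sweep spans 10 -> 500 Hz, a 50x period contraction
  expect_gt(mean(gaps[seq_len(20)]), 10 * mean(rev(gaps)[seq_len(20)]))
})

test_that("invalid excitation configs are rejected with the field named", {
  expect_error(excitation_config(f_start = 500, f_end = 10), "f_end")
  expect_error(excitation_config(duration = 0), "duration")
  expect_error(excitation_config(sample_rate = 100), "sample_rate")
  expect_error(excitation_config(amplitude = 1.5), "amplitude")
})

test_that("WAV round-trip is exact to 24-bit quantization", {
  sw <- generate_sweep(excitation_config(duration = 0.05))
  p <- withr::local_tempfile(fileext = ".wav")
  write_recording(sw, p)
  rt <- read_recording(p)
  expect_length(rt$samples, length(sw$samples))
  expect_identical(rt$sample_rate, 44100L)
  expect_lt(max(abs(rt$samples - sw$samples)), 2^-23)

  # value 0.5 survives within one quantization step
  rec <- recording(rep(0.5, 1000), 44100)
  write_recording(rec, p)
  expect_lt(max(abs(read_recording(p)$samples - 0.5)), 2^-23)

  # arbitrary waveforms in [-1, 1]
  set.seed(42)
  for (i in 1:5) {
    x <- runif(500, -1, 1)
    write_recording(recording(x, 8000), p)
    expect_lt(max(abs(read_recording(p)$samples - x)), 2^-23)
  }
})

test_that("non-mono and truncated WAV files raise format errors", {
  p <- withr::local_tempfile(fileext = ".wav")
  # hand-build a stereo header
  con <- file(p, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(2L, con, size = 2, endian = "little") # stereo
  writeBin(44100L, con, size = 4, endian = "little")
  writeBin(176400L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(0L, con, size = 4, endian = "little")
  close(con)
  expect_error(read_recording(p), class = "vibroscrew_format_error")

  # truncated data chunk
  rec <- recording(runif(100, -1, 1), 8000)
  write_recording(rec, p)
  raw <- readBin(p, "raw", file.size(p))
  writeBin(raw[1:100], p)
  expect_error(read_recording(p), class = "vibroscrew_format_error")

  # not a RIFF file at all
  writeLines("hello", p)
  expect_error(read_recording(p), class = "vibroscrew_format_error")
})

test_that("build_manifest scans a directory and enforces uniqueness", {
  d <- withr::local_tempdir()
  expect_equal(nrow(build_manifest(d)), 0) # empty directory

  rec <- recording(sin(2 * pi * 50 * (0:999) / 8000) * 0.5, 8000)
  for (sp in 0:1) for (cond in c("fixed", "loose")) for (sw in 1:2) {
    meta <- list(specimen_id = sp, screw_id = 1L, sensor_id = 1L,
                 condition = cond, sweep_index = sw)
    write_recording(rec, file.path(d, vibroscrew:::recording_filename(meta)))
  }
  man <- build_manifest(d)
  expect_equal(nrow(man), 8)
  expect_equal(sum(man$condition == "fixed"), 4)
  expect_equal(sum(man$condition == "loose"), 4)

  # duplicated metadata tuple -> manifest error
  man2 <- rbind(man, man[1, ])
  expect_error(vibroscrew:::check_manifest_unique(man2),
               class = "vibroscrew_manifest_error")
})

test_that("manifest CSV round-trips with provenance comments", {
  d <- withr::local_tempdir()
  man <- data.frame(path = "a.wav", specimen_id = 0L, screw_id = 1L,
                    sensor_id = 1L, condition = "fixed", sweep_index = 1L)
  p <- file.path(d, "manifest.csv")
  write_manifest(man, p, provenance = c(master_seed = "7"))
  expect_true(any(grepl("^# master_seed", readLines(p))))
  expect_equal(read_manifest(p), man)
})
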