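# Sine-sweep excitation and the capture-format surface: recordings carry
# their provenance metadata (specimen, screw, sensor, condition, sweep
# index) so every downstream stage can trace a waveform back to its cell in
# the study design.

#' Excitation configuration
#'
#' Defines the standardized sweep used to excite the instrumented vertebra:
#' 10 to 500 Hz over 2.5 s at 44.1 kHz by default, matching the acquisition
#' protocol the pipeline is designed around.
#'
#' @param f_start sweep start frequency in Hz.
#' @param f_end sweep end frequency in Hz; must exceed `f_start`.
#' @param duration sweep duration in seconds.
#' @param sample_rate sampling rate in Hz; must be at least `2 * f_end`.
#' @param amplitude peak amplitude in `(0, 1]` full scale. The default 0.8
#'   leaves headroom for resonant gain in simulated transfer paths.
#' @param law frequency law: `"linear"` (default) or `"exponential"`.
#' @return an object of class `excitation_config`.
#' @export
excitation_config <- function(f_start = 10, f_end = 500, duration = 2.5,
                              sample_rate = 44100, amplitude = 0.8,
                              law = c("linear", "exponential")) {
  law <- match.arg(law)
  if (!is.numeric(f_start) || f_start <= 0)
    vs_stop("invalid excitation config: f_start must be > 0",
            "vibroscrew_config_error")
  if (!is.numeric(f_end) || f_end <= f_start)
    vs_stop("invalid excitation config: f_end must exceed f_start",
            "vibroscrew_config_error")
  if (!is.numeric(duration) || duration <= 0)
    vs_stop("invalid excitation config: duration must be > 0",
            "vibroscrew_config_error")
  if (!is.numeric(sample_rate) || sample_rate < 2 * f_end)
    vs_stop("invalid excitation config: sample_rate must be >= 2 * f_end",
            "vibroscrew_config_error")
  if (!is.numeric(amplitude) || amplitude <= 0 || amplitude > 1)
    vs_stop("invalid excitation config: amplitude must be in (0, 1]",
            "vibroscrew_config_error")
  structure(list(f_start = f_start, f_end = f_end, duration = duration,
                 sample_rate = sample_rate, amplitude = amplitude, law = law),
            class = "excitation_config")
}

#' Construct a recording object
#'
#' A recording is a mono waveform in `[-1, 1]` plus its provenance metadata.
#'
#' @param samples numeric waveform, all values finite and in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param bit_depth nominal capture bit depth (24 by default).
#' @param meta named list with `specimen_id` (0-3), `screw_id` (1-2),
#'   `sensor_id` (1-2), `condition` (`"fixed"`/`"loose"`), `sweep_index`.
#'   May be `NULL` for recordings not tied to the study design (e.g. the
#'   excitation itself).
#' @return an object of class `recording`.
#' @export
recording <- function(samples, sample_rate, bit_depth = 24L, meta = NULL) {
  if (!is.numeric(samples) || length(samples) == 0)
    vs_stop("recording samples must be a nonempty numeric vector",
            "vibroscrew_input_error")
  if (any(!is.finite(samples)))
    vs_stop("recording samples must all be finite", "vibroscrew_input_error")
  if (max(abs(samples)) > 1 + 1e-9)
    vs_stop("recording samples must lie in [-1, 1]", "vibroscrew_input_error")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    vs_stop("recording sample_rate must be > 0", "vibroscrew_input_error")
  if (!is.null(meta) && !is.null(meta$condition) &&
      !meta$condition %in% c("fixed", "loose"))
    vs_stop("recording condition must be 'fixed' or 'loose'",
            "vibroscrew_input_error")
  structure(list(samples = as.numeric(samples),
                 sample_rate = sample_rate,
                 bit_depth = as.integer(bit_depth),
                 meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples @ %g Hz (%d-bit)\n",
              length(x$samples), x$sample_rate, x$bit_depth))
  if (!is.null(x$meta))
    cat(sprintf("  specimen %s, screw %s, sensor %s, %s, sweep %s\n",
                x$meta$specimen_id, x$meta$screw_id, x$meta$sensor_id,
                x$meta$condition, x$meta$sweep_index))
  invisible(x)
}

#' Generate the sine-sweep excitation signal
#'
#' Produces the chirp used to probe the bone-implant transfer path. The
#' default is a linear chirp with zero initial phase, so the instantaneous
#' frequency rises monotonically from `f_start` to `f_end` across the
#' sweep; an exponential law is available via the config.
#'
#' @param config an [excitation_config()].
#' @return a [recording()] of `round(duration * sample_rate)` samples with
#'   peak amplitude `config$amplitude`.
#' @export
generate_sweep <- function(config = excitation_config()) {
  if (!inherits(config, "excitation_config"))
    vs_stop("config must be an excitation_config", "vibroscrew_config_error")
  n <- round(config$duration * config$sample_rate)
  t <- (seq_len(n) - 1) / config$sample_rate
  if (config$law == "linear") {
    # phase(t) = 2*pi*(f0*t + (f1 - f0)/(2*D) * t^2)
    phase <- 2 * pi * (config$f_start * t +
                         (config$f_end - config$f_start) /
                           (2 * config$duration) * t^2)
  } else {
    k <- config$f_end / config$f_start
    phase <- 2 * pi * config$f_start * config$duration / log(k) *
      (k^(t / config$duration) - 1)
  }
  x <- config$amplitude * sin(phase)
  recording(x, config$sample_rate, 24L, meta = NULL)
}

#' Write / read a recording as a WAV file
#'
#' Round-trips are exact to within one quantization step of the chosen bit
#' depth (at 24 bits: max absolute error `<= 2^-23`). Metadata is carried in
#' the dataset manifest, not inside the WAV.
#'
#' @param rec a [recording()].
#' @param path file path ending in `.wav`.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns a [recording()] (with `meta = NULL`; attach metadata from the
#'   manifest).
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "recording"))
    vs_stop("rec must be a recording", "vibroscrew_input_error")
  wav_write_raw(rec$samples, rec$sample_rate, rec$bit_depth, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  raw <- wav_read_raw(path)
  recording(raw$samples, raw$sample_rate, raw$bit_depth, meta = NULL)
}

# Filename codec for recordings inside a dataset directory; metadata is
# recoverable from the name alone so a directory is self-describing.
recording_filename <- function(meta) {
  sprintf("s%d_screw%d_sensor%d_%s_sweep%03d.wav",
          meta$specimen_id, meta$screw_id, meta$sensor_id,
          meta$condition, meta$sweep_index)
}

parse_recording_filename <- function(name) {
  pat <- "^s(\\d+)_screw(\\d+)_sensor(\\d+)_(fixed|loose)_sweep(\\d+)\\.wav$"
  if (!grepl(pat, name)) return(NULL)
  m <- regmatches(name, regexec(pat, name))[[1]]
  list(specimen_id = as.integer(m[2]), screw_id = as.integer(m[3]),
       sensor_id = as.integer(m[4]), condition = m[5],
       sweep_index = as.integer(m[6]))
}

#' Build a dataset manifest from a directory of recordings
#'
#' Scans a directory for WAV files whose names encode their study-design
#' metadata and assembles the manifest table. The
#' (specimen, screw, sensor, condition, sweep) tuple must be unique.
#'
#' @param directory path containing `.wav` files written by
#'   [generate_dataset()] or named with the same scheme.
#' @return a `data.frame` with columns
#'   `path, specimen_id, screw_id, sensor_id, condition, sweep_index`.
#' @export
build_manifest <- function(directory) {
  files <- sort(list.files(directory, pattern = "\\.wav$"))
  rows <- lapply(files, function(f) {
    meta <- parse_recording_filename(f)
    if (is.null(meta)) return(NULL)
    data.frame(path = file.path(directory, f),
               specimen_id = meta$specimen_id, screw_id = meta$screw_id,
               sensor_id = meta$sensor_id, condition = meta$condition,
               sweep_index = meta$sweep_index, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(path = character(), specimen_id = integer(),
                      screw_id = integer(), sensor_id = integer(),
                      condition = character(), sweep_index = integer(),
                      stringsAsFactors = FALSE))
  }
  manifest <- do.call(rbind, rows)
  check_manifest_unique(manifest)
  manifest
}

check_manifest_unique <- function(manifest) {
  key <- with(manifest, paste(specimen_id, screw_id, sensor_id, condition,
                              sweep_index, sep = "|"))
  dup <- key[duplicated(key)]
  if (length(dup) > 0)
    vs_stop(paste0("duplicate manifest tuples: ",
                   paste(unique(dup), collapse = ", ")),
            "vibroscrew_manifest_error")
  invisible(TRUE)
}

#' Write / read a manifest CSV
#'
#' The CSV has header `path,specimen_id,screw_id,sensor_id,condition,`
#' `sweep_index`; provenance (generator seed, config digest) is carried in
#' `#`-prefixed comment lines at the top.
#'
#' @param manifest a manifest `data.frame`.
#' @param path CSV path.
#' @param provenance optional named character vector written as comments.
#' @export
write_manifest <- function(manifest, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  write.csv(manifest, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  manifest <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_manifest_unique(manifest)
  manifest
}
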