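# Log-mel spectrogram frontend. The classifier consumes 256 x 218 matrices:
# 256 triangular mel filters evenly spaced on f_mel = 2595*log10(1 + f/700),
# applied to the magnitude STFT (Hann window, hop 256) of the recording
# after resampling to 22.05 kHz and canonicalizing to 55,552 samples, then
# mapped to decibels. With centered framing this yields exactly
# 1 + floor(55552/256) = 218 time frames.

#' Feature extraction configuration
#'
#' @param n_fft analysis window / FFT length in samples.
#' @param hop hop length `H` between successive frames, in samples.
#' @param n_mels number of triangular mel filters (rows of the spectrogram).
#' @param analysis_rate rate in Hz the waveform is resampled to before
#'   analysis. Halving the capture rate keeps the analysis band (0-11.025
#'   kHz) comfortably above the excited range while making the printed
#'   256x218 feature shape reachable with hop 256.
#' @param canonical_length length in samples every resampled waveform is
#'   trimmed/zero-padded to; the default gives exactly 218 frames.
#' @param db_floor amplitude floor applied before the log, keeping silent
#'   bins finite.
#' @param f_min,f_max mel filterbank frequency range in Hz.
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(n_fft = 2048L, hop = 256L, n_mels = 256L,
                           analysis_rate = 22050, canonical_length = 55552L,
                           db_floor = 1e-10, f_min = 0,
                           f_max = analysis_rate / 2) {
  if (hop <= 0) vs_stop("hop must be > 0", "vibroscrew_config_error")
  if (n_mels <= 0) vs_stop("n_mels must be > 0", "vibroscrew_config_error")
  if (!(f_min < f_max && f_max <= analysis_rate / 2))
    vs_stop("need f_min < f_max <= analysis_rate/2",
            "vibroscrew_config_error")
  structure(list(n_fft = as.integer(n_fft), hop = as.integer(hop),
                 n_mels = as.integer(n_mels), analysis_rate = analysis_rate,
                 canonical_length = as.integer(canonical_length),
                 db_floor = db_floor, f_min = f_min, f_max = f_max),
            class = "feature_config")
}

# reflect-pad a vector by `pad` samples on each side (librosa-style,
# edge sample not repeated); falls back to cycling reflection for very
# short inputs.
reflect_pad <- function(x, pad) {
  n <- length(x)
  if (n == 1) return(rep(x, 2 * pad + 1))
  idx <- seq_len(n)
  # indices follow a triangle wave of period 2(n-1)
  pos <- c(rev(seq_len(pad)), idx - 1, n - 1 - seq_len(pad)) # 0-based naive
  per <- 2 * (n - 1)
  pos <- pos %% per
  pos <- ifelse(pos >= n, per - pos, pos)
  x[pos + 1]
}

#' Short-time Fourier transform
#'
#' Centered STFT: the waveform is reflection-padded by `n_fft/2` on both
#' ends, framed with hop `H`, Hann-windowed, and transformed. Frame `m`,
#' bin `k` holds `sum_n x(n + mH) w(n) exp(-2*pi*i*k*n / N_w)` over the
#' padded signal.
#'
#' @param waveform numeric vector, length >= 1.
#' @param config a [feature_config()].
#' @return complex matrix, `n_fft/2 + 1` frequency rows (bin 0 ... Nyquist)
#'   by `1 + floor(length(waveform)/hop)` time columns.
#' @export
stft <- function(waveform, config = feature_config()) {
  stft_raw(waveform, config$n_fft, config$hop)
}

stft_raw <- function(waveform, n_fft, hop) {
  if (length(waveform) < 1)
    vs_stop("waveform must be nonempty", "vibroscrew_input_error")
  n_frames <- 1L + length(waveform) %/% hop
  xp <- reflect_pad(waveform, n_fft %/% 2L)
  w <- hann_window(n_fft)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- matrix(0, nrow = n_fft, ncol = n_frames)
  for (m in seq_len(n_frames))
    frames[, m] <- xp[starts[m] + seq_len(n_fft)]
  frames <- frames * w
  X <- stats::mvfft(frames)
  X[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
}

# periodic Hann window, the standard analysis window for STFT framing
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

#' Amplitude-to-decibel mapping
#'
#' `X_dB = 10 log10(max(|X|, floor)^2)`, elementwise. The floor keeps
#' silence finite: a zero magnitude maps to `10*log10(floor^2)` (-200 dB at
#' the default floor).
#'
#' @param X numeric or complex matrix/vector of spectral amplitudes.
#' @param db_floor amplitude floor.
#' @return numeric array of the same shape, in dB.
#' @export
power_to_db <- function(X, db_floor = 1e-10) {
  a <- pmax(Mod(X), db_floor)
  out <- 20 * log10(a)
  if (!is.null(dim(X))) dim(out) <- dim(X)
  out
}

#' Mel scale conversions
#'
#' `f_mel = 2595 log10(1 + f/700)` and its algebraic inverse.
#'
#' @param f frequency in Hz (nonnegative).
#' @param m frequency in mel (nonnegative).
#' @return converted frequencies.
#' @export
hz_to_mel <- function(f) {
  if (any(f < 0)) vs_stop("frequency must be nonnegative",
                          "vibroscrew_domain_error")
  2595 * log10(1 + f / 700)
}

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) {
  if (any(m < 0)) vs_stop("mel value must be nonnegative",
                          "vibroscrew_domain_error")
  700 * (10^(m / 2595) - 1)
}

#' Triangular mel filterbank
#'
#' `n_mels` unit-peak triangular filters whose centers are evenly spaced on
#' the mel scale between `f_min` and `f_max`.
#'
#' @param config a [feature_config()].
#' @return numeric matrix `n_mels` x `n_fft/2 + 1`.
#' @export
mel_filterbank <- function(config = feature_config()) {
  n_bins <- config$n_fft %/% 2L + 1L
  fft_freqs <- (seq_len(n_bins) - 1) * config$analysis_rate / config$n_fft
  mel_pts <- seq(hz_to_mel(config$f_min), hz_to_mel(config$f_max),
                 length.out = config$n_mels + 2L)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, nrow = config$n_mels, ncol = n_bins)
  for (i in seq_len(config$n_mels)) {
    lo <- hz_pts[i]; ce <- hz_pts[i + 1]; hi <- hz_pts[i + 2]
    up <- (fft_freqs - lo) / (ce - lo)
    down <- (hi - fft_freqs) / (hi - ce)
    fb[i, ] <- pmax(0, pmin(up, down))
  }
  if (any(rowSums(fb) == 0))
    vs_stop(paste0("mel filterbank has empty filters; increase n_fft or ",
                   "reduce n_mels"), "vibroscrew_config_error")
  attr(fb, "center_freqs") <- hz_pts[2:(config$n_mels + 1L)]
  fb
}

# rational-factor polyphase resampler via signal::resample
resample_waveform <- function(x, from_rate, to_rate) {
  if (from_rate == to_rate) return(x)
  r <- to_rate / from_rate
  # rational approximation with denominator <= 1000
  cf <- function(v, maxden) {
    p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; a <- v
    repeat {
      ai <- floor(a)
      p2 <- ai * p1 + p0; q2 <- ai * q1 + q0
      if (q2 > maxden) return(c(p1, q1))
      p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
      if (abs(p2 / q2 - v) < 1e-12) return(c(p2, q2))
      a <- 1 / (a - ai)
    }
  }
  pq <- cf(r, 1000)
  y <- signal::resample(x, pq[1], pq[2])
  n_out <- round(length(x) * r)
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(0, n_out - length(y)))
}

fit_length <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, rep(0, n - length(x)))
}

#' Log-mel spectrogram of a recording
#'
#' The full frontend: resample to `analysis_rate`, trim/zero-pad to
#' `canonical_length`, centered STFT, mel filterbank on the magnitudes,
#' decibel mapping. With default settings every recording maps to a
#' 256 x 218 matrix (mel bins, low to high frequency, by time frames).
#'
#' @param rec a [recording()] (or bare numeric waveform, in which case
#'   `sample_rate` must be given).
#' @param config a [feature_config()].
#' @param sample_rate required if `rec` is a bare numeric vector.
#' @return an object of class `spectrogram`: the dB matrix with attributes
#'   `meta` (copied from the recording) and `config_digest`.
#' @export
logmel <- function(rec, config = feature_config(), sample_rate = NULL) {
  if (inherits(rec, "recording")) {
    x <- rec$samples
    sr <- rec$sample_rate
    meta <- rec$meta
  } else {
    if (is.null(sample_rate))
      vs_stop("sample_rate is required for bare waveforms",
              "vibroscrew_input_error")
    x <- rec
    sr <- sample_rate
    meta <- NULL
  }
  if (length(x) == 0)
    vs_stop("empty waveform", "vibroscrew_input_error")
  x <- resample_waveform(x, sr, config$analysis_rate)
  x <- fit_length(x, config$canonical_length)
  X <- stft(x, config)
  fb <- mel_filterbank(config)
  S <- fb %*% Mod(X)
  out <- power_to_db(S, config$db_floor)
  structure(out, class = c("spectrogram", "matrix"),
            meta = meta, config_digest = config_digest(unclass(config)))
}

#' Normalization statistics over a spectrogram collection
#'
#' Global mean and standard deviation over every matrix element of every
#' spectrogram in the collection. `scope` records whether the statistics
#' were fit on training data only (default elsewhere in the package,
#' avoiding test leakage) or over the entire dataset (the
#' protocol-faithful option).
#'
#' @param spectrograms list of spectrograms (or numeric matrices).
#' @param scope `"train_only"` or `"entire_dataset"` (a bookkeeping flag).
#' @return list with `mu`, `sigma` (population sd), `scope`.
#' @export
compute_norm_stats <- function(spectrograms,
                               scope = c("train_only", "entire_dataset")) {
  scope <- match.arg(scope)
  if (length(spectrograms) < 1)
    vs_stop("need at least one spectrogram", "vibroscrew_input_error")
  v <- unlist(lapply(spectrograms, as.numeric), use.names = FALSE)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma <= 0)
    vs_stop("zero variance: cannot normalize a constant collection",
            "vibroscrew_input_error")
  list(mu = mu, sigma = sigma, scope = scope)
}

#' Normalize a spectrogram
#'
#' `(X - mu) / sigma` with statistics from [compute_norm_stats()].
#'
#' @param spec a spectrogram (numeric matrix).
#' @param stats normalization statistics.
#' @return normalized spectrogram, attributes preserved.
#' @export
normalize_spectrogram <- function(spec, stats) {
  if (stats$sigma <= 0)
    vs_stop("sigma must be > 0", "vibroscrew_input_error")
  out <- (unclass(spec) - stats$mu) / stats$sigma
  attributes(out) <- attributes(spec)
  out
}

## ---- waveform-level augmentation -------------------------------------

# inverse STFT by Hann-windowed overlap-add (hop must divide n_fft and
# satisfy COLA; n_fft/4 does)
istft <- function(X, n_fft, hop, out_length) {
  n_frames <- ncol(X)
  full <- matrix(0+0i, nrow = n_fft, ncol = n_frames)
  full[seq_len(nrow(X)), ] <- X
  if (nrow(X) < n_fft) {
    conj_rows <- seq(n_fft %/% 2L, 2L)
    full[seq(n_fft %/% 2L + 2L, n_fft), ] <- Conj(X[conj_rows, ])
  }
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / n_fft
  w <- hann_window(n_fft)
  frames <- frames * w
  total <- n_fft + (n_frames - 1L) * hop
  y <- numeric(total)
  wsum <- numeric(total)
  for (m in seq_len(n_frames)) {
    idx <- (m - 1L) * hop + seq_len(n_fft)
    y[idx] <- y[idx] + frames[, m]
    wsum[idx] <- wsum[idx] + w^2
  }
  y <- y / pmax(wsum, 1e-12)
  pad <- n_fft %/% 2L
  y <- y[(pad + 1L):length(y)]
  fit_length(y, out_length)
}

#' Time stretching by phase vocoder
#'
#' Stretches a waveform to `round(length(x)/rate)` samples without changing
#' its pitch: STFT magnitudes are read at fractional frame positions while
#' phases are advanced by the per-bin expected phase increment plus the
#' measured deviation.
#'
#' @param x numeric waveform.
#' @param rate stretch rate; `rate < 1` lengthens, `rate > 1` shortens.
#' @param n_fft,hop vocoder analysis parameters (`hop = n_fft/4` preserves
#'   overlap-add identity).
#' @return stretched waveform of length `round(length(x)/rate)`.
#' @export
time_stretch <- function(x, rate, n_fft = 2048L, hop = n_fft %/% 4L) {
  if (rate == 1) return(x)
  if (rate <= 0) vs_stop("rate must be > 0", "vibroscrew_config_error")
  X <- stft_raw(x, n_fft, hop)
  n_bins <- nrow(X)
  n_frames <- ncol(X)
  steps <- seq(0, n_frames - 1, by = rate)
  phi_adv <- 2 * pi * hop * (seq_len(n_bins) - 1) / n_fft
  out <- matrix(0+0i, nrow = n_bins, ncol = length(steps))
  phase <- Arg(X[, 1])
  mag_of <- function(tt) {
    lo <- floor(tt) + 1
    hi <- min(lo + 1, n_frames)
    a <- tt - floor(tt)
    (1 - a) * Mod(X[, lo]) + a * Mod(X[, hi])
  }
  for (j in seq_along(steps)) {
    tt <- steps[j]
    out[, j] <- mag_of(tt) * exp(1i * phase)
    lo <- floor(tt) + 1
    hi <- min(lo + 1, n_frames)
    dphi <- Arg(X[, hi]) - Arg(X[, lo]) - phi_adv
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    phase <- phase + phi_adv + dphi
  }
  out_len <- round(length(x) / rate)
  istft(out, n_fft, hop, out_len)
}

#' Pitch shifting by resampling plus time stretch
#'
#' Shifts pitch by `semitones` (factor `2^(semitones/12)`) while keeping the
#' waveform length: the signal is sped up by resampling and then stretched
#' back to the original duration.
#'
#' @param x numeric waveform.
#' @param semitones pitch offset in semitones (may be fractional).
#' @param sample_rate waveform sampling rate in Hz.
#' @return shifted waveform, same length as `x`.
#' @export
pitch_shift <- function(x, semitones, sample_rate) {
  if (semitones == 0) return(x)
  factor <- 2^(semitones / 12)
  n <- length(x)
  # play faster by `factor`: take samples at stride `factor`
  t_new <- seq(1, n, by = factor)
  sped <- stats::approx(seq_len(n), x, xout = t_new)$y
  stretched <- time_stretch(sped, rate = length(sped) / n)
  fit_length(stretched, n)
}

#' Waveform augmentation
#'
#' Training-time augmentation applied to raw waveforms: a pitch shift drawn
#' uniformly from \[-3, 3\] semitones and a time stretch with factor drawn
#' from \{0.9, 1.1\}, followed by re-trimming/padding to the original
#' length. Both transforms may also be fixed explicitly.
#'
#' @param x numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param semitones pitch offset; `NULL` to draw uniformly from \[-3, 3\].
#' @param stretch stretch factor; `NULL` to draw from \{0.9, 1.1\}.
#' @return augmented waveform, same length as `x`.
#' @export
augment_waveform <- function(x, sample_rate, semitones = NULL,
                             stretch = NULL) {
  if (length(x) == 0)
    vs_stop("waveform must be nonempty", "vibroscrew_input_error")
  if (is.null(semitones)) semitones <- runif(1, -3, 3)
  if (is.null(stretch)) stretch <- sample(c(0.9, 1.1), 1)
  n <- length(x)
  y <- pitch_shift(x, semitones, sample_rate)
  if (stretch != 1) y <- time_stretch(y, rate = stretch)
  y <- fit_length(y, n)
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  y
}
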