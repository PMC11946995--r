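# Independent brute-force oracles used to pin the fast implementations.

# Literal direct-summation STFT: reflection-pad, frame, Hann-window, and
# evaluate the DFT sum term by term. Triple loop on purpose -- this is the
# reference, not the implementation.
naive_stft <- function(x, n_fft, hop) {
  pad <- n_fft %/% 2
  n <- length(x)
  # reflection padding (edge sample not repeated)
  left <- rev(x[2:(pad + 1)])
  right <- rev(x[(n - pad):(n - 1)])
  xp <- c(left, x, right)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n_fft - 1)) / n_fft)
  n_frames <- 1 + n %/% hop
  out <- matrix(0 + 0i, nrow = n_fft %/% 2 + 1, ncol = n_frames)
  for (m in 0:(n_frames - 1)) {
    frame <- xp[m * hop + seq_len(n_fft)] * w
    for (k in 0:(n_fft %/% 2)) {
      out[k + 1, m + 1] <-
        sum(frame * exp(-2i * pi * k * (0:(n_fft - 1)) / n_fft))
    }
  }
  out
}

# Literal two-pass evaluation of the centered mean absolute movement
naive_centered_mean_abs <- function(dx) {
  n <- length(dx)
  m <- 0
  for (i in seq_len(n)) m <- m + dx[i]
  m <- m / n
  s <- 0
  for (i in seq_len(n)) s <- s + abs(dx[i] - m)
  s / n
}

# Direct nested-loop 2D convolution (stride/pad aware), the reference for
# the compiled im2col/GEMM kernel
naive_conv2d <- function(x, w, b, stride, pad) {
  dx <- dim(x); dw <- dim(w)
  H <- dx[1]; W <- dx[2]; Cin <- dx[3]; N <- dx[4]
  kh <- dw[1]; kw <- dw[2]; Cout <- dw[4]
  Ho <- (H + 2 * pad - kh) %/% stride + 1
  Wo <- (W + 2 * pad - kw) %/% stride + 1
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (wo in 1:Wo) for (ho in 1:Ho) {
    acc <- b[co]
    for (ci in 1:Cin) for (dwi in 1:kw) for (dhi in 1:kh) {
      hi <- (ho - 1) * stride - pad + dhi
      wi <- (wo - 1) * stride - pad + dwi
      if (hi >= 1 && hi <= H && wi >= 1 && wi <= W)
        acc <- acc + x[hi, wi, ci, n] * w[dhi, dwi, ci, co]
    }
    y[ho, wo, co, n] <- acc
  }
  y
}

# dominant frequency of a waveform by periodogram argmax
dominant_freq <- function(x, sample_rate) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(p) - 1) * sample_rate / length(p)
  half <- f <= sample_rate / 2
  f[half][which.max(p[half])]
}

# fraction of spectral power above a cutoff frequency
high_band_fraction <- function(x, sample_rate, cutoff = 600) {
  p <- Mod(stats::fft(x))^2
  f <- (seq_along(p) - 1) * sample_rate / length(p)
  half <- f <= sample_rate / 2
  sum(p[half & f > cutoff]) / sum(p[half])
}

# small study conditions shared by the fast end-to-end tests
tiny_excitation <- function() excitation_config(duration = 0.8)
tiny_feature_config <- function()
  feature_config(n_mels = 64L, canonical_length = 16384L)
tiny_model_config <- function(...) {
  defaults <- list(stage_filters = c(8L, 16L, 32L, 64L),
                   learning_rate = 1e-3, epochs = 3L, batch_size = 16L)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}
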