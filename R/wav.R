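# Minimal RIFF/WAVE reader and writer for the capture format used by the
# recording rig: mono PCM, 24-bit by default. 16-bit PCM and 32-bit IEEE
# float are accepted on read for convenience. No external audio package is
# involved; the format is simple enough to handle with readBin/writeBin.

wav_write_raw <- function(samples, sample_rate, bit_depth, path) {
  if (!bit_depth %in% c(16L, 24L))
    vs_stop(sprintf("unsupported bit depth for writing: %d", bit_depth),
            "vibroscrew_format_error")
  x <- pmax(pmin(samples, 1), -1)
  n <- length(x)
  if (bit_depth == 24L) {
    fullscale <- 8388607 # 2^23 - 1
    v <- round(x * fullscale)
    v[v < 0] <- v[v < 0] + 16777216 # two's complement
    bytes <- as.raw(rbind(v %% 256, (v %/% 256) %% 256, v %/% 65536))
  } else {
    fullscale <- 32767
    v <- round(x * fullscale)
    v[v < 0] <- v[v < 0] + 65536
    bytes <- as.raw(rbind(v %% 256, v %/% 256))
  }
  block_align <- bit_depth %/% 8L
  data_size <- n * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, size = 4,
           endian = "little")                               # byte rate
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  writeBin(bytes, con)
  invisible(path)
}

wav_read_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    vs_stop(sprintf("not a RIFF file: %s", path), "vibroscrew_format_error")
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    vs_stop(sprintf("not a WAVE file: %s", path), "vibroscrew_format_error")
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4)
      vs_stop(sprintf("truncated WAV file (no data chunk): %s", path),
              "vibroscrew_format_error")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (length(size) == 0)
      vs_stop(sprintf("truncated WAV file: %s", path),
              "vibroscrew_format_error")
    if (identical(id, "fmt ")) {
      audio_format <- readBin(con, integer(), size = 2, endian = "little")
      n_channels <- readBin(con, integer(), size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bit_depth <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16) readBin(con, raw(), n = size - 16)
      fmt <- list(audio_format = audio_format, n_channels = n_channels,
                  sample_rate = sample_rate, bit_depth = bit_depth)
    } else if (identical(id, "data")) {
      if (is.null(fmt))
        vs_stop(sprintf("malformed WAV (data before fmt): %s", path),
                "vibroscrew_format_error")
      if (fmt$n_channels != 1L)
        vs_stop(sprintf("expected mono WAV, got %d channels: %s",
                        fmt$n_channels, path), "vibroscrew_format_error")
      ba <- fmt$bit_depth %/% 8L
      n <- size %/% ba
      if (fmt$audio_format == 3L && fmt$bit_depth == 32L) {
        x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
      } else if (fmt$audio_format == 1L && fmt$bit_depth == 24L) {
        b <- as.integer(readBin(con, raw(), n = size))
        if (length(b) < size)
          vs_stop(sprintf("truncated WAV data chunk: %s", path),
                  "vibroscrew_format_error")
        b <- matrix(b[seq_len(n * 3L)], nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v[v >= 8388608] <- v[v >= 8388608] - 16777216
        x <- v / 8388607
      } else if (fmt$audio_format == 1L && fmt$bit_depth == 16L) {
        v <- readBin(con, integer(), n = n, size = 2, signed = TRUE,
                     endian = "little")
        if (length(v) < n)
          vs_stop(sprintf("truncated WAV data chunk: %s", path),
                  "vibroscrew_format_error")
        x <- v / 32767
      } else {
        vs_stop(sprintf("unsupported WAV encoding (format %d, %d-bit): %s",
                        fmt$audio_format, fmt$bit_depth, path),
                "vibroscrew_format_error")
      }
      if (length(x) < n)
        vs_stop(sprintf("truncated WAV data chunk: %s", path),
                "vibroscrew_format_error")
      return(list(samples = x, sample_rate = fmt$sample_rate,
                  bit_depth = fmt$bit_depth))
    } else {
      skip <- readBin(con, raw(), n = size + size %% 2)
      if (length(skip) < size)
        vs_stop(sprintf("truncated WAV file: %s", path),
                "vibroscrew_format_error")
    }
  }
}
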