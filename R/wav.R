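# Minimal RIFF/WAVE reader and writer. Supports PCM 16/24-bit and IEEE
# float32, any channel count. No pre-installed R package in this stack reads
# WAV, so the container is parsed directly; only canonical chunk layouts are
# handled (fmt then data, extra chunks skipped).

#' Read a WAV file into a `recording`
#'
#' Analyses in this package use a single channel; field tag data are analysed
#' from the first (left) channel, which is the default here.
#'
#' @param path WAV file path.
#' @param channel 1-based channel to keep (default 1, the left channel).
#' @param min_rate_hz minimum acceptable sample rate. The analysis band
#'   reaches 10 kHz, so rates at or below 20 kHz are rejected.
#' @return An object of class `recording`: list with `samples` (double,
#'   in [-1, 1] for integer PCM), `sample_rate_hz`, `channel_used`.
#' @export
read_recording <- function(path, channel = 1L, min_rate_hz = 20000) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2))  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)

  n_ch <- fmt$n_channels
  if (channel < 1 || channel > n_ch)
    stop(sprintf("channel %d out of range; file has %d channel(s)", channel, n_ch))
  if (fmt$sample_rate <= min_rate_hz)
    stop(sprintf(paste0("sample rate %d Hz is too low: the 1-10 kHz analysis band ",
                        "requires a rate above %d Hz"), fmt$sample_rate, min_rate_hz))

  x <- switch(as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = {
      m <- matrix(as.integer(data_raw), nrow = 3)
      v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = {
      if (fmt$audio_format == 3) {
        readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
      } else {
        readBin(data_raw, "integer", length(data_raw) / 4, 4,
                endian = "little") / 2147483648
      }
    },
    stop("unsupported WAV bit depth: ", fmt$bits)
  )
  # deinterleave
  samples <- x[seq(channel, length(x), by = n_ch)]
  new_recording(samples, fmt$sample_rate, channel_used = channel)
}

#' Construct a recording from samples in memory
#'
#' @param samples numeric amplitude vector.
#' @param sample_rate_hz sampling rate in Hz.
#' @param channel_used which source channel the samples came from.
#' @return `recording` object.
#' @export
new_recording <- function(samples, sample_rate_hz, channel_used = 1L) {
  stopifnot(is.numeric(samples), sample_rate_hz > 0)
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 channel_used = as.integer(channel_used)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d samples @ %g Hz (%.3f s), channel %d\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$channel_used))
  invisible(x)
}

#' Write samples to a WAV file
#'
#' @param samples numeric vector, or a matrix with one column per channel.
#' @param sample_rate_hz sampling rate.
#' @param path output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate_hz, path, bits = 32L) {
  if (is.matrix(samples)) {
    n_ch <- ncol(samples)
    x <- as.numeric(t(samples))   # interleave
  } else {
    n_ch <- 1L
    x <- as.numeric(samples)
  }
  bytes_per <- bits / 8L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  audio_format <- if (bits == 32L) 3L else 1L
  writeBin(audio_format, con, 2, endian = "little")
  writeBin(as.integer(n_ch), con, 2, endian = "little")
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * n_ch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(n_ch * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32L) {
    writeBin(x, con, 4, endian = "little")
  } else if (bits == 16L) {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(x * 32768)))), con,
             2, endian = "little")
  } else stop("unsupported bit depth for writing: ", bits)
  invisible(path)
}
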