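# Time-insensitive coda assembly: per-click segments are extracted around the
# click peak, DC-centered, peak-normalized to [-1, 1], and concatenated in
# click order so that the natural inter-click timing is removed. Coda-level
# spectral analysis (formant tracking) then operates on these assemblies.

#' Extract one click segment
#'
#' The segment starts `start_offset_ms` relative to the click peak (negative =
#' before; default -2 ms) and lasts `duration_ms` (default 15 ms). The peak is
#' the annotated `peak_time_s` if present, otherwise the maximum of
#' |amplitude| in a search window after the annotated click time. Portions
#' falling outside the recording are zero-padded (and logged).
#'
#' @param recording a [new_recording()].
#' @param cd a [coda()].
#' @param click_index 0-based click index within the coda.
#' @param start_offset_ms start relative to peak, in ms (negative = earlier).
#' @param duration_ms segment duration in ms.
#' @param peak_search_ms peak localization window (see [locate_click_peak()]).
#' @param normalize DC-center and peak-normalize (default TRUE).
#' @return `click_segment`: list with `samples` (exactly
#'   `round(duration_ms * fs / 1000)` of them), `coda_id`, `click_index`,
#'   `start_offset_ms`, `duration_ms`, `sample_rate_hz`, `peak_time_s`.
#' @export
extract_click_segment <- function(recording, cd, click_index,
                                  start_offset_ms = -2.0, duration_ms = 15.0,
                                  peak_search_ms = 15, normalize = TRUE) {
  fs <- recording$sample_rate_hz
  j <- which(cd$click_index == click_index)
  if (!length(j)) stop("click_index ", click_index, " not in coda ", cd$coda_id)
  pk <- cd$peak_time_s[j]
  if (is.na(pk)) pk <- locate_click_peak(recording, cd$click_time_s[j], peak_search_ms)
  n_seg <- round(duration_ms * fs / 1000)
  i0 <- round((pk + start_offset_ms / 1000) * fs) + 1L
  idx <- i0:(i0 + n_seg - 1L)
  inside <- idx >= 1L & idx <= length(recording$samples)
  if (!all(inside))
    cv_log("WARN", sprintf("segment for coda %s click %d extends outside the recording; zero-padded",
                           cd$coda_id, click_index))
  samples <- numeric(n_seg)
  samples[inside] <- recording$samples[idx[inside]]
  if (normalize) {
    samples <- samples - mean(samples)
    pkv <- max(abs(samples))
    if (pkv > 0) samples <- samples / pkv
    else cv_log("WARN", sprintf("all-constant segment for coda %s click %d; normalization skipped",
                                cd$coda_id, click_index))
  }
  structure(list(samples = samples, coda_id = cd$coda_id,
                 click_index = as.integer(click_index),
                 start_offset_ms = start_offset_ms, duration_ms = duration_ms,
                 sample_rate_hz = fs, peak_time_s = pk),
            class = "click_segment")
}

#' Assemble a time-insensitive coda from click segments
#'
#' Segments are concatenated in click order; total duration is exactly
#' `n_clicks * segment duration` (e.g. five 3.5 ms segments give 17.5 ms,
#' five 15 ms segments give 75 ms).
#'
#' @param segments list of `click_segment`s sharing coda id, rate and
#'   duration, ordered by click index. No hidden sorting: the given order is
#'   the assembly order.
#' @return `ti_coda`: list with `samples`, `coda_id`, `segment_duration_ms`,
#'   `n_clicks`, `sample_rate_hz`, `duration_ms`.
#' @export
assemble_time_insensitive_coda <- function(segments) {
  if (!length(segments)) stop("no segments")
  fs <- unique(vapply(segments, `[[`, 0, "sample_rate_hz"))
  if (length(fs) != 1) stop("segments have mixed sample rates")
  dur <- unique(vapply(segments, `[[`, 0, "duration_ms"))
  if (length(dur) != 1) stop("segments have mixed durations")
  ids <- unique(vapply(segments, `[[`, "", "coda_id"))
  if (length(ids) != 1) stop("segments belong to different codas")
  samples <- unlist(lapply(segments, `[[`, "samples"), use.names = FALSE)
  structure(list(samples = samples, coda_id = ids,
                 segment_duration_ms = dur, n_clicks = length(segments),
                 sample_rate_hz = fs,
                 duration_ms = length(samples) / fs * 1000),
            class = "ti_coda")
}

#' Assemble a coda directly from a recording
#'
#' Convenience wrapper: extracts all click segments of `cd` and assembles the
#' time-insensitive coda.
#'
#' @inheritParams extract_click_segment
#' @return `ti_coda`.
#' @export
time_insensitive_coda <- function(recording, cd, start_offset_ms = -2.0,
                                  duration_ms = 15.0, peak_search_ms = 15) {
  segs <- lapply(cd$click_index, function(ci)
    extract_click_segment(recording, cd, ci, start_offset_ms, duration_ms,
                          peak_search_ms))
  assemble_time_insensitive_coda(segs)
}

#' Join time-insensitive codas into one session waveform
#'
#' Codas are separated by an exact-zero silence buffer (default 25 ms), the
#' layout used for manual labeling of assembled codas.
#'
#' @param ti_codas list of `ti_coda` objects with a common sample rate.
#' @param buffer_ms silence between codas in ms.
#' @return list with `samples`, `sample_rate_hz`, and `onsets_s` giving each
#'   coda's start time in the joined waveform.
#' @export
assemble_session_waveform <- function(ti_codas, buffer_ms = 25) {
  if (!length(ti_codas)) stop("empty coda list")
  fs <- unique(vapply(ti_codas, `[[`, 0, "sample_rate_hz"))
  if (length(fs) != 1) stop("codas have mixed sample rates")
  buf <- numeric(round(buffer_ms * fs / 1000))
  pieces <- list(); onsets <- numeric(length(ti_codas)); pos <- 0L
  for (i in seq_along(ti_codas)) {
    onsets[i] <- pos / fs
    pieces[[length(pieces) + 1]] <- ti_codas[[i]]$samples
    pos <- pos + length(ti_codas[[i]]$samples)
    if (i < length(ti_codas)) {
      pieces[[length(pieces) + 1]] <- buf
      pos <- pos + length(buf)
    }
  }
  list(samples = unlist(pieces, use.names = FALSE), sample_rate_hz = fs,
       onsets_s = onsets)
}

#' Render a spectrogram
#'
#' Short-time Fourier magnitude with a Gaussian-like analysis window (default
#' 5 ms, the window length used for coda figures), hop of one tenth of the
#' window, magnitude in dB, limited to 0-`fmax_hz` (default 15 kHz).
#'
#' @param samples signal.
#' @param sample_rate_hz sampling rate.
#' @param window_ms analysis window (ms).
#' @param fmax_hz upper frequency limit of the returned grid.
#' @param png_path optional path; when given the grid is also drawn to a PNG.
#' @return list with `freqs_hz`, `times_s`, `mag_db` (frequencies x times).
#' @export
render_spectrogram <- function(samples, sample_rate_hz, window_ms = 5,
                               fmax_hz = 15000, png_path = NULL) {
  win_n <- max(8L, round(window_ms * sample_rate_hz / 1000))
  hop_n <- max(1L, round(win_n / 10))
  sg <- stft_mag(samples, sample_rate_hz, win_n, hop_n)
  keep <- sg$freqs_hz <= fmax_hz
  out <- list(freqs_hz = sg$freqs_hz[keep], times_s = sg$times_s,
              mag_db = db(sg$mag[keep, , drop = FALSE]^2))
  if (!is.null(png_path)) {
    grDevices::png(png_path, width = 900, height = 500)
    on.exit(grDevices::dev.off())
    graphics::image(out$times_s, out$freqs_hz, t(out$mag_db),
                    xlab = "time (s)", ylab = "frequency (Hz)",
                    col = grDevices::hcl.colors(64, "Inferno"),
                    useRaster = TRUE)
  }
  out
}

#' Write a spectrogram grid to CSV
#'
#' Long format (time_s, freq_hz, mag_db) so figures are regenerable from the
#' stage output alone.
#' @param sg result of [render_spectrogram()].
#' @param path output CSV.
#' @export
write_spectrogram_csv <- function(sg, path) {
  grid <- expand.grid(freq_hz = sg$freqs_hz, time_s = sg$times_s)
  grid$mag_db <- as.vector(sg$mag_db)
  utils::write.csv(grid[, c("time_s", "freq_hz", "mag_db")], path,
                   row.names = FALSE)
  invisible(path)
}
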