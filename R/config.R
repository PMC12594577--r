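#' Analysis configuration
#'
#' Collects every tunable of the pipeline with defaults that reproduce the
#' published analysis parameters: the 1-10 kHz analysis band, 1,500 Hz minimum
#' peak separation, 25% relative peak height, the 3.5 ms Welch window split as
#' 2.0 ms before / 1.5 ms after the click peak, 15 ms click segments starting
#' 2 ms before the peak, the 25 ms inter-coda silence buffer, the 5 ms
#' spectrogram window, and the formant hyperparameter grid of start offsets
#' (-2.0, -1.5) ms crossed with segment durations (3.0, 3.5, 4.0, 4.5, 5.0,
#' 14.5, 15.0) ms. Tracker internals (ceiling ladder, LPC order, window/step,
#' smoothness weight, bandwidth cap) are declared implementation choices and
#' are recorded in output metadata.
#'
#' @param ... named overrides of any default listed in the source.
#' @return An object of class `analysis_config` (a named list).
#' @export
#' @examples
#' cfg <- analysis_config(seed = 7)
#' cfg$band_hz
analysis_config <- function(...) {
  cfg <- list(
    # spectral peak detection
    band_hz        = c(1000, 10000),
    min_sep_hz     = 1500,
    rel_height     = 0.25,
    # per-click Welch segment around the click peak
    welch_pre_ms   = 2.0,
    welch_post_ms  = 1.5,
    welch_window   = "hann",
    welch_nfft_pad = 1L,      # zero-padding factor; 1 = none (library default)
    # click segment extraction / time-insensitive assembly
    start_offset_ms = -2.0,
    segment_ms      = 15.0,
    peak_search_ms  = 15.0,   # window after annotated time to locate |x| max
    buffer_ms       = 25.0,
    # spectrogram rendering
    spec_window_ms  = 5.0,
    spec_fmax_hz    = 15000,
    # formant hyperparameter grid (extraction cells)
    grid_offsets_ms   = c(-2.0, -1.5),
    grid_durations_ms = c(3.0, 3.5, 4.0, 4.5, 5.0, 14.5, 15.0),
    # formant tracker internals (implementation choices, config-exposed)
    lpc_ceilings_hz    = round(exp(seq(log(7000), log(13000), length.out = 5))),
    lpc_order          = 6L,
    lpc_window_ms      = 5.0,
    lpc_step_ms        = 1.0,
    lpc_preemph_hz     = 50,
    lpc_bw_cap_hz      = 800,
    smoothness_weight  = 1.0,
    # GMM model selection
    gmm_k_range    = 1:5,
    gmm_restarts   = 5L,
    gmm_max_iter   = 300L,
    gmm_tol        = 1e-8,
    # exclusion filtering
    unknown_whale_ids = c("unknown", "UNKNOWN", ""),
    min_codas_per_whale = 35L,
    # dialogue / bouts
    overlap_s = 1.0,
    bout_gap_s = 10.0,
    # tube model
    sound_speed_m_s = 343,
    # reproducibility
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Write / read configuration as JSON
#'
#' @param cfg an `analysis_config`.
#' @param path file path.
#' @return `read_config` returns an `analysis_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "analysis_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}

# Log to stderr with a level prefix; shared by all stages.
cv_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}
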