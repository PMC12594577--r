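# Per-click spectral analysis: Welch PSD of a 3.5 ms window around each click
# peak (2.0 ms before, 1.5 ms after, i.e. roughly the first half of the
# inter-pulse interval), constrained peak detection in the 1-10 kHz band, and
# the discreteness statistics (a/i click labels, coda majority, mismatch
# histogram).

#' Welch spectrum of one click
#'
#' @param recording a [new_recording()].
#' @param cd a [coda()].
#' @param click_index 0-based click index.
#' @param pre_ms window before the click peak (default 2.0 ms).
#' @param post_ms window after the click peak (default 1.5 ms).
#' @param peak_search_ms peak localization window when no peak annotated.
#' @param nfft_pad zero-padding factor for a finer frequency grid (default 1,
#'   i.e. the raw resolution of the 3.5 ms window, ~286 Hz).
#' @return list with `freqs_hz`, `psd`, `segment_n`, `resolution_hz`.
#' @export
welch_click_spectrum <- function(recording, cd, click_index, pre_ms = 2.0,
                                 post_ms = 1.5, peak_search_ms = 15,
                                 nfft_pad = 1L) {
  fs <- recording$sample_rate_hz
  if (fs <= 20000) stop("sample rate too low for the 1-10 kHz analysis band")
  j <- which(cd$click_index == click_index)
  if (!length(j)) stop("click_index not found in coda")
  pk <- cd$peak_time_s[j]
  if (is.na(pk)) pk <- locate_click_peak(recording, cd$click_time_s[j], peak_search_ms)
  n_seg <- round((pre_ms + post_ms) / 1000 * fs)
  i0 <- round((pk - pre_ms / 1000) * fs) + 1L
  if (i0 < 1 || i0 + n_seg - 1 > length(recording$samples))
    stop("click window outside recording for coda ", cd$coda_id,
         " click ", click_index)
  seg <- recording$samples[i0:(i0 + n_seg - 1L)]
  ps <- welch_psd(seg, fs, nperseg = n_seg, nfft = n_seg * nfft_pad)
  list(freqs_hz = ps$freqs_hz, psd = ps$psd, segment_n = n_seg,
       resolution_hz = fs / (n_seg * nfft_pad))
}

#' Constrained spectral peak detection
#'
#' Local maxima of the PSD restricted to the analysis band (default
#' 1,000-10,000 Hz), with a minimum height of `rel_height` (default 25%) of
#' the highest PSD value in the band and a minimum separation of `min_sep_hz`
#' (default 1,500 Hz) enforced greedily by descending height, as in the
#' standard distance-constrained peak picking. Of the survivors, at most the
#' two highest are selected and returned in ascending frequency order
#' ("first" and "second" spectral peaks).
#'
#' @param freqs_hz frequency grid.
#' @param psd power spectral density values.
#' @param band analysis band (Hz).
#' @param min_sep_hz minimum distance between adjacent selected peaks.
#' @param rel_height minimum height as a fraction of the band maximum.
#' @param max_peaks how many of the highest surviving peaks to keep.
#' @return data.frame `freq_hz`, `height`, ascending in frequency (0-2 rows).
#' @export
find_constrained_peaks <- function(freqs_hz, psd, band = c(1000, 10000),
                                   min_sep_hz = 1500, rel_height = 0.25,
                                   max_peaks = 2L) {
  in_band <- which(freqs_hz >= band[1] & freqs_hz <= band[2])
  if (!length(in_band)) stop("analysis band outside the frequency grid")
  f <- freqs_hz[in_band]; p <- psd[in_band]
  n <- length(p)
  if (n < 3) return(data.frame(freq_hz = numeric(0), height = numeric(0)))
  # strict local maxima (plateaus resolved to their first sample)
  is_max <- logical(n)
  for (i in 2:(n - 1)) {
    if (p[i] > p[i - 1]) {
      k <- i
      while (k < n && p[k + 1] == p[i]) k <- k + 1
      if (k < n && p[k + 1] < p[i]) is_max[i] <- TRUE
    }
  }
  cand <- which(is_max)
  cand <- cand[p[cand] >= rel_height * max(p)]
  if (!length(cand)) return(data.frame(freq_hz = numeric(0), height = numeric(0)))
  # distance constraint: keep by descending height, discard neighbours
  cand <- cand[order(p[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(f[i] - f[kept]) >= min_sep_hz)) kept <- c(kept, i)
  }
  kept <- kept[seq_len(min(length(kept), max_peaks))]  # highest peaks first
  kept <- kept[order(f[kept])]
  data.frame(freq_hz = f[kept], height = p[kept])
}

#' Classify one click from its constrained peaks
#'
#' Two or more peaks in the band: i-type. Fewer: a-type (a zero-peak click is
#' a-type with a low-confidence flag).
#'
#' @param peaks data.frame from [find_constrained_peaks()].
#' @return character "a" or "i", with attribute `low_confidence = TRUE` when
#'   no peak at all was found.
#' @export
classify_click <- function(peaks) {
  lab <- if (nrow(peaks) >= 2) "i" else "a"
  if (nrow(peaks) == 0) attr(lab, "low_confidence") <- TRUE
  lab
}

#' Coda-level majority classification and mismatch count
#'
#' A click is mismatched if its label differs from the majority label of its
#' coda. Even splits are labeled "tie" (with n/2 mismatches) rather than
#' silently coerced.
#'
#' @param click_labels character vector of per-click "a"/"i" labels.
#' @param coda_id optional identifier carried through.
#' @return list with `coda_id`, `click_labels`, `majority_label`
#'   ("a"/"i"/"tie"), `n_mismatched`, `pct_mismatched`.
#' @export
classify_coda_majority <- function(click_labels, coda_id = NA_character_) {
  if (!length(click_labels)) stop("empty click label list")
  n_a <- sum(click_labels == "a"); n_i <- sum(click_labels == "i")
  if (n_a > n_i) {
    maj <- "a"; mism <- n_i
  } else if (n_i > n_a) {
    maj <- "i"; mism <- n_a
  } else {
    maj <- "tie"; mism <- n_a
  }
  list(coda_id = coda_id, click_labels = click_labels, majority_label = maj,
       n_mismatched = mism,
       pct_mismatched = 100 * mism / length(click_labels))
}

#' Histogram of codas by mismatched-click count
#'
#' @param classifications list of results from [classify_coda_majority()].
#' @return list of two data.frames: `by_count` (n_mismatched, n_codas, pct)
#'   and `by_pct` (pct bin label, n_codas, pct). The published corpus gives
#'   roughly 78% / 12% / 9% of codas with 0 / 1 / 2+ mismatched clicks; those
#'   are reference numbers for the field data, not assertions about synthetic
#'   runs.
#' @export
mismatch_summary <- function(classifications) {
  if (!length(classifications)) stop("no classifications")
  nm <- vapply(classifications, `[[`, 0, "n_mismatched")
  pm <- vapply(classifications, `[[`, 0, "pct_mismatched")
  tab <- table(nm)
  by_count <- data.frame(n_mismatched = as.integer(names(tab)),
                         n_codas = as.integer(tab),
                         pct = 100 * as.integer(tab) / length(nm))
  brk <- c(-0.001, 0.001, 10, 20, 30, 40, 50, 100)
  lab <- c("0", "(0,10]", "(10,20]", "(20,30]", "(30,40]", "(40,50]", ">50")
  cut_tab <- table(cut(pm, brk, labels = lab))
  by_pct <- data.frame(pct_bin = names(cut_tab), n_codas = as.integer(cut_tab),
                       pct = 100 * as.integer(cut_tab) / length(pm))
  list(by_count = by_count, by_pct = by_pct)
}

#' Per-click spectral analysis of a set of codas
#'
#' Runs [welch_click_spectrum()], [find_constrained_peaks()] and
#' [classify_click()] for every click, then [classify_coda_majority()] per
#' coda.
#'
#' @param recording a [new_recording()].
#' @param codas list of [coda()] objects.
#' @param cfg an [analysis_config()].
#' @return list with `clicks` (data.frame: coda_id, click_index, peak1_hz,
#'   peak2_hz, n_peaks, label) and `codas` (data.frame: coda_id, whale_id,
#'   majority_label, n_mismatched, pct_mismatched) and `majorities` (raw
#'   list).
#' @export
analyze_click_spectra <- function(recording, codas, cfg = analysis_config()) {
  click_rows <- list(); majorities <- vector("list", length(codas))
  for (i in seq_along(codas)) {
    cd <- codas[[i]]
    labs <- character(n_clicks(cd))
    for (j in seq_along(cd$click_index)) {
      sp <- welch_click_spectrum(recording, cd, cd$click_index[j],
                                 pre_ms = cfg$welch_pre_ms,
                                 post_ms = cfg$welch_post_ms,
                                 peak_search_ms = cfg$peak_search_ms,
                                 nfft_pad = cfg$welch_nfft_pad)
      pks <- find_constrained_peaks(sp$freqs_hz, sp$psd, cfg$band_hz,
                                    cfg$min_sep_hz, cfg$rel_height)
      labs[j] <- classify_click(pks)
      click_rows[[length(click_rows) + 1]] <- data.frame(
        coda_id = cd$coda_id, whale_id = cd$whale_id,
        click_index = cd$click_index[j],
        peak_time_s = cd$peak_time_s[j],
        peak1_hz = if (nrow(pks) >= 1) pks$freq_hz[1] else NA_real_,
        peak2_hz = if (nrow(pks) >= 2) pks$freq_hz[2] else NA_real_,
        n_peaks = nrow(pks), label = labs[j], stringsAsFactors = FALSE)
    }
    majorities[[i]] <- classify_coda_majority(labs, cd$coda_id)
  }
  clicks <- do.call(rbind, click_rows)
  coda_df <- data.frame(
    coda_id = vapply(majorities, `[[`, "", "coda_id"),
    whale_id = vapply(codas, `[[`, "", "whale_id"),
    majority_label = vapply(majorities, `[[`, "", "majority_label"),
    n_mismatched = vapply(majorities, `[[`, 0, "n_mismatched"),
    pct_mismatched = vapply(majorities, `[[`, 0, "pct_mismatched"),
    stringsAsFactors = FALSE)
  list(clicks = clicks, codas = coda_df, majorities = majorities)
}
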