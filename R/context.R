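# Context analyses: exclusion filtering, movement-spectrum correlation, the
# closed-tube resonance model, bout segmentation, and dialogue transcription.

#' Filter codas by the exclusion rules
#'
#' Two rules, mirroring the published corpus filter: (1) codas from an
#' unidentified whale are dropped; (2) whales with fewer than
#' `min_codas_per_whale` codas overall AND no i-type coda are dropped (a gap
#' that may be accidental at such counts). Every exclusion carries exactly one
#' reason; kept + excluded partition the input.
#'
#' @param codas list of [coda()] objects (or a data.frame with `coda_id`,
#'   `whale_id`, `hand_vowel` columns).
#' @param unknown_ids whale ids treated as unidentified.
#' @param min_codas_per_whale threshold for rule 2 (default 35).
#' @return list with `kept`, `excluded`, and `reasons` (data.frame coda_id,
#'   whale_id, reason) plus `counts` per reason.
#' @export
filter_codas <- function(codas, unknown_ids = c("unknown", "UNKNOWN", ""),
                         min_codas_per_whale = 35L) {
  df <- if (is.data.frame(codas)) codas else codas_summary(codas)
  whale <- df$whale_id
  vowel <- if ("hand_vowel" %in% names(df)) df$hand_vowel else rep(NA, nrow(df))
  reason <- rep(NA_character_, nrow(df))
  reason[whale %in% unknown_ids | is.na(whale)] <- "unknown_whale"
  counts <- table(whale[is.na(reason)])
  has_i <- tapply(vowel == "i" & !is.na(vowel), whale, any)
  for (w in names(counts)) {
    if (counts[[w]] < min_codas_per_whale && !isTRUE(has_i[[w]]))
      reason[whale == w & is.na(reason)] <- "sparse_whale_no_i"
  }
  kept_idx <- which(is.na(reason))
  excl_idx <- which(!is.na(reason))
  pick <- function(idx) if (is.data.frame(codas)) codas[idx, , drop = FALSE] else codas[idx]
  list(kept = pick(kept_idx), excluded = pick(excl_idx),
       reasons = data.frame(coda_id = df$coda_id[excl_idx],
                            whale_id = whale[excl_idx],
                            reason = reason[excl_idx], stringsAsFactors = FALSE),
       counts = as.list(table(reason[excl_idx])))
}

#' Pearson correlation of spectral peaks with movement channels
#'
#' Movement channels are linearly interpolated to the click (peak) times; the
#' Pearson coefficient is computed per channel over all paired observations
#' (pooled across whales; per-whale use is a matter of subsetting the input).
#' Constant series yield an undefined r, reported as NA with a reason.
#'
#' @param peak_hz per-click spectral peak frequencies (first constrained
#'   peak by convention).
#' @param time_s per-click times (s), same length.
#' @param movement a `movement_series`.
#' @param exclude_whales,whale_id optional: whale id per click and ids to
#'   drop before correlating (the reference analysis drops whales with
#'   known data-quality issues).
#' @return data.frame with one row per channel: `channel`, `r`, `n`, `note`.
#' @export
movement_correlation <- function(peak_hz, time_s, movement,
                                 exclude_whales = NULL, whale_id = NULL) {
  stopifnot(length(peak_hz) == length(time_s))
  keep <- is.finite(peak_hz) & is.finite(time_s)
  if (!is.null(exclude_whales) && !is.null(whale_id))
    keep <- keep & !(whale_id %in% exclude_whales)
  peak_hz <- peak_hz[keep]; time_s <- time_s[keep]
  if (length(peak_hz) < 3) stop("need at least 3 paired observations")
  mv <- movement_at(movement, time_s, "all")
  chans <- c(depth = "depth_m", head = "head_deg", pitch = "pitch_deg",
             roll = "roll_deg")
  rows <- lapply(names(chans), function(ch) {
    y <- mv[[chans[[ch]]]]
    if (stats::sd(y) == 0 || stats::sd(peak_hz) == 0)
      data.frame(channel = ch, r = NA_real_, n = length(y),
                 note = "constant series: r undefined", stringsAsFactors = FALSE)
    else
      data.frame(channel = ch, r = stats::cor(peak_hz, y), n = length(y),
                 note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Resonance of a simple tube closed at both ends
#'
#' f_n = n c / (2 L): the nth resonant frequency of a tube of length `L_m`
#' with sound speed `c_m_s` (343 m/s in air). Models the distal air sac as
#' the resonating filter.
#'
#' @param L_m tube length (m), positive.
#' @param n harmonic index (default 1).
#' @param c_m_s speed of sound (m/s).
#' @return frequency in Hz.
#' @export
tube_resonance_frequency <- function(L_m, n = 1, c_m_s = 343) {
  if (any(L_m <= 0)) stop("tube length must be positive")
  n * c_m_s / (2 * L_m)
}

#' Tube length producing a given resonance
#'
#' Algebraic inverse of [tube_resonance_frequency()]: L = n c / (2 f). A
#' 7,827 Hz first resonance corresponds to 2.2 cm; 6,397 Hz to just over
#' 2.7 cm.
#'
#' @param f_hz resonant frequency (Hz), positive.
#' @param n harmonic index.
#' @param c_m_s speed of sound (m/s).
#' @return length in metres.
#' @export
tube_length_for_frequency <- function(f_hz, n = 1, c_m_s = 343) {
  if (any(f_hz <= 0)) stop("frequency must be positive")
  n * c_m_s / (2 * f_hz)
}

#' Segment coda onsets into bouts
#'
#' A bout is a run of codas whose inter-onset gaps do not exceed `gap_s`
#' (default 10 s, inclusive: a gap of exactly 10 s stays within the bout).
#'
#' @param onset_s coda onset times (sorted internally).
#' @param gap_s maximum within-bout gap.
#' @return integer bout index per input onset (in input order).
#' @export
segment_bouts <- function(onset_s, gap_s = 10) {
  ord <- order(onset_s)
  t <- onset_s[ord]
  bout_sorted <- cumsum(c(1, as.integer(diff(t) > gap_s)))
  out <- integer(length(onset_s))
  out[ord] <- bout_sorted
  out
}

#' Transcribe a focal/non-focal dialogue
#'
#' Codas from both whales are merged chronologically; a focal and a non-focal
#' coda whose onsets differ by less than `overlap_s` (default 1 s) are
#' transcribed in the same row. Pairing is greedy by nearest onset; when a
#' coda could pair with more than one partner, the surplus coda gets its own
#' row with a flag (third-whale candidates are flagged, not resolved).
#'
#' @param focal,nonfocal data.frames with columns `coda_id`, `onset_s`, and
#'   optionally `coda_type` and `vowel`.
#' @param overlap_s pairing window in seconds.
#' @return data.frame with columns `focal_id`, `nonfocal_id`, `focal_type`,
#'   `nonfocal_type`, `focal_vowel`, `nonfocal_vowel`, `overlap` (logical),
#'   `flagged` (TRUE where a greedy conflict was detected), in chronological
#'   order.
#' @export
transcribe_dialogue <- function(focal, nonfocal, overlap_s = 1.0) {
  get_col <- function(df, col) if (col %in% names(df)) df[[col]] else rep(NA_character_, nrow(df))
  f <- data.frame(coda_id = focal$coda_id, onset_s = focal$onset_s,
                  coda_type = get_col(focal, "coda_type"),
                  vowel = get_col(focal, "vowel"), stringsAsFactors = FALSE)
  nf <- data.frame(coda_id = nonfocal$coda_id, onset_s = nonfocal$onset_s,
                   coda_type = get_col(nonfocal, "coda_type"),
                   vowel = get_col(nonfocal, "vowel"), stringsAsFactors = FALSE)
  f <- f[order(f$onset_s), , drop = FALSE]
  nf <- nf[order(nf$onset_s), , drop = FALSE]
  # candidate pairs within the window, greedy by |onset difference|
  pairs <- expand.grid(i = seq_len(nrow(f)), j = seq_len(nrow(nf)))
  pairs$d <- abs(f$onset_s[pairs$i] - nf$onset_s[pairs$j])
  pairs <- pairs[pairs$d < overlap_s, , drop = FALSE]
  pairs <- pairs[order(pairs$d), , drop = FALSE]
  pair_f <- rep(NA_integer_, nrow(f)); pair_nf <- rep(NA_integer_, nrow(nf))
  flagged_f <- logical(nrow(f)); flagged_nf <- logical(nrow(nf))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (is.na(pair_f[i]) && is.na(pair_nf[j])) {
      pair_f[i] <- j; pair_nf[j] <- i
    } else {
      # a coda within range of an already-paired partner: overlapping triple
      if (is.na(pair_f[i])) flagged_f[i] <- TRUE
      if (is.na(pair_nf[j])) flagged_nf[j] <- TRUE
    }
  }
  rows <- list()
  for (i in seq_len(nrow(f))) {
    j <- pair_f[i]
    rows[[length(rows) + 1]] <- data.frame(
      onset_s = f$onset_s[i],
      focal_id = f$coda_id[i],
      nonfocal_id = if (!is.na(j)) nf$coda_id[j] else NA_character_,
      focal_type = f$coda_type[i],
      nonfocal_type = if (!is.na(j)) nf$coda_type[j] else NA_character_,
      focal_vowel = f$vowel[i],
      nonfocal_vowel = if (!is.na(j)) nf$vowel[j] else NA_character_,
      overlap = !is.na(j), flagged = flagged_f[i], stringsAsFactors = FALSE)
  }
  for (j in which(is.na(pair_nf))) {
    rows[[length(rows) + 1]] <- data.frame(
      onset_s = nf$onset_s[j], focal_id = NA_character_,
      nonfocal_id = nf$coda_id[j], focal_type = NA_character_,
      nonfocal_type = nf$coda_type[j], focal_vowel = NA_character_,
      nonfocal_vowel = nf$vowel[j], overlap = FALSE, flagged = flagged_nf[j],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}
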