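# LPC formant tracking over time-insensitive codas. Candidate analyses are
# produced along a ladder of formant ceilings (the signal is resampled to
# twice the ceiling before autocorrelation LPC); a dynamic program then picks,
# per frame, the ceiling whose formants give the smoothest trajectory —
# minimal frame-to-frame |delta log f| plus a bandwidth-fraction penalty.
# This mirrors the multi-candidate "smoothest path" approach used for short
# speech segments.

#' LPC formant candidates for every analysis frame
#'
#' For one ceiling: the signal is resampled to 2x the ceiling, pre-emphasized,
#' cut into Gaussian-windowed frames, and each frame is fit with an
#' autocorrelation LPC of the given order. Roots of the prediction polynomial
#' give (frequency, bandwidth) pairs; roots outside (0, ceiling) or above the
#' bandwidth cap are rejected. Frames where the fit degenerates come back
#' empty.
#'
#' @param samples signal (typically a time-insensitive coda).
#' @param sample_rate_hz original sampling rate.
#' @param ceiling_hz formant ceiling; must be at most Nyquist.
#' @param order LPC order (default 6: two pole pairs for the expected one or
#'   two resonances plus a spectral-tilt pair; higher orders admit spurious
#'   noise poles on these short click segments).
#' @param window_ms,step_ms frame length and hop in ms (defaults 5, 1).
#' @param preemph_hz pre-emphasis cutoff (default 50 Hz).
#' @param bw_cap_hz maximum admissible formant bandwidth (default 800 Hz).
#' @return list of data.frames (`freq_hz`, `bw_hz`), one per frame, plus
#'   attribute `frame_times_ms` (frame centres).
#' @export
lpc_candidate_frames <- function(samples, sample_rate_hz, ceiling_hz,
                                 order = 6L, window_ms = 5, step_ms = 1,
                                 preemph_hz = 50, bw_cap_hz = 800) {
  if (ceiling_hz > sample_rate_hz / 2) stop("ceiling above Nyquist")
  fs2 <- 2 * ceiling_hz
  n2 <- max(16L, round(length(samples) * fs2 / sample_rate_hz))
  x <- resample_fft(samples, n2)
  x <- pre_emphasize(x, fs2, preemph_hz)
  win_n <- round(window_ms / 1000 * fs2)
  if (win_n < 2 * order) stop("window too short for LPC order ", order)
  step_n <- max(1L, round(step_ms / 1000 * fs2))
  # frame grid in original time so candidate analyses align across ceilings
  dur_ms <- length(samples) / sample_rate_hz * 1000
  starts_ms <- seq(0, dur_ms - window_ms, by = step_ms)
  if (!length(starts_ms)) starts_ms <- 0
  w <- gaussian_window(win_n)
  frames <- vector("list", length(starts_ms))
  for (k in seq_along(starts_ms)) {
    i0 <- round(starts_ms[k] / 1000 * fs2) + 1L
    idx <- i0:min(n2, i0 + win_n - 1L)
    seg <- x[idx]
    if (length(seg) < win_n) seg <- c(seg, numeric(win_n - length(seg)))
    a <- lpc_coefficients(seg * w, order)
    if (is.null(a)) {
      frames[[k]] <- data.frame(freq_hz = numeric(0), bw_hz = numeric(0))
      next
    }
    fm <- lpc_root_formants(a, fs2)
    fm <- fm[fm$freq_hz > 0 & fm$freq_hz < ceiling_hz & fm$bw_hz < bw_cap_hz, ,
             drop = FALSE]
    frames[[k]] <- fm
  }
  attr(frames, "frame_times_ms") <- starts_ms + window_ms / 2
  frames
}

# F1/F2 selection from one frame's candidates: the lowest one or two
# candidates inside the analysis band (mirroring the click-spectra band).
select_f1_f2 <- function(fm, band = c(1000, 10000)) {
  fm <- fm[fm$freq_hz > band[1] & fm$freq_hz < band[2], , drop = FALSE]
  fm[seq_len(min(2L, nrow(fm))), , drop = FALSE]
}

#' Smoothest-path formant track
#'
#' Runs [lpc_candidate_frames()] for every ceiling on the ladder and chooses
#' one candidate analysis per frame by minimizing a global cost: the sum over
#' consecutive frames of |delta log f| across shared formants, plus
#' `smoothness_weight` times the per-frame mean normalized bandwidth (bw/f),
#' plus a fixed penalty when the number of tracked formants changes between
#' frames. The optimum over ceiling assignments is found by dynamic
#' programming.
#'
#' @param samples signal (a time-insensitive coda).
#' @param sample_rate_hz sampling rate.
#' @param ceilings_hz ceiling ladder (>= 2 values; default log-spaced
#'   7-13 kHz).
#' @param smoothness_weight weight of the bandwidth term (default 1).
#' @param band formants outside this band are not counted toward F1/F2.
#' @param count_change_penalty cost per unit change in formant count between
#'   consecutive frames.
#' @param ... passed to [lpc_candidate_frames()].
#' @return `formant_track`: list with `frames` data.frame (`frame_ms`,
#'   `ceiling_hz`, `f1_hz`, `b1_hz`, `f2_hz`, `b2_hz`; F2 columns NA when
#'   absent), `path_cost`, and `vowel_label` from
#'   [classify_coda_from_formants()].
#' @export
formant_path <- function(samples, sample_rate_hz,
                         ceilings_hz = round(exp(seq(log(7000), log(13000),
                                                     length.out = 5))),
                         smoothness_weight = 1.0, band = c(1000, 10000),
                         count_change_penalty = 0.5, ...) {
  ceilings_hz <- ceilings_hz[ceilings_hz <= sample_rate_hz / 2]
  if (length(ceilings_hz) < 2)
    stop("need at least 2 usable ceilings below Nyquist")
  per_ceiling <- lapply(ceilings_hz, function(cl)
    lpc_candidate_frames(samples, sample_rate_hz, cl, ...))
  times_ms <- attr(per_ceiling[[1]], "frame_times_ms")
  n_t <- length(times_ms); n_c <- length(ceilings_hz)
  # candidate F1/F2 per (frame, ceiling)
  cand <- vector("list", n_t)
  for (t in seq_len(n_t)) cand[[t]] <- lapply(per_ceiling, function(fr)
    select_f1_f2(fr[[t]], band))
  local_cost <- function(fm) {
    if (nrow(fm) == 0) return(5)                 # empty frame is expensive
    mean(fm$bw_hz / fm$freq_hz)
  }
  trans_cost <- function(a, b) {
    m <- min(nrow(a), nrow(b))
    cost <- count_change_penalty * abs(nrow(a) - nrow(b))
    if (m > 0) cost <- cost + sum(abs(log(b$freq_hz[1:m]) - log(a$freq_hz[1:m])))
    cost
  }
  # dynamic programming over ceiling choice per frame
  D <- matrix(Inf, n_t, n_c); back <- matrix(0L, n_t, n_c)
  for (c in seq_len(n_c))
    D[1, c] <- smoothness_weight * local_cost(cand[[1]][[c]])
  if (n_t > 1) for (t in 2:n_t) for (c in seq_len(n_c)) {
    lc <- smoothness_weight * local_cost(cand[[t]][[c]])
    costs <- vapply(seq_len(n_c), function(cp)
      D[t - 1, cp] + trans_cost(cand[[t - 1]][[cp]], cand[[t]][[c]]), 0)
    back[t, c] <- which.min(costs)
    D[t, c] <- costs[back[t, c]] + lc
  }
  path <- integer(n_t)
  path[n_t] <- which.min(D[n_t, ])
  if (n_t > 1) for (t in (n_t - 1):1) path[t] <- back[t + 1, path[t + 1]]
  frames <- do.call(rbind, lapply(seq_len(n_t), function(t) {
    fm <- cand[[t]][[path[t]]]
    data.frame(frame_ms = times_ms[t], ceiling_hz = ceilings_hz[path[t]],
               f1_hz = if (nrow(fm) >= 1) fm$freq_hz[1] else NA_real_,
               b1_hz = if (nrow(fm) >= 1) fm$bw_hz[1] else NA_real_,
               f2_hz = if (nrow(fm) >= 2) fm$freq_hz[2] else NA_real_,
               b2_hz = if (nrow(fm) >= 2) fm$bw_hz[2] else NA_real_)
  }))
  if (all(is.na(frames$f1_hz))) stop("no formant candidates in any frame")
  track <- structure(list(frames = frames, path_cost = min(D[n_t, ])),
                     class = "formant_track")
  track$vowel_label <- classify_coda_from_formants(track)
  track
}

#' Coda vowel label from a formant track
#'
#' i-type if every analysis frame has both F1 and F2; a-type if F2 is present
#' in no frame; mixed presence is left unclassified (rendered "?" in
#' transcriptions). Frame order is irrelevant.
#'
#' @param track a `formant_track` (or its `frames` data.frame).
#' @return "a", "i", or "unclassified".
#' @export
classify_coda_from_formants <- function(track) {
  frames <- if (inherits(track, "formant_track")) track$frames else track
  if (!nrow(frames)) stop("empty track")
  has_f2 <- !is.na(frames$f2_hz)
  has_f1 <- !is.na(frames$f1_hz)
  if (all(has_f1 & has_f2)) "i"
  else if (!any(has_f2)) "a"
  else "unclassified"
}

#' Run the formant hyperparameter grid
#'
#' For every cell of the extraction grid (start offset x segment duration; the
#' defaults give the 2 x 7 = 14 published cells) every coda is re-assembled
#' into a time-insensitive coda with those extraction parameters, tracked, and
#' classified; agreement with the hand vowel labels is scored per whale.
#'
#' @param recording a [new_recording()].
#' @param codas list of [coda()] objects; those without a hand label in
#'   `c("a","i")` are not scored.
#' @param cfg an [analysis_config()] (supplies grid values and tracker
#'   settings).
#' @return list with `results` (data.frame: whale_id, pset_id,
#'   start_offset_ms, segment_ms, n_scored, n_agree, pct_agree) and
#'   `coda_tracks` (data.frame per coda x pset: label, mean F1/F2 over
#'   frames).
#' @export
run_hyperparameter_grid <- function(recording, codas,
                                    cfg = analysis_config()) {
  grid <- expand.grid(start_offset_ms = cfg$grid_offsets_ms,
                      segment_ms = cfg$grid_durations_ms)
  grid$pset_id <- sprintf("p%02d", seq_len(nrow(grid)))
  hand <- vapply(codas, `[[`, "", "hand_vowel")
  scored <- which(hand %in% c("a", "i"))
  whales <- vapply(codas, `[[`, "", "whale_id")
  if (!length(scored)) stop("no hand-labeled codas to score")
  dropped <- setdiff(unique(whales), unique(whales[scored]))
  for (w in dropped)
    cv_log("WARN", "whale ", w, " has no hand-labeled codas; excluded from grid scoring")

  track_rows <- list(); res_rows <- list()
  for (g in seq_len(nrow(grid))) {
    labels <- rep(NA_character_, length(codas))
    for (i in scored) {
      tic <- time_insensitive_coda(recording, codas[[i]],
                                   start_offset_ms = grid$start_offset_ms[g],
                                   duration_ms = grid$segment_ms[g],
                                   peak_search_ms = cfg$peak_search_ms)
      tr <- tryCatch(
        formant_path(tic$samples, tic$sample_rate_hz,
                     ceilings_hz = cfg$lpc_ceilings_hz,
                     smoothness_weight = cfg$smoothness_weight,
                     band = cfg$band_hz, order = cfg$lpc_order,
                     window_ms = cfg$lpc_window_ms, step_ms = cfg$lpc_step_ms,
                     preemph_hz = cfg$lpc_preemph_hz,
                     bw_cap_hz = cfg$lpc_bw_cap_hz),
        error = function(e) NULL)
      if (is.null(tr)) next
      labels[i] <- tr$vowel_label
      track_rows[[length(track_rows) + 1]] <- data.frame(
        coda_id = codas[[i]]$coda_id, whale_id = whales[i],
        pset_id = grid$pset_id[g], hand_vowel = hand[i],
        label = tr$vowel_label,
        mean_f1_hz = mean(tr$frames$f1_hz, na.rm = TRUE),
        mean_f2_hz = if (all(is.na(tr$frames$f2_hz))) NA_real_
                     else mean(tr$frames$f2_hz, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
    for (w in unique(whales[scored])) {
      idx <- scored[whales[scored] == w]
      ok <- !is.na(labels[idx])
      res_rows[[length(res_rows) + 1]] <- data.frame(
        whale_id = w, pset_id = grid$pset_id[g],
        start_offset_ms = grid$start_offset_ms[g],
        segment_ms = grid$segment_ms[g],
        n_scored = sum(ok), n_agree = sum(labels[idx][ok] == hand[idx][ok]),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res_rows)
  results$pct_agree <- 100 * results$n_agree / pmax(results$n_scored, 1)
  list(results = results, coda_tracks = do.call(rbind, track_rows),
       grid = grid)
}

#' Per-whale report over the best hyperparameter sets
#'
#' For each whale: the maximal hand-label agreement, the number of
#' hyperparameter sets tied at that maximum (`psetsN`), hand-labeled a/i coda
#' counts, and formant means computed from all tied best sets (frame means per
#' coda, averaged over codas, then over tied sets), grouped by hand label.
#'
#' @param grid_out result of [run_hyperparameter_grid()].
#' @return data.frame, one row per whale: `whale_id`, `psetsN`, `pct_agree`,
#'   `n_a`, `a_f1_hz`, `n_i`, `i_f1_hz`, `i_f2_hz`.
#' @export
best_pset_report <- function(grid_out) {
  res <- grid_out$results; tracks <- grid_out$coda_tracks
  rows <- lapply(split(res, res$whale_id), function(rw) {
    best <- max(rw$pct_agree)
    best_psets <- rw$pset_id[rw$pct_agree == best]
    tw <- tracks[tracks$whale_id == rw$whale_id[1] &
                 tracks$pset_id %in% best_psets, , drop = FALSE]
    mean_over <- function(sub, col) {
      if (!nrow(sub)) return(NA_real_)
      per_pset <- tapply(sub[[col]], sub$pset_id, mean, na.rm = TRUE)
      mean(per_pset, na.rm = TRUE)
    }
    a_cod <- tw[tw$hand_vowel == "a", , drop = FALSE]
    i_cod <- tw[tw$hand_vowel == "i", , drop = FALSE]
    data.frame(
      whale_id = rw$whale_id[1], psetsN = length(best_psets),
      pct_agree = best,
      n_a = length(unique(a_cod$coda_id)),
      a_f1_hz = mean_over(a_cod, "mean_f1_hz"),
      n_i = length(unique(i_cod$coda_id)),
      i_f1_hz = mean_over(i_cod, "mean_f1_hz"),
      i_f2_hz = mean_over(i_cod, "mean_f2_hz"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
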