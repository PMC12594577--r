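# Source-filter synthetic coda generator. Clicks are modelled as impulse
# excitations (one per pulse, the first strongest) passed through a cascade of
# two-pole resonators whose centre frequencies encode the coda "vowel":
# a-type has one resonance (default 5,780 Hz), i-type two (3,757 and 6,579 Hz,
# the reported population means). Diphthong-like codas move the resonances
# across clicks following a piecewise-linear trajectory law.

#' Specify a synthetic coda vowel
#'
#' @param label "a" (one formant) or "i" (two formants).
#' @param formant_centers_hz formant centres; defaults 5780 (a) or
#'   c(3757, 6579) (i).
#' @param bandwidths_hz per-formant 3 dB bandwidths (default 400).
#' @param trajectory one of "level", "rising", "falling", "rise_fall",
#'   "fall_rise" — how centres move across clicks.
#' @param trajectory_span_hz total excursion in Hz across the coda (free
#'   parameter; the published analysis reports trajectories qualitatively).
#' @param first_click_offset_hz optional extra Hz added to the first click's
#'   centres (emulating codas whose first click sits substantially higher).
#' @return `vowel_spec` object.
#' @export
vowel_spec <- function(label = c("a", "i"), formant_centers_hz = NULL,
                       bandwidths_hz = NULL, trajectory = "level",
                       trajectory_span_hz = 1400, first_click_offset_hz = 0) {
  label <- match.arg(label)
  if (is.null(formant_centers_hz))
    formant_centers_hz <- if (label == "a") 5780 else c(3757, 6579)
  nf <- length(formant_centers_hz)
  if (label == "a" && nf != 1) stop("a-vowel requires exactly 1 formant centre")
  if (label == "i") {
    if (nf != 2) stop("i-vowel requires exactly 2 formant centres")
    if (diff(sort(formant_centers_hz)) < 1500)
      stop("i-vowel centres must be separated by at least 1,500 Hz")
  }
  if (any(formant_centers_hz <= 1000 | formant_centers_hz >= 10000))
    stop("formant centres must lie in (1,000, 10,000) Hz")
  if (is.null(bandwidths_hz)) bandwidths_hz <- rep(400, nf)
  if (length(bandwidths_hz) == 1) bandwidths_hz <- rep(bandwidths_hz, nf)
  trajectory <- match.arg(trajectory,
    c("level", "rising", "falling", "rise_fall", "fall_rise"))
  structure(list(label = label, formant_centers_hz = sort(formant_centers_hz),
                 bandwidths_hz = bandwidths_hz, trajectory = trajectory,
                 trajectory_span_hz = trajectory_span_hz,
                 first_click_offset_hz = first_click_offset_hz),
            class = "vowel_spec")
}

#' Specify a coda's click-timing template
#'
#' Built-in templates follow the traditional type grammar: "1+1+3" is five
#' clicks with the first two inter-click intervals long and the next two
#' short; "5R1"/"5R2" are five regularly spaced clicks (shorter/longer
#' duration variant). Each click carries `pulses_per_click` pulses separated
#' by the inter-pulse interval (IPI; the reported focal-click mean first-to-
#' second pulse time is 3.1 ms), with geometrically decaying amplitude.
#'
#' @param coda_type template name or any traditional type string; unknown
#'   types require explicit `icis_s`.
#' @param icis_s inter-click intervals (s); defaults supplied for the
#'   built-ins.
#' @param ipi_s inter-pulse interval within a click (default 0.0031 s).
#' @param pulses_per_click number of pulses (default 2, first strongest).
#' @param pulse_decay amplitude ratio of successive pulses (default 0.5).
#' @return `coda_template` object with `n_clicks = length(icis_s) + 1`.
#' @export
coda_template <- function(coda_type = "1+1+3", icis_s = NULL, ipi_s = 0.0031,
                          pulses_per_click = 2L, pulse_decay = 0.5) {
  if (is.null(icis_s)) {
    icis_s <- switch(coda_type,
      "1+1+3" = c(0.35, 0.35, 0.18, 0.18),
      "5R1"   = rep(0.20, 4),
      "5R2"   = rep(0.30, 4),
      stop("no built-in ICI template for type '", coda_type,
           "'; supply icis_s"))
  }
  if (any(icis_s <= 0)) stop("all inter-click intervals must be positive")
  if (ipi_s >= min(icis_s)) stop("ipi_s must be shorter than the shortest ICI")
  structure(list(coda_type = coda_type, icis_s = as.numeric(icis_s),
                 n_clicks = length(icis_s) + 1L, ipi_s = ipi_s,
                 pulses_per_click = as.integer(pulses_per_click),
                 pulse_decay = pulse_decay),
            class = "coda_template")
}

#' Synthesize a single click
#'
#' Unit impulse passed through a cascade of two-pole resonator sections, one
#' per formant. A section with centre f and bandwidth b at rate fs has poles
#' at radius exp(-pi b / fs) and angle 2 pi f / fs, so the output is a sum of
#' exponentially decaying sinusoids whose spectral maxima sit at the requested
#' centres.
#'
#' @param formants data.frame with columns `center_hz`, `bw_hz`, and
#'   optionally `gain` (default 1).
#' @param duration_s output duration (s).
#' @param sample_rate_hz sampling rate; centres must be below Nyquist.
#' @return numeric amplitude vector of `round(duration_s * sample_rate_hz)`
#'   samples, peak-normalized to 1 unless all-zero.
#' @export
synthesize_click <- function(formants, duration_s, sample_rate_hz) {
  stopifnot(is.data.frame(formants), nrow(formants) >= 1)
  if (any(formants$center_hz >= sample_rate_hz / 2))
    stop("formant centre at or above Nyquist")
  if (any(formants$bw_hz <= 0)) stop("bandwidths must be positive")
  n <- round(duration_s * sample_rate_hz)
  if (n < 8) stop("duration too short to resolve the resonance")
  gain <- if ("gain" %in% names(formants)) formants$gain else rep(1, nrow(formants))
  x <- c(prod(gain), numeric(n - 1))     # impulse excitation
  for (k in seq_len(nrow(formants))) {
    r <- exp(-pi * formants$bw_hz[k] / sample_rate_hz)
    th <- 2 * pi * formants$center_hz[k] / sample_rate_hz
    x <- as.numeric(stats::filter(x, c(2 * r * cos(th), -r^2),
                                  method = "recursive"))
  }
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk
  x
}

# Per-click formant centres under the trajectory law: linear in click index,
# with rise_fall / fall_rise turning at the middle click. Returns an
# n_clicks x n_formants matrix.
trajectory_centers <- function(vowel, n_clicks) {
  base <- vowel$formant_centers_hz
  span <- vowel$trajectory_span_hz
  j <- seq_len(n_clicks)
  delta <- switch(vowel$trajectory,
    level   = rep(0, n_clicks),
    rising  = if (n_clicks == 1) 0 else -span / 2 + span * (j - 1) / (n_clicks - 1),
    falling = if (n_clicks == 1) 0 else  span / 2 - span * (j - 1) / (n_clicks - 1),
    rise_fall = {
      m <- ceiling(n_clicks / 2)
      up <- if (m > 1) span * (pmin(j, m) - 1) / (m - 1) else rep(span, n_clicks)
      dn <- if (n_clicks > m) span * (pmax(j, m) - m) / (n_clicks - m) else 0
      up - dn
    },
    fall_rise = {
      m <- ceiling(n_clicks / 2)
      up <- if (m > 1) span * (pmin(j, m) - 1) / (m - 1) else rep(span, n_clicks)
      dn <- if (n_clicks > m) span * (pmax(j, m) - m) / (n_clicks - m) else 0
      -(up - dn)
    })
  centers <- outer(delta, rep(1, length(base))) +
    outer(rep(1, n_clicks), base)
  centers[1, ] <- centers[1, ] + vowel$first_click_offset_hz
  pmax(pmin(centers, 9500), 1200)
}

#' Synthesize one coda
#'
#' Clicks are placed at cumulative inter-click-interval times; each click is a
#' pulse train (pulses `ipi_s` apart, amplitudes decaying by `pulse_decay`)
#' filtered by the vowel's resonators, with per-click formant centres
#' following the trajectory law. White Gaussian noise is added at the stated
#' SNR (power ratio against the click portions of the waveform).
#'
#' @param template [coda_template()].
#' @param vowel [vowel_spec()].
#' @param sample_rate_hz sampling rate (Hz); must exceed 20 kHz.
#' @param snr_db signal-to-noise ratio in dB (default 30; Inf for noiseless).
#' @param seed integer RNG seed (noise only).
#' @param coda_id,whale_id identifiers for the emitted annotation.
#' @param onset_s time of the first click in the output (default 0.1 s of
#'   leading context).
#' @param tail_s trailing duration after the last click (default 0.1 s).
#' @return list with `samples`, `sample_rate_hz`, `coda` (a [coda()] with
#'   exact click and peak times), and `truth` (per-click data.frame:
#'   vowel/trajectory labels and true formant centres).
#' @export
synthesize_coda <- function(template, vowel, sample_rate_hz = 96000,
                            snr_db = 30, seed = NULL, coda_id = "syn1",
                            whale_id = "SYNTH", onset_s = 0.1, tail_s = 0.1) {
  stopifnot(inherits(template, "coda_template"), inherits(vowel, "vowel_spec"))
  if (sample_rate_hz <= 20000) stop("sample_rate_hz must exceed 20 kHz")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fs <- sample_rate_hz
  nc <- template$n_clicks
  click_times <- onset_s + c(0, cumsum(template$icis_s))
  # quantize to the sample grid so annotated times index exact samples
  click_times <- round(click_times * fs) / fs
  click_dur_s <- template$ipi_s * (template$pulses_per_click - 1) + 0.008
  total_n <- round((max(click_times) + click_dur_s + tail_s) * fs)
  y <- numeric(total_n)
  centers <- trajectory_centers(vowel, nc)
  peak_times <- numeric(nc)
  for (j in seq_len(nc)) {
    fmts <- data.frame(center_hz = centers[j, ],
                       bw_hz = vowel$bandwidths_hz, gain = 1)
    click <- synthesize_click(fmts, click_dur_s, fs)
    # pulse train: replicate the filtered impulse response at IPI offsets
    w <- numeric(length(click))
    for (p in seq_len(template$pulses_per_click)) {
      off <- round((p - 1) * template$ipi_s * fs)
      amp <- template$pulse_decay^(p - 1)
      idx <- seq_len(length(click) - off)
      w[idx + off] <- w[idx + off] + amp * click[idx]
    }
    i0 <- round(click_times[j] * fs) + 1L
    idx <- i0:min(total_n, i0 + length(w) - 1L)
    y[idx] <- y[idx] + w[seq_along(idx)]
    peak_times[j] <- (i0 - 1L + which.max(abs(w[seq_along(idx)])) - 1L) / fs
  }
  if (is.finite(snr_db)) {
    active <- abs(y) > 0
    sig_rms <- sqrt(mean(y[active]^2))
    y <- y + stats::rnorm(total_n, sd = sig_rms * 10^(-snr_db / 20))
  }
  cd <- coda(coda_id, whale_id, click_time_s = click_times,
             peak_time_s = peak_times, coda_type = template$coda_type,
             hand_vowel = vowel$label)
  truth <- data.frame(
    coda_id = coda_id, whale_id = whale_id, click_index = seq_len(nc) - 1L,
    vowel = vowel$label, trajectory = vowel$trajectory,
    f1_true_hz = centers[, 1],
    f2_true_hz = if (ncol(centers) > 1) centers[, 2] else NA_real_,
    click_time_s = click_times, peak_time_s = peak_times,
    stringsAsFactors = FALSE)
  list(samples = y, sample_rate_hz = fs, coda = cd, truth = truth)
}

#' Default synthetic-dataset configuration
#'
#' States the world the generator emulates: a handful of tagged whales
#' producing mostly level a/i codas of the common Eastern Caribbean types,
#' with occasional diphthong trajectories, 30 dB SNR, and a slow dive profile
#' whose coupling to formant centres is configurable (0 = null regime; ~0.6
#' emulates the observed depth correlation regime).
#'
#' @param n_codas_per_whale named integer vector (names = whale ids).
#' @param vowel_mix named proportions for a/i (default 60/40).
#' @param trajectory_mix named proportions over trajectory labels.
#' @param coda_type_mix named proportions over built-in templates.
#' @param sample_rate_hz audio rate (default 96 kHz fixture rate).
#' @param snr_db synthesis SNR.
#' @param center_sd_hz between-coda spread of formant centres (Hz).
#' @param depth_coupling correlation between standardized depth and the
#'   per-coda formant-centre displacement (in [-1, 1]).
#' @param gap_s_range uniform range of silent gaps between codas (s).
#' @return configuration list for [synthesize_dataset()].
#' @export
synthetic_config <- function(n_codas_per_whale = c(ATW = 6, FRK = 6, PIN = 6),
                             vowel_mix = c(a = 0.6, i = 0.4),
                             trajectory_mix = c(level = 0.8, rising = 0.06,
                                                falling = 0.06,
                                                rise_fall = 0.04,
                                                fall_rise = 0.04),
                             coda_type_mix = c("1+1+3" = 0.6, "5R1" = 0.2,
                                               "5R2" = 0.2),
                             sample_rate_hz = 96000, snr_db = 30,
                             center_sd_hz = 400, depth_coupling = 0,
                             gap_s_range = c(0.5, 2)) {
  list(n_codas_per_whale = n_codas_per_whale, vowel_mix = vowel_mix,
       trajectory_mix = trajectory_mix, coda_type_mix = coda_type_mix,
       sample_rate_hz = sample_rate_hz, snr_db = snr_db,
       center_sd_hz = center_sd_hz, depth_coupling = depth_coupling,
       gap_s_range = gap_s_range)
}

#' Synthesize a full annotated dataset
#'
#' Generates one continuous recording with all requested codas laid out
#' sequentially (whales interleaved), a movement trace (slow dive profile plus
#' smoothed attitude noise), per-click ground truth, and — if `outdir` is
#' given — WAV + annotations/movement/truth CSVs plus a config/seed manifest.
#' A pure function of `(config, seed)`: the same pair reproduces every file
#' byte for byte.
#'
#' @param config from [synthetic_config()].
#' @param seed integer seed.
#' @param outdir optional output directory.
#' @return list with `recording`, `codas` (list of [coda()]), `movement`
#'   (`movement_series`), `truth` (data.frame), and `paths` when written.
#' @export
synthesize_dataset <- function(config = synthetic_config(), seed = 1L,
                               outdir = NULL) {
  n_total <- sum(config$n_codas_per_whale)
  if (n_total < 1) stop("config requests zero codas")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fs <- config$sample_rate_hz

  whale_ids <- rep(names(config$n_codas_per_whale), config$n_codas_per_whale)
  whale_ids <- sample(whale_ids)             # interleave whales
  vowels <- sample(names(config$vowel_mix), n_total, TRUE, config$vowel_mix)
  trajs <- sample(names(config$trajectory_mix), n_total, TRUE,
                  config$trajectory_mix)
  types <- sample(names(config$coda_type_mix), n_total, TRUE,
                  config$coda_type_mix)
  gaps <- stats::runif(n_total, config$gap_s_range[1], config$gap_s_range[2])

  # movement trace: slow sinusoidal dive plus smoothed noise; attitude
  # channels are smoothed white noise in degrees
  approx_len_s <- n_total * 2.5 + 10
  t_grid <- seq(0, approx_len_s * 1.5, by = 0.5)
  smooth <- function(x, k = 9) as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)) |>
    (\(v) { v[is.na(v)] <- x[is.na(v)]; v })()
  depth <- 350 + 150 * sin(2 * pi * t_grid / 900) + smooth(stats::rnorm(length(t_grid), sd = 40))
  depth <- pmax(depth, 0)
  mv <- movement_series(t_grid, depth,
                        head_deg = smooth(stats::rnorm(length(t_grid), sd = 25)),
                        pitch_deg = smooth(stats::rnorm(length(t_grid), sd = 15)),
                        roll_deg = smooth(stats::rnorm(length(t_grid), sd = 20)))
  z_depth_fun <- function(t) {
    (movement_at(mv, t, "depth") - mean(mv$depth_m)) / stats::sd(mv$depth_m)
  }

  waves <- vector("list", n_total)
  codas <- vector("list", n_total)
  truths <- vector("list", n_total)
  t_cursor <- 0
  rho <- config$depth_coupling
  for (i in seq_len(n_total)) {
    tmpl <- coda_template(types[i])
    # per-coda centre displacement: correlated with standardized depth at the
    # coda onset through the coupling coefficient
    z <- rho * z_depth_fun(t_cursor + 0.1) +
      sqrt(max(0, 1 - rho^2)) * stats::rnorm(1)
    shift <- config$center_sd_hz * z
    base <- if (vowels[i] == "a") 5780 else c(3757, 6579)
    vw <- vowel_spec(vowels[i], formant_centers_hz = pmax(pmin(base + shift, 9400), 1300),
                     trajectory = trajs[i])
    syn <- synthesize_coda(tmpl, vw, fs, snr_db = config$snr_db,
                           coda_id = sprintf("c%04d", i), whale_id = whale_ids[i],
                           onset_s = 0.05, tail_s = 0.05)
    waves[[i]] <- syn$samples
    # shift times to absolute position in the session recording
    cd <- syn$coda
    cd$click_time_s <- cd$click_time_s + t_cursor
    cd$peak_time_s <- cd$peak_time_s + t_cursor
    codas[[i]] <- cd
    tr <- syn$truth
    tr$click_time_s <- tr$click_time_s + t_cursor
    tr$peak_time_s <- tr$peak_time_s + t_cursor
    truths[[i]] <- tr
    t_cursor <- t_cursor + length(syn$samples) / fs + gaps[i]
  }
  # assemble session audio with exact-zero gaps
  total_n <- round(t_cursor * fs)
  samples <- numeric(total_n)
  pos_s <- 0
  for (i in seq_len(n_total)) {
    i0 <- round((codas[[i]]$click_time_s[1] - 0.05) * fs) + 1L
    idx <- i0:(i0 + length(waves[[i]]) - 1L)
    samples[idx] <- waves[[i]]
  }
  rec <- new_recording(samples, fs)
  truth <- do.call(rbind, truths)
  truth$depth_m <- movement_at(mv, truth$click_time_s, "depth")

  out <- list(recording = rec, codas = codas, movement = mv, truth = truth,
              seed = seed, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      wav = file.path(outdir, "session.wav"),
      annotations = file.path(outdir, "annotations.csv"),
      movement = file.path(outdir, "movement.csv"),
      truth = file.path(outdir, "truth.csv"),
      manifest = file.path(outdir, "manifest.json"))
    write_wav(rec$samples, fs, paths$wav)
    write_annotations(codas, paths$annotations)
    write_movement(mv, paths$movement)
    utils::write.csv(truth, paths$truth, row.names = FALSE)
    jsonlite::write_json(list(seed = seed, config = config,
                              package_version = as.character(utils::packageVersion("codavowel")),
                              files = lapply(paths, basename)),
                         paths$manifest, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- paths
  }
  out
}

#' Synthesize dialogue timing with known pairing
#'
#' Emits onset times for a focal and a non-focal whale where each event is,
#' with stated probabilities, focal-only, non-focal-only, or an overlapping
#' pair (onsets closer than 1 s). Rows are spaced widely enough that the truth
#' pairing is unambiguous; used to validate [transcribe_dialogue()].
#'
#' @param n_events number of dialogue rows to generate.
#' @param p_pair probability an event is an overlapping pair.
#' @param p_focal probability a non-pair event belongs to the focal whale.
#' @param seed RNG seed.
#' @return list with data.frames `focal`, `nonfocal` (coda_id, onset_s,
#'   coda_type, vowel) and `truth_pairs` (focal_id, nonfocal_id; NA for
#'   unpaired rows).
#' @export
synthesize_dialogue_times <- function(n_events = 30, p_pair = 0.4,
                                      p_focal = 0.5, seed = 1L) {
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  focal <- list(); nonfocal <- list(); pairs <- list()
  t <- 0; fi <- 0; ni <- 0
  for (k in seq_len(n_events)) {
    t <- t + stats::runif(1, 2.5, 6)     # > 2 x overlap window between events
    kind <- if (stats::runif(1) < p_pair) "pair"
            else if (stats::runif(1) < p_focal) "focal" else "nonfocal"
    vw <- function() sample(c("a", "i"), 1)
    if (kind %in% c("pair", "focal")) {
      fi <- fi + 1
      focal[[length(focal) + 1]] <- data.frame(
        coda_id = sprintf("F%03d", fi), onset_s = t, coda_type = "1+1+3",
        vowel = vw(), stringsAsFactors = FALSE)
    }
    if (kind %in% c("pair", "nonfocal")) {
      ni <- ni + 1
      off <- if (kind == "pair") stats::runif(1, 0.05, 0.9) else 0
      nonfocal[[length(nonfocal) + 1]] <- data.frame(
        coda_id = sprintf("N%03d", ni), onset_s = t + off,
        coda_type = "1+1+3", vowel = vw(), stringsAsFactors = FALSE)
    }
    pairs[[k]] <- data.frame(
      focal_id = if (kind %in% c("pair", "focal")) sprintf("F%03d", fi) else NA_character_,
      nonfocal_id = if (kind %in% c("pair", "nonfocal")) sprintf("N%03d", ni) else NA_character_,
      stringsAsFactors = FALSE)
  }
  list(focal = do.call(rbind, focal), nonfocal = do.call(rbind, nonfocal),
       truth_pairs = do.call(rbind, pairs))
}
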