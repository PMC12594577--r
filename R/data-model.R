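# Domain types for annotated click trains. A coda is an ordered set of clicks
# from one whale with a traditional timing-based type label ("1+1+3", "5R1",
# "9i", ...) and, optionally, a hand-assigned vowel label (a/i).

#' Construct a coda from per-click annotations
#'
#' @param coda_id identifier.
#' @param whale_id whale identifier.
#' @param click_time_s strictly increasing click times (seconds from recording
#'   start). These are annotated onsets; the exact peak may be later.
#' @param peak_time_s optional per-click peak times (seconds); `NA` entries are
#'   derived from the waveform when needed (see [locate_click_peak()]).
#' @param coda_type traditional label, e.g. "1+1+3", "5R2", "9i"; may be `NA`.
#' @param hand_vowel one of "a", "i", "unknown", or `NA` (absent).
#' @param focal logical; whether the coda is from the tagged whale.
#' @return An object of class `coda` with derived `icis_s`
#'   (inter-click intervals, length `n_clicks - 1`).
#' @export
coda <- function(coda_id, whale_id, click_time_s, peak_time_s = NULL,
                 coda_type = NA_character_, hand_vowel = NA_character_,
                 focal = TRUE) {
  click_time_s <- as.numeric(click_time_s)
  n <- length(click_time_s)
  if (n < 1) stop("coda must contain at least one click")
  if (n > 1 && any(diff(click_time_s) <= 0))
    stop("click times must be strictly increasing within coda ", coda_id)
  if (is.null(peak_time_s)) peak_time_s <- rep(NA_real_, n)
  peak_time_s <- as.numeric(peak_time_s)
  if (length(peak_time_s) != n) stop("peak_time_s length mismatch")
  bad <- which(!is.na(peak_time_s) & peak_time_s < click_time_s)
  if (length(bad))
    stop("peak_time_s before click_time_s at click(s) ",
         paste(bad, collapse = ","), " of coda ", coda_id)
  if (!is.na(coda_type) && !grepl(coda_type_grammar(), coda_type))
    warning("coda_type '", coda_type, "' does not match the traditional grammar")
  if (!is.na(hand_vowel) && !hand_vowel %in% c("a", "i", "unknown"))
    stop("hand_vowel must be one of a/i/unknown or NA")
  structure(list(
    coda_id = as.character(coda_id),
    whale_id = as.character(whale_id),
    click_time_s = click_time_s,
    peak_time_s = peak_time_s,
    click_index = seq_len(n) - 1L,
    coda_type = coda_type,
    hand_vowel = hand_vowel,
    focal = isTRUE(focal),
    icis_s = if (n > 1) diff(click_time_s) else numeric(0)
  ), class = "coda")
}

# Traditional coda-type grammar: digits + optional letter {R,D,i} + optional
# duration digit (e.g. 5R1, 9i), or '+'-joined digits (e.g. 1+1+3). Whitespace
# around '+' tolerated.
coda_type_grammar <- function() {
  "^([0-9]+[RDi]?[0-9]?|[0-9]+(\\s*\\+\\s*[0-9]+)+)$"
}

#' @export
print.coda <- function(x, ...) {
  cat(sprintf("<coda %s> whale=%s clicks=%d type=%s vowel=%s\n",
              x$coda_id, x$whale_id, length(x$click_time_s),
              x$coda_type, x$hand_vowel))
  invisible(x)
}

n_clicks <- function(cd) length(cd$click_time_s)

#' Read a click-annotation CSV into a list of codas
#'
#' The table must have a header with at least `coda_id`, `whale_id`,
#' `click_time_s`; optional columns are `peak_time_s`, `coda_type`,
#' `hand_vowel`, `focal`. Rows are grouped by `coda_id`, clicks sorted by
#' time, and inter-click intervals derived.
#'
#' @param path CSV path.
#' @return List of [coda()] objects, ordered by first click time.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("coda_id", "whale_id", "click_time_s")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("annotation file is empty: ", path)
  split_rows <- split(df, df$coda_id)
  codas <- lapply(split_rows, function(g) {
    g <- g[order(g$click_time_s), , drop = FALSE]
    if (anyDuplicated(g$click_time_s))
      stop("duplicate click times in coda ", g$coda_id[1])
    coda(
      coda_id = g$coda_id[1],
      whale_id = g$whale_id[1],
      click_time_s = g$click_time_s,
      peak_time_s = if ("peak_time_s" %in% names(g)) g$peak_time_s else NULL,
      coda_type = if ("coda_type" %in% names(g)) as.character(g$coda_type[1]) else NA_character_,
      hand_vowel = if ("hand_vowel" %in% names(g)) as.character(g$hand_vowel[1]) else NA_character_,
      focal = if ("focal" %in% names(g)) isTRUE(as.logical(g$focal[1])) else TRUE
    )
  })
  codas[order(vapply(codas, function(cd) cd$click_time_s[1], 0))]
}

#' Write codas to an annotation CSV
#'
#' Inverse of [read_annotations()]; the round-trip is lossless for all fields.
#'
#' @param codas list of [coda()] objects.
#' @param path output CSV path.
#' @export
write_annotations <- function(codas, path) {
  rows <- lapply(codas, function(cd) {
    data.frame(coda_id = cd$coda_id, whale_id = cd$whale_id,
               click_index = cd$click_index,
               click_time_s = cd$click_time_s, peak_time_s = cd$peak_time_s,
               coda_type = cd$coda_type, hand_vowel = cd$hand_vowel,
               focal = cd$focal, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Convert codas to a per-coda data frame
#' @param codas list of codas.
#' @return data.frame with one row per coda.
#' @export
codas_summary <- function(codas) {
  data.frame(
    coda_id = vapply(codas, `[[`, "", "coda_id"),
    whale_id = vapply(codas, `[[`, "", "whale_id"),
    n_clicks = vapply(codas, n_clicks, 0L),
    onset_s = vapply(codas, function(cd) cd$click_time_s[1], 0),
    coda_type = vapply(codas, `[[`, "", "coda_type"),
    hand_vowel = vapply(codas, `[[`, "", "hand_vowel"),
    focal = vapply(codas, `[[`, TRUE, "focal"),
    stringsAsFactors = FALSE
  )
}

#' Read a movement table (time, depth, head, pitch, roll)
#'
#' @param path CSV with columns `time_s`, `depth_m`, `head_deg`, `pitch_deg`,
#'   `roll_deg`.
#' @return A `movement_series` object; use [movement_at()] to interpolate.
#' @export
read_movement <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_s", "depth_m", "head_deg", "pitch_deg", "roll_deg")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("movement file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) stop("movement file is empty: ", path)
  movement_series(df$time_s, df$depth_m, df$head_deg, df$pitch_deg, df$roll_deg)
}

#' Construct a movement series
#'
#' @param time_s strictly increasing times (s).
#' @param depth_m,head_deg,pitch_deg,roll_deg channel vectors, same length.
#' @return `movement_series` object.
#' @export
movement_series <- function(time_s, depth_m, head_deg, pitch_deg, roll_deg) {
  n <- length(time_s)
  stopifnot(length(depth_m) == n, length(head_deg) == n,
            length(pitch_deg) == n, length(roll_deg) == n)
  if (n > 1 && any(diff(time_s) <= 0)) stop("movement time must be strictly increasing")
  if (any(depth_m < 0)) stop("depth_m must be >= 0")
  structure(list(time_s = as.numeric(time_s), depth_m = as.numeric(depth_m),
                 head_deg = as.numeric(head_deg), pitch_deg = as.numeric(pitch_deg),
                 roll_deg = as.numeric(roll_deg)),
            class = "movement_series")
}

#' Interpolate movement channels at arbitrary times
#'
#' Linear interpolation; queries outside the recorded span are clamped to the
#' first/last value.
#'
#' @param mv a `movement_series`.
#' @param time_s query times.
#' @param channel one of "depth", "head", "pitch", "roll", or "all".
#' @return numeric vector, or a data.frame when `channel = "all"`.
#' @export
movement_at <- function(mv, time_s, channel = "all") {
  one <- function(y) stats::approx(mv$time_s, y, xout = time_s, rule = 2)$y
  if (length(mv$time_s) == 1) one <- function(y) rep(y, length(time_s))
  switch(channel,
    depth = one(mv$depth_m),
    head = one(mv$head_deg),
    pitch = one(mv$pitch_deg),
    roll = one(mv$roll_deg),
    all = data.frame(time_s = time_s, depth_m = one(mv$depth_m),
                     head_deg = one(mv$head_deg), pitch_deg = one(mv$pitch_deg),
                     roll_deg = one(mv$roll_deg)),
    stop("unknown channel: ", channel))
}

#' Write a movement series to CSV
#' @param mv `movement_series`.
#' @param path output path.
#' @export
write_movement <- function(mv, path) {
  utils::write.csv(data.frame(time_s = mv$time_s, depth_m = mv$depth_m,
                              head_deg = mv$head_deg, pitch_deg = mv$pitch_deg,
                              roll_deg = mv$roll_deg),
                   path, row.names = FALSE)
  invisible(path)
}

#' Locate the click peak in a recording
#'
#' Annotated click times are not guaranteed to coincide with the highest click
#' peak, so when a peak time is absent it is derived as the time of the
#' maximum of |amplitude| within a search window after the annotated time.
#'
#' @param recording a [new_recording()] object.
#' @param click_time_s annotated click time (s).
#' @param search_ms search window length after the annotated time (default 15).
#' @return peak time in seconds.
#' @export
locate_click_peak <- function(recording, click_time_s, search_ms = 15) {
  fs <- recording$sample_rate_hz
  i0 <- max(1L, 1L + floor(click_time_s * fs))
  i1 <- min(length(recording$samples), i0 + round(search_ms / 1000 * fs))
  if (i0 > length(recording$samples)) stop("click time outside recording")
  seg <- recording$samples[i0:i1]
  (i0 - 1L + which.max(abs(seg)) - 1L) / fs
}

# Resolve per-click peak times for a coda against a recording: keep annotated
# peaks where present, derive the rest.
resolve_peaks <- function(recording, cd, search_ms = 15) {
  pk <- cd$peak_time_s
  for (j in seq_along(pk)) {
    if (is.na(pk[j])) pk[j] <- locate_click_peak(recording, cd$click_time_s[j], search_ms)
  }
  pk
}
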