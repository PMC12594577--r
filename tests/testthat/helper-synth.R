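# Shared fixtures, built in code and cached per test file process.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# Small labeled dataset: 3 whales x 6 codas at 48 kHz, 25 dB SNR, level codas.
small_dataset <- function() fixture("small48", function() {
  synthesize_dataset(
    synthetic_config(n_codas_per_whale = c(ATW = 6, FRK = 6, PIN = 6),
                     trajectory_mix = c(level = 1),
                     sample_rate_hz = 48000, snr_db = 25),
    seed = 42)
})

# One noiseless a-coda and i-coda at 96 kHz for deterministic DSP checks.
clean_coda <- function(label) fixture(paste0("clean_", label), function() {
  syn <- synthesize_coda(coda_template("5R1"), vowel_spec(label),
                         sample_rate_hz = 96000, snr_db = Inf,
                         coda_id = paste0("clean_", label))
  syn$recording <- new_recording(syn$samples, syn$sample_rate_hz)
  syn
})

# Independent FFT-argmax oracle: strongest spectral bin of a segment in-band.
fft_argmax_oracle <- function(x, fs, band = c(1000, 10000)) {
  n <- length(x)
  X <- Mod(stats::fft(x)[1:(n %/% 2 + 1)])^2
  f <- (0:(n %/% 2)) * fs / n
  keep <- f >= band[1] & f <= band[2]
  f[keep][which.max(X[keep])]
}

# Independent brute-force constrained peak filter (oracle for
# find_constrained_peaks): enumerate local maxima by scanning, filter by
# height, then O(n^2) greedy-by-height distance pruning.
brute_force_peaks <- function(freqs, psd, band = c(1000, 10000),
                              min_sep = 1500, rel_height = 0.25,
                              max_peaks = 2) {
  sel <- freqs >= band[1] & freqs <= band[2]
  f <- freqs[sel]; p <- psd[sel]
  maxima <- integer(0)
  for (i in seq_along(p)) {
    if (i == 1 || i == length(p)) next
    left <- p[i - 1]
    j <- i
    while (j < length(p) && p[j + 1] == p[i]) j <- j + 1
    if (j == length(p)) next
    if (p[i] > left && p[j + 1] < p[i]) maxima <- c(maxima, i)
  }
  maxima <- maxima[p[maxima] >= rel_height * max(p)]
  kept <- integer(0)
  while (length(maxima)) {
    best <- maxima[which.max(p[maxima])]
    ok <- TRUE
    for (k in kept) if (abs(f[best] - f[k]) < min_sep) ok <- FALSE
    if (ok) kept <- c(kept, best)
    maxima <- setdiff(maxima, best)
  }
  kept <- kept[seq_len(min(length(kept), max_peaks))]
  sort(f[kept])
}
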