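# Core signal-processing primitives. Everything here is deliberately plain
# base R: short windows, real FFTs, autocorrelation LPC.

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

# Gaussian-like window (as used for spectrogram analysis frames); alpha
# controls edge attenuation.
gaussian_window <- function(n, alpha = 2.5) {
  k <- seq(-(n - 1) / 2, (n - 1) / 2, length.out = n)
  exp(-0.5 * (alpha * k / ((n - 1) / 2))^2)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram. The default uses a single Hann-windowed
#' segment spanning the whole input — appropriate for the very short (3.5 ms)
#' click windows this pipeline analyses, where splitting would destroy
#' frequency resolution. Density scaling matches the usual convention
#' (power per Hz; one-sided).
#'
#' @param x numeric signal.
#' @param fs sample rate (Hz).
#' @param nperseg segment length (default: full signal, no averaging).
#' @param overlap fractional overlap between segments (default 0.5 when
#'   segmenting).
#' @param window "hann" or "rect".
#' @param nfft FFT length; values above `nperseg` zero-pad for a finer
#'   frequency grid (default `nperseg`).
#' @return list with `freqs_hz` and `psd` (one-sided).
#' @export
welch_psd <- function(x, fs, nperseg = length(x), overlap = 0.5,
                      window = "hann", nfft = nperseg) {
  n <- length(x)
  if (n == 0) stop("empty signal")
  nperseg <- min(nperseg, n)
  if (nfft < nperseg) stop("nfft must be >= nperseg")
  w <- switch(window, hann = hann_window(nperseg), rect = rep(1, nperseg),
              stop("unknown window: ", window))
  step <- max(1L, round(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  u <- sum(w^2)                      # window power normalisation
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w     # detrend (constant) as is conventional
    X <- stats::fft(c(seg, numeric(nfft - nperseg)))
    p <- Mod(X[1:(nfft %/% 2 + 1)])^2 / (fs * u)
    # one-sided: double all bins except DC (and Nyquist for even nfft)
    dbl <- rep(2, length(p)); dbl[1] <- 1
    if (nfft %% 2 == 0) dbl[length(p)] <- 1
    acc <- acc + p * dbl
  }
  list(freqs_hz = (0:(nfft %/% 2)) * fs / nfft, psd = acc / length(starts))
}

# Short-time Fourier transform magnitude grid. Returns frequencies x times.
stft_mag <- function(x, fs, window_n, hop_n, window = gaussian_window(window_n)) {
  n <- length(x)
  if (n == 0) stop("empty signal")
  if (window_n > n) stop("window longer than signal")
  starts <- seq(1L, n - window_n + 1L, by = hop_n)
  nfreq <- window_n %/% 2 + 1
  mag <- matrix(0, nrow = nfreq, ncol = length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + window_n - 1L)] * window
    mag[, k] <- Mod(stats::fft(seg)[1:nfreq])
  }
  list(freqs_hz = (0:(nfreq - 1)) * fs / window_n,
       times_s = (starts - 1 + window_n / 2) / fs,
       mag = mag)
}

# Fourier-domain resampling (as scipy.signal.resample): truncate or zero-pad
# the spectrum. Used to decimate frames to 2x the formant ceiling before LPC.
resample_fft <- function(x, n_out) {
  n_in <- length(x)
  if (n_out == n_in) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  nh <- min(n_in, n_out)
  keep <- nh %/% 2 + 1
  Y[1:keep] <- X[1:keep]
  if (keep > 1) Y[(n_out - keep + 2):n_out] <- X[(n_in - keep + 2):n_in]
  if (nh %% 2 == 0) {  # split Nyquist bin
    Y[keep] <- Y[keep] / 2
    Y[n_out - keep + 2] <- Conj(Y[keep])
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

# Autocorrelation-method LPC via Levinson-Durbin. Returns predictor
# coefficients a (x[n] ~ sum a_k x[n-k]) or NULL on degenerate input.
lpc_coefficients <- function(x, order) {
  n <- length(x)
  if (n <= order) return(NULL)
  r <- numeric(order + 1)
  for (k in 0:order) r[k + 1] <- sum(x[1:(n - k)] * x[(1 + k):n])
  if (r[1] <= 0) return(NULL)
  a <- numeric(order)
  err <- r[1]
  for (i in 1:order) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a[1:(i - 1)] * r[i:2])
    k <- acc / err
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[1:(i - 1)] <- a[1:(i - 1)] - k * a[(i - 1):1]
    a <- a_new
    err <- err * (1 - k^2)
    if (err <= 0) return(NULL)
  }
  a
}

# Roots of the LPC prediction polynomial -> (frequency, bandwidth) pairs at
# sample rate fs. Only upper-half-plane roots are meaningful.
lpc_root_formants <- function(a, fs) {
  p <- length(a)
  # polynomial z^p - a1 z^(p-1) - ... - ap; polyroot wants increasing powers
  roots <- polyroot(c(-rev(a), 1))
  roots <- roots[Im(roots) > 0]
  if (!length(roots)) return(data.frame(freq_hz = numeric(0), bw_hz = numeric(0)))
  freq <- Arg(roots) * fs / (2 * pi)
  bw <- -log(pmin(Mod(roots), 1 - 1e-12)) * fs / pi
  ord <- order(freq)
  data.frame(freq_hz = freq[ord], bw_hz = bw[ord])
}

# First-order pre-emphasis from a given cutoff frequency.
pre_emphasize <- function(x, fs, from_hz = 50) {
  if (length(x) < 2) return(x)
  alpha <- exp(-2 * pi * from_hz / fs)
  c(x[1], x[-1] - alpha * x[-length(x)])
}

db <- function(p, floor_db = -120) {
  out <- 10 * log10(pmax(p, 10^(floor_db / 10)))
  out
}
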