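test_that("the Welch click window is exactly 3.5 ms around the peak", {
  syn <- clean_coda("a")
  sp <- welch_click_spectrum(syn$recording, syn$coda, 0)
  expect_equal(sp$segment_n, round(0.0035 * 96000))
  expect_equal(sp$resolution_hz, 96000 / sp$segment_n)
  # PSD argmax within one bin + bw/2 of the single resonance
  expect_lt(abs(sp$freqs_hz[which.max(sp$psd)] - 5780),
            sp$resolution_hz + 200)
  lowrate <- new_recording(numeric(1000), 16000)
  expect_error(welch_click_spectrum(lowrate, syn$coda, 0), "too low")
})

test_that("white-noise segments give an approximately flat PSD", {
  set.seed(21)
  ps <- codavowel:::welch_psd(rnorm(8192), 48000, nperseg = 512)
  # spectral flatness (geometric/arithmetic mean) near 1 for white noise
  flat <- exp(mean(log(ps$psd[-1]))) / mean(ps$psd[-1])
  expect_gt(flat, 0.8)
})

test_that("constrained peak detection enforces all three constraints", {
  f <- seq(0, 12000, by = 50)
  bump <- function(c0, h, w = 300) h * exp(-0.5 * ((f - c0) / w)^2)
  # separation < 1,500 Hz: only the higher of the two survives
  p <- bump(2000, 1) + bump(2800, 0.8) + 1e-6
  pks <- find_constrained_peaks(f, p)
  expect_equal(nrow(pks), 1)
  expect_equal(pks$freq_hz, 2000)
  # the i-vowel geometry passes both peaks, in ascending frequency order
  p2 <- bump(6579, 1) + bump(3757, 0.5) + 1e-6
  pks2 <- find_constrained_peaks(f, p2)
  expect_equal(nrow(pks2), 2)
  expect_lt(abs(pks2$freq_hz[1] - 3757), 50)
  expect_lt(abs(pks2$freq_hz[2] - 6579), 50)
  expect_true(all(diff(pks2$freq_hz) >= 1500))
  # below 25% of the band maximum: rejected
  p3 <- bump(6579, 1) + bump(3757, 0.2) + 1e-6
  expect_equal(nrow(find_constrained_peaks(f, p3)), 1)
  # monotone PSD: zero peaks
  expect_equal(nrow(find_constrained_peaks(f, seq_along(f) * 1.0)), 0)
  # at most two peaks selected, the two highest
  p4 <- bump(2000, 0.6) + bump(5000, 1) + bump(8000, 0.9) + 1e-6
  pks4 <- find_constrained_peaks(f, p4)
  expect_equal(pks4$freq_hz, c(5000, 8000))
  expect_error(find_constrained_peaks(f[f < 500], p[f < 500]), "band")
})

test_that("find_constrained_peaks matches the brute-force oracle on 1,000 PSDs", {
  set.seed(77)
  f <- seq(0, 12000, length.out = 241)
  for (i in 1:1000) {
    n_bumps <- sample(0:4, 1)
    p <- rep(1e-8, length(f)) + abs(rnorm(length(f), sd = 1e-3))
    for (b in seq_len(n_bumps)) {
      p <- p + runif(1, 0.1, 1) *
        exp(-0.5 * ((f - runif(1, 500, 11500)) / runif(1, 150, 600))^2)
    }
    got <- find_constrained_peaks(f, p)$freq_hz
    want <- brute_force_peaks(f, p)
    expect_equal(got, want, label = paste("psd", i))
  }
})

test_that("click classification implements the two-peak rule", {
  two <- data.frame(freq_hz = c(3757, 6579), height = c(1, 1))
  one <- data.frame(freq_hz = 5780, height = 1)
  none <- data.frame(freq_hz = numeric(0), height = numeric(0))
  expect_equal(classify_click(two), "i")
  expect_equal(as.character(classify_click(one)), "a")
  lab <- classify_click(none)
  expect_equal(as.character(lab), "a")
  expect_true(isTRUE(attr(lab, "low_confidence")))
})

test_that("coda majority and mismatch counting follow the majority rule", {
  expect_equal(classify_coda_majority(rep("a", 5))$n_mismatched, 0)
  m <- classify_coda_majority(c("a", "a", "i", "a", "a"))
  expect_equal(m$majority_label, "a")
  expect_equal(m$n_mismatched, 1)
  expect_equal(m$pct_mismatched, 20)
  tie <- classify_coda_majority(c("a", "a", "i", "i"))
  expect_equal(tie$majority_label, "tie")
  expect_equal(tie$n_mismatched, 2)
  expect_error(classify_coda_majority(character(0)), "empty")
})

test_that("mismatch histogram percentages sum to 100", {
  cls <- list(classify_coda_majority(rep("a", 5)),
              classify_coda_majority(c("a", "a", "i", "a", "a")),
              classify_coda_majority(c("i", "i", "i")),
              classify_coda_majority(c("a", "i", "i", "a", "i")))
  ms <- mismatch_summary(cls)
  expect_equal(sum(ms$by_count$pct), 100)
  expect_equal(sum(ms$by_pct$n_codas), 4)
  expect_equal(ms$by_count$n_codas[ms$by_count$n_mismatched == 0], 2)
})

test_that("zero-mismatch fraction matches the Monte-Carlo flip oracle", {
  # per-click label-flip probability 0.05 on 5-click codas: the chance a coda
  # has zero mismatches is p0 = (1-q)^5 + q^5 (all flipped = unanimous too)
  q <- 0.05; n_codas <- 2000
  set.seed(101)
  flips <- matrix(runif(n_codas * 5) < q, ncol = 5)
  labs <- ifelse(flips, "i", "a")
  cls <- apply(labs, 1, classify_coda_majority, simplify = FALSE)
  frac0 <- mean(vapply(cls, `[[`, 0, "n_mismatched") == 0)
  p0 <- (1 - q)^5 + q^5
  ci <- qnorm(c(0.005, 0.995), p0, sqrt(p0 * (1 - p0) / n_codas))
  expect_gt(frac0, ci[1]); expect_lt(frac0, ci[2])
})

test_that("peak detection is deterministic", {
  ds <- small_dataset()
  rec <- ds$recording
  cs1 <- analyze_click_spectra(rec, ds$codas[1:3])
  cs2 <- analyze_click_spectra(rec, ds$codas[1:3])
  expect_identical(cs1$clicks, cs2$clicks)
})
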