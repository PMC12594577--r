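test_that("synthesize_click places spectral maxima at the requested centres", {
  fs <- 96000
  # one resonator at the a-vowel mean
  x <- synthesize_click(data.frame(center_hz = 5780, bw_hz = 400), 0.01, fs)
  expect_lt(abs(fft_argmax_oracle(x, fs) - 5780), 200)
  # two resonators at the i-vowel means: two PSD maxima >= 1,500 Hz apart
  y <- synthesize_click(data.frame(center_hz = c(3757, 6579),
                                   bw_hz = c(400, 400)), 0.01, fs)
  ps <- codavowel:::welch_psd(y, fs)
  pks <- find_constrained_peaks(ps$freqs_hz, ps$psd)
  expect_equal(nrow(pks), 2)
  expect_gte(diff(pks$freq_hz), 1500)
  expect_lt(abs(pks$freq_hz[1] - 3757), 200)
  expect_lt(abs(pks$freq_hz[2] - 6579), 200)
  # zero gain -> all-zero output; bad inputs rejected
  z <- synthesize_click(data.frame(center_hz = 5780, bw_hz = 400, gain = 0),
                        0.01, fs)
  expect_true(all(z == 0))
  expect_error(synthesize_click(data.frame(center_hz = 60000, bw_hz = 400),
                                0.01, fs), "Nyquist")
})

test_that("trajectory law is linear with the turn at the middle click", {
  level <- vowel_spec("a", trajectory = "level")
  expect_true(all(codavowel:::trajectory_centers(level, 5) == 5780))
  rising <- vowel_spec("a", trajectory = "rising", trajectory_span_hz = 1400)
  ctr <- codavowel:::trajectory_centers(rising, 5)[, 1]
  expect_equal(diff(ctr), rep(350, 4))          # 1,400 Hz span over 5 clicks
  falling <- vowel_spec("a", trajectory = "falling", trajectory_span_hz = 1400)
  expect_equal(diff(codavowel:::trajectory_centers(falling, 5)[, 1]),
               rep(-350, 4))
  rf <- vowel_spec("a", trajectory = "rise_fall", trajectory_span_hz = 800)
  seq_rf <- codavowel:::trajectory_centers(rf, 5)[, 1]
  expect_equal(which.max(seq_rf), 3)            # turn at the middle click
  expect_equal(seq_rf[1], seq_rf[5])
  # elevated first click
  hi1 <- vowel_spec("a", trajectory = "level", first_click_offset_hz = 1500)
  ctr2 <- codavowel:::trajectory_centers(hi1, 5)[, 1]
  expect_equal(ctr2[1] - ctr2[2], 1500)
})

test_that("vowel_spec enforces the a/i geometry", {
  expect_error(vowel_spec("a", formant_centers_hz = c(3757, 6579)), "exactly 1")
  expect_error(vowel_spec("i", formant_centers_hz = c(5000, 6000)), "1,500 Hz")
  expect_error(vowel_spec("i", formant_centers_hz = c(500, 6000)), "1,000")
})

test_that("the 1+1+3 template gives long-long-short-short ICIs", {
  tmpl <- coda_template("1+1+3")
  expect_equal(tmpl$n_clicks, 5L)
  icis <- tmpl$icis_s
  expect_true(icis[1] > icis[3] && icis[2] > icis[4])
  expect_equal(icis[1], icis[2])
  expect_equal(tmpl$ipi_s, 0.0031)
  expect_error(coda_template("5R1", ipi_s = 0.5), "shorter than")
})

test_that("annotated times index local maxima and truth is FFT-recoverable", {
  syn <- synthesize_coda(coda_template("1+1+3"), vowel_spec("a"),
                         sample_rate_hz = 48000, snr_db = 25, seed = 9)
  fs <- 48000
  half_ms <- round(0.5e-3 * fs)
  for (j in seq_along(syn$coda$peak_time_s)) {
    i_pk <- round(syn$coda$peak_time_s[j] * fs) + 1L
    win <- abs(syn$samples[(i_pk - half_ms):(i_pk + half_ms)])
    expect_equal(which.max(win), half_ms + 1L)  # peak is the local max
    # FFT-argmax oracle on the 3.5 ms first-pulse window recovers the truth
    seg <- syn$samples[(i_pk - round(0.002 * fs)):(i_pk + round(0.0015 * fs))]
    got <- fft_argmax_oracle(seg, fs)
    bin <- fs / length(seg)
    expect_lt(abs(got - syn$truth$f1_true_hz[j]), 400 / 2 + bin)
  }
})

test_that("dataset generation is a pure function of (config, seed)", {
  cfg <- synthetic_config(n_codas_per_whale = c(A = 2, B = 2),
                          sample_rate_hz = 24000)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  synthesize_dataset(cfg, seed = 7, outdir = d1)
  synthesize_dataset(cfg, seed = 7, outdir = d2)
  for (f in c("annotations.csv", "movement.csv", "truth.csv", "session.wav"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), label = f)
  expect_error(synthesize_dataset(synthetic_config(n_codas_per_whale = c(A = 0)),
                                  1), "zero codas")
})

test_that("generator files round-trip into equal codas and truth rows", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  synthesize_dataset(ds$config, seed = 42, outdir = dir)
  back <- read_annotations(file.path(dir, "annotations.csv"))
  expect_length(back, length(ds$codas))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$coda_id, ds$codas[[i]]$coda_id)
    expect_equal(back[[i]]$click_time_s, ds$codas[[i]]$click_time_s)
    expect_equal(back[[i]]$peak_time_s, ds$codas[[i]]$peak_time_s)
    expect_equal(back[[i]]$hand_vowel, ds$codas[[i]]$hand_vowel)
  }
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  expect_equal(nrow(truth), sum(vapply(ds$codas, function(cd)
    length(cd$click_time_s), 0L)))
})

test_that("vowel mixture proportions match the binomial oracle at n=500", {
  cfg <- synthetic_config(n_codas_per_whale = c(W = 500),
                          vowel_mix = c(a = 0.6, i = 0.4))
  set.seed(3)
  # draw labels exactly as the generator does, without synthesizing audio
  labs <- sample(names(cfg$vowel_mix), 500, TRUE, cfg$vowel_mix)
  p_hat <- mean(labs == "a")
  ci <- qnorm(c(0.005, 0.995), 0.6, sqrt(0.6 * 0.4 / 500))
  expect_gt(p_hat, ci[1]); expect_lt(p_hat, ci[2])
  # and the full generator, at a size that stays cheap
  ds <- synthesize_dataset(synthetic_config(n_codas_per_whale = c(W = 60),
                                            sample_rate_hz = 24000,
                                            vowel_mix = c(a = 0.6, i = 0.4)),
                           seed = 3)
  p60 <- mean(vapply(ds$codas, `[[`, "", "hand_vowel") == "a")
  ci60 <- qnorm(c(0.005, 0.995), 0.6, sqrt(0.6 * 0.4 / 60))
  expect_gt(p60, ci60[1]); expect_lt(p60, ci60[2])
})
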