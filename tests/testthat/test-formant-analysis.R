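test_that("LPC candidates recover one and two resonances", {
  fs <- 96000
  one <- synthesize_click(data.frame(center_hz = 5780, bw_hz = 400), 0.02, fs)
  fr <- lpc_candidate_frames(one, fs, ceiling_hz = 11000)
  # the resonance decays within ~2 ms, so only the onset frames carry it
  for (fm in fr[1:2]) {
    fm <- fm[fm$freq_hz > 1000, , drop = FALSE]
    expect_gte(nrow(fm), 1)
    expect_lt(abs(fm$freq_hz[1] - 5780), 150)
  }
  two <- synthesize_click(data.frame(center_hz = c(3757, 6579),
                                     bw_hz = c(400, 400)), 0.02, fs)
  fr2 <- lpc_candidate_frames(two, fs, ceiling_hz = 11000)
  fm <- fr2[[1]][fr2[[1]]$freq_hz > 1000, , drop = FALSE]
  expect_gte(nrow(fm), 2)
  expect_lt(abs(fm$freq_hz[1] - 3757), 150)   # ascending order preserved
  expect_lt(abs(fm$freq_hz[2] - 6579), 150)
  # accepted candidates always satisfy the constraints
  set.seed(4)
  frn <- lpc_candidate_frames(rnorm(2000), fs, ceiling_hz = 11000)
  for (fm in frn) {
    expect_true(all(fm$freq_hz > 0 & fm$freq_hz < 11000))
    expect_true(all(fm$bw_hz < 800))
  }
  expect_error(lpc_candidate_frames(one, fs, ceiling_hz = 60000), "Nyquist")
})

test_that("formant_path tracks stationary and rising synthetic codas", {
  syn_i <- clean_coda("i")
  tic <- time_insensitive_coda(syn_i$recording, syn_i$coda, -2, 3.5)
  tr <- formant_path(tic$samples, 96000)
  expect_equal(tr$vowel_label, "i")
  expect_lt(abs(mean(tr$frames$f1_hz) - 3757), 150)
  expect_lt(abs(mean(tr$frames$f2_hz) - 6579), 150)
  expect_true(all(tr$frames$f1_hz < tr$frames$f2_hz))

  rising <- synthesize_coda(coda_template("5R1"),
                            vowel_spec("a", trajectory = "rising",
                                       trajectory_span_hz = 1400),
                            96000, snr_db = Inf, coda_id = "rise")
  rec <- new_recording(rising$samples, 96000)
  ttr <- formant_path(time_insensitive_coda(rec, rising$coda, -2, 3.5)$samples,
                      96000)
  # F1 across the assembled coda should rise with the click-truth trajectory
  n <- nrow(ttr$frames)
  rho <- suppressWarnings(cor(ttr$frames$frame_ms, ttr$frames$f1_hz,
                              method = "spearman"))
  expect_gt(rho, 0.9)
})

test_that("single-frame input reduces to the best single candidate", {
  x <- synthesize_click(data.frame(center_hz = 5780, bw_hz = 400), 0.005, 96000)
  tr <- formant_path(x, 96000)     # 5 ms signal, one 5 ms frame
  expect_equal(nrow(tr$frames), 1)
  expect_lt(abs(tr$frames$f1_hz - 5780), 150)
})

test_that("the DP path cost equals exhaustive enumeration", {
  syn <- synthesize_coda(coda_template("5R1"), vowel_spec("i"), 96000,
                         snr_db = 25, seed = 14)
  rec <- new_recording(syn$samples, 96000)
  # 10 ms signal -> 6 frames; 4 ceilings -> 4^6 assignments
  tic <- time_insensitive_coda(rec, syn$coda, -2, 3.5)
  x <- tic$samples[1:round(0.010 * 96000)]
  ceilings <- c(7000, 9000, 11000, 13000)
  tr <- formant_path(x, 96000, ceilings_hz = ceilings)
  per_ceiling <- lapply(ceilings, function(cl)
    lpc_candidate_frames(x, 96000, cl))
  n_t <- length(attr(per_ceiling[[1]], "frame_times_ms"))
  cand <- lapply(seq_len(n_t), function(t)
    lapply(per_ceiling, function(fr) codavowel:::select_f1_f2(fr[[t]])))
  local_cost <- function(fm) if (nrow(fm) == 0) 5 else mean(fm$bw_hz / fm$freq_hz)
  trans_cost <- function(a, b) {
    m <- min(nrow(a), nrow(b))
    cost <- 0.5 * abs(nrow(a) - nrow(b))
    if (m > 0) cost <- cost + sum(abs(log(b$freq_hz[1:m]) - log(a$freq_hz[1:m])))
    cost
  }
  grid <- expand.grid(rep(list(seq_along(ceilings)), n_t))
  costs <- apply(grid, 1, function(assign) {
    total <- local_cost(cand[[1]][[assign[1]]])
    for (t in seq_len(n_t)[-1]) {
      total <- total + local_cost(cand[[t]][[assign[t]]]) +
        trans_cost(cand[[t - 1]][[assign[t - 1]]], cand[[t]][[assign[t]]])
    }
    total
  })
  expect_equal(tr$path_cost, min(costs), tolerance = 1e-10)
})

test_that("the frame-presence rule classifies a/i/unclassified", {
  frames_i <- data.frame(frame_ms = 1:3, f1_hz = c(3700, 3750, 3800),
                         b1_hz = 300, f2_hz = c(6500, 6550, 6600), b2_hz = 300)
  frames_a <- transform(frames_i, f2_hz = NA_real_, b2_hz = NA_real_)
  frames_mix <- frames_i
  frames_mix$f2_hz[2] <- NA
  expect_equal(classify_coda_from_formants(frames_i), "i")
  expect_equal(classify_coda_from_formants(frames_a), "a")
  expect_equal(classify_coda_from_formants(frames_mix), "unclassified")
  # invariant to frame order
  expect_equal(classify_coda_from_formants(frames_mix[c(3, 1, 2), ]),
               "unclassified")
  expect_error(classify_coda_from_formants(frames_i[0, ]), "empty")
})

test_that("the hyperparameter grid scores agreement and reports best psets", {
  ds <- small_dataset()
  cfg <- analysis_config(grid_durations_ms = c(3.5, 15.0))  # 4 of the 14 cells
  grid_out <- run_hyperparameter_grid(ds$recording, ds$codas, cfg)
  expect_equal(nrow(grid_out$grid), 4)
  expect_setequal(unique(grid_out$results$whale_id), c("ATW", "FRK", "PIN"))
  # separable synthetic vowels: some pset reaches 100% agreement per whale
  best <- tapply(grid_out$results$pct_agree, grid_out$results$whale_id, max)
  expect_true(all(best == 100))

  rep_df <- best_pset_report(grid_out)
  expect_equal(nrow(rep_df), 3)
  expect_true(all(rep_df$psetsN >= 1))
  expect_true(all(rep_df$pct_agree >= 0 & rep_df$pct_agree <= 100))
  # psetsN equals the tie count in the raw results
  for (w in rep_df$whale_id) {
    rw <- grid_out$results[grid_out$results$whale_id == w, ]
    expect_equal(rep_df$psetsN[rep_df$whale_id == w],
                 sum(rw$pct_agree == max(rw$pct_agree)))
  }
  # formant means near the generator truth (coda centres are jittered around
  # the population means by the generator's between-coda spread)
  truth <- ds$truth
  for (w in rep_df$whale_id) {
    r <- rep_df[rep_df$whale_id == w, ]
    tw_a <- truth[truth$whale_id == w & truth$vowel == "a", ]
    if (r$n_a > 0)
      expect_lt(abs(r$a_f1_hz - mean(tw_a$f1_true_hz)), 250)
  }
  # shuffled-label permutation oracle: mean agreement ~ label overlap
  tracks <- grid_out$coda_tracks
  t1 <- tracks[tracks$pset_id == tracks$pset_id[1], ]
  set.seed(8)
  agree <- replicate(300, mean(sample(t1$hand_vowel) == t1$label))
  pred_p <- mean(t1$label == "a"); hand_p <- mean(t1$hand_vowel == "a")
  expected <- pred_p * hand_p + (1 - pred_p) * (1 - hand_p)
  expect_lt(abs(mean(agree) - expected), 0.05)
})
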