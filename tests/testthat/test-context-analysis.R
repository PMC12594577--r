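test_that("the exclusion filter reproduces the corpus arithmetic", {
  # 1,375 codas: 108 from an unknown whale plus three sparse whales with no
  # i-type (7 + 12 + 34) leave 1,214 analyzed codas
  counts <- c(unknown = 108, LADYO = 7, NALGENE = 12, SOURSOP = 34,
              ATWOOD = 400, FORK = 350, PINCHY = 250, TBB = 214)
  df <- data.frame(
    coda_id = sprintf("c%04d", seq_len(sum(counts))),
    whale_id = rep(names(counts), counts),
    hand_vowel = "a", stringsAsFactors = FALSE)
  # kept whales have at least one i-type
  df$hand_vowel[df$whale_id %in% c("ATWOOD", "FORK", "PINCHY", "TBB") &
                  !duplicated(df$whale_id)] <- "i"
  expect_equal(nrow(df), 1375)
  flt <- filter_codas(df, min_codas_per_whale = 35)
  expect_equal(nrow(flt$kept), 1214)
  expect_equal(nrow(flt$excluded), 161)
  expect_equal(flt$counts$unknown_whale, 108)
  expect_equal(flt$counts$sparse_whale_no_i, 53)
  # conservation: kept + excluded = input, one reason per exclusion
  expect_equal(nrow(flt$kept) + nrow(flt$excluded), nrow(df))
  expect_false(any(is.na(flt$reasons$reason)))

  # sparse whale WITH an i-type is retained; no rules -> identity
  df2 <- df
  df2$hand_vowel[df2$whale_id == "SOURSOP"][1] <- "i"
  expect_equal(nrow(filter_codas(df2, min_codas_per_whale = 35)$kept), 1248)
  expect_equal(nrow(filter_codas(df, unknown_ids = character(0),
                                 min_codas_per_whale = 0)$kept), 1375)
})

test_that("an affine peak/depth relation gives r = 1 and affine invariance", {
  t <- seq(0, 100, by = 1)
  depth <- 100 + 3 * t
  mv <- movement_series(t, depth, head_deg = rnorm(101),
                        pitch_deg = rnorm(101), roll_deg = rnorm(101))
  peaks <- 2 * depth + 500     # affine in depth
  cr <- movement_correlation(peaks, t, mv)
  expect_equal(cr$r[cr$channel == "depth"], 1, tolerance = 1e-12)
  # affine transforms of either series leave r unchanged
  cr2 <- movement_correlation(-3 * peaks + 7, t, mv)
  expect_equal(abs(cr2$r[cr2$channel == "depth"]), 1, tolerance = 1e-12)
  expect_equal(cr2$r[cr2$channel == "head"], -cr$r[cr$channel == "head"],
               tolerance = 1e-9)
  # constant movement channel: r undefined with a reason
  mvc <- movement_series(t, rep(5, 101), rep(1, 101), rep(1, 101), rep(1, 101))
  crc <- movement_correlation(peaks, t, mvc)
  expect_true(all(is.na(crc$r)))
  expect_match(crc$note[1], "constant")
  expect_error(movement_correlation(1:2, 1:2, mv), "at least 3")
})

test_that("whale exclusion before correlating is honoured", {
  t <- 0:99
  mv <- movement_series(t, 100 + t, rnorm(100), rnorm(100), rnorm(100))
  peaks <- c(rep(5000, 50), 100 + t[51:100] * 50)
  whales <- rep(c("SALLY", "GOOD"), each = 50)
  cr_all <- movement_correlation(peaks, t, mv)
  cr_ex <- movement_correlation(peaks, t, mv, exclude_whales = "SALLY",
                                whale_id = whales)
  expect_equal(cr_ex$n[1], 50)
  expect_gt(cr_ex$r[cr_ex$channel == "depth"],
            cr_all$r[cr_all$channel == "depth"])
})

test_that("tube resonance formula and its algebraic round-trip", {
  # f = n c / (2L): 171.5 m tube -> 1 Hz fundamental
  expect_equal(tube_resonance_frequency(171.5), 1)
  expect_equal(tube_resonance_frequency(1, n = 2), 343)
  # round-trip to machine precision for arbitrary lengths
  for (L in c(0.01, 0.022, 0.027, 0.5, 2, 171.5)) {
    expect_equal(tube_length_for_frequency(tube_resonance_frequency(L)), L,
                 tolerance = 1e-12)
  }
  # the published worked examples, at the one-decimal cm the source prints
  expect_equal(round(100 * tube_length_for_frequency(7827), 1), 2.2)
  expect_equal(round(100 * tube_length_for_frequency(6397), 1), 2.7)
  expect_equal(tube_length_for_frequency(343 / 2), 1)
  expect_error(tube_resonance_frequency(0), "positive")
  expect_error(tube_length_for_frequency(-5), "positive")
})

test_that("bout segmentation treats a 10 s gap as within-bout", {
  onsets <- c(0, 4, 14, 30)      # gaps: 4, 10, 16
  expect_equal(segment_bouts(onsets, gap_s = 10), c(1, 1, 1, 2))
  # unsorted input keeps input order
  expect_equal(segment_bouts(c(30, 0, 14, 4), 10), c(2, 1, 1, 1))
})

test_that("dialogue transcription pairs codas under 1 s and flags triples", {
  f <- data.frame(coda_id = "F1", onset_s = 0, coda_type = "1+1+3", vowel = "i")
  nf <- data.frame(coda_id = "N1", onset_s = 0.5, coda_type = "5R2", vowel = "a")
  one_row <- transcribe_dialogue(f, nf)
  expect_equal(nrow(one_row), 1)
  expect_true(one_row$overlap)
  expect_equal(one_row$nonfocal_vowel, "a")

  nf2 <- data.frame(coda_id = "N1", onset_s = 2, coda_type = "5R2", vowel = "a")
  two_rows <- transcribe_dialogue(f, nf2)
  expect_equal(nrow(two_rows), 2)
  expect_false(any(two_rows$overlap))

  # a triple within the window: nearest pair wins, the surplus coda is flagged
  f3 <- data.frame(coda_id = c("F1", "F2"), onset_s = c(0, 0.8))
  nf3 <- data.frame(coda_id = "N1", onset_s = 0.1)
  tr3 <- transcribe_dialogue(f3, nf3)
  expect_equal(nrow(tr3), 2)
  expect_equal(tr3$nonfocal_id[tr3$focal_id == "F1"], "N1")
  expect_true(tr3$flagged[tr3$focal_id == "F2"])
})

test_that("dialogue row pairing matches the generator truth exactly", {
  dlg <- synthesize_dialogue_times(n_events = 40, seed = 6)
  out <- transcribe_dialogue(dlg$focal, dlg$nonfocal)
  expect_equal(nrow(out), nrow(dlg$truth_pairs))
  got <- out[order(out$onset_s), c("focal_id", "nonfocal_id")]
  rownames(got) <- NULL
  expect_equal(got, dlg$truth_pairs)
})
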