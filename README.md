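# codavowel

Spectral analysis of sperm whale codas for researchers studying cetacean
communication. Sperm whales exchange short stereotyped click trains
("codas"), traditionally classified by click count and inter-click timing
(e.g. `1+1+3`, `5R1`). Beyond timing, codas carry **spectral** structure:
clicks can show either a single pronounced formant below 10 kHz (~5.8 kHz;
the *a*-coda vowel) or two formants (~3.8 and ~6.6 kHz; the *i*-coda vowel),
and some codas show rising/falling formant trajectories across clicks
("diphthongs"). This package implements the full acoustic pipeline to detect
and quantify those patterns, plus a source-filter simulator that generates
annotated recordings with known ground truth so every stage can be validated
without field data.

## What it computes

- **Time-insensitive codas** — per-click segments (default 15 ms, starting
  2 ms before the click peak) DC-centered, peak-normalized to [-1, 1], and
  concatenated so inter-click timing is removed; sessions are joined with
  25 ms silence buffers.
- **Click spectra and a/i labels** — Welch PSD of a 3.5 ms window around each
  click peak (2.0 ms pre / 1.5 ms post, covering the first pulse); peaks in
  the 1–10 kHz band with ≥ 1,500 Hz separation and height ≥ 25% of the band
  maximum; clicks with ≥ 2 peaks are *i*-type, otherwise *a*-type; coda
  majority labels and the mismatched-click histogram quantify discreteness.
- **Formant tracks** — autocorrelation LPC along a ladder of formant
  ceilings, with a dynamic program selecting per frame the analysis giving
  the smoothest track (minimal Σ|Δ log f| + bandwidth penalty); a coda is
  *i* if every frame has F1 and F2, *a* if no frame has F2. A hyperparameter
  grid (start offsets −2.0/−1.5 ms × durations 3.0–15.0 ms) is scored
  against hand labels per whale, and formant means are reported over the
  best-performing set(s).
- **Diphthong statistics** — per-coda signed peak displacements
  `c1dist` (mean distance of each non-initial click's peak from the first
  click's peak) and `cndist` (from the preceding click's peak), with 1-D
  Gaussian mixture models (k = 1…5) selected by BIC
  (−2 log L + (3k−1) ln n) to test bimodality.
- **Context controls** — Pearson correlation of spectral peaks against
  depth/head/pitch/roll interpolated to click times; corpus exclusion rules;
  bout segmentation (gaps > 10 s); dialogue transcription pairing focal and
  non-focal codas with onsets < 1 s apart; and the closed-tube resonance
  model `f_n = n·c / (2L)` (c = 343 m/s) linking formants to air-sac size.

## Worked example

```r
library(codavowel)

ds <- synthesize_dataset(synthetic_config(n_codas_per_whale = c(PINCHY = 8),
                                          sample_rate_hz = 48000),
                         seed = 2026)
cs <- analyze_click_spectra(ds$recording, ds$codas)
head(cs$clicks[, c("coda_id", "click_index", "peak1_hz", "peak2_hz", "label")])
#>   coda_id click_index peak1_hz peak2_hz label
#> 1   c0001           0 5428.571       NA     a
#> 2   c0001           1 5428.571       NA     a
#> ...
table(cs$codas$majority_label)
#> a i
#> 6 2
```

One peak in band → the click is *a*-type; the 5,429 Hz peak sits one
frequency bin (≈ 286 Hz at 3.5 ms) from this coda's true resonance, which
the generator jittered to 5,431 Hz. Formant tracking over the assembled
time-insensitive coda agrees:

```r
tic <- time_insensitive_coda(ds$recording, ds$codas[[1]], -2.0, 3.5)
tic$duration_ms              # 5 clicks x 3.5 ms
#> [1] 17.5
tr <- formant_path(tic$samples, 48000)
tr$vowel_label; round(mean(tr$frames$f1_hz))
#> [1] "a"
#> [1] 5439
tube_length_for_frequency(7827) * 100   # cm of closed tube for a 7.8 kHz peak
#> [1] 2.191133
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli/codavowel.R", package="codavowel"))') \
    simulate --outdir sim --seed 3
Rscript .../codavowel.R analyze --wav sim/session.wav \
    --annotations sim/annotations.csv --movement sim/movement.csv --outdir out
```

`analyze` writes per-stage CSVs (clicks, coda labels, mismatch histogram,
formant grid, per-whale vowel report, trajectory stats, movement
correlations) and a JSON manifest; exit codes are 0/2/3 for
ok/bad-input/stage-failure.

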