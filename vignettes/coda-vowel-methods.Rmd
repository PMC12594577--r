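---
title: "Methods: coda vowel and diphthong analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coda vowel and diphthong analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(codavowel)
```

## The problem and the model

Sperm whale codas are short trains of broadband multipulse clicks. The
working hypothesis behind this package is source–filter production: the
phonic lips provide an impulsive source, and air-filled cavities (notably the
distal air sac) act as a resonant filter, imposing formant-like spectral
peaks on each click. Under that model a coda's "vowel" is the configuration
of the filter — one resonance near 5.8 kHz (*a*) or two resonances near 3.8
and 6.6 kHz (*i*) — and a "diphthong" is a controlled movement of the
resonance across the clicks of one coda.

The pipeline tests two empirical claims on any annotated recording:

1. **Discreteness** — per-click spectral-peak counts sort codas into two
   categories with few mixed codas (the mismatch histogram).
2. **Bimodality of trajectories** — the distribution of within-coda peak
   displacement (`c1dist`, `cndist`) is better described by two Gaussian
   components than one (BIC selection), separating level codas from
   diphthongs.

Both statistics are computed from primitives implemented here: Welch PSD,
constrained peak picking, LPC formant tracking, and 1-D Gaussian mixture EM.

## Key parameters (defaults in `analysis_config()`)

| parameter | default | unit | why |
|---|---|---|---|
| `band_hz` | 1000–10000 | Hz | analysis band for peaks and formants |
| `min_sep_hz` | 1500 | Hz | minimum distance between selected peaks |
| `rel_height` | 0.25 | – | peak height floor, fraction of band max |
| `welch_pre_ms`/`welch_post_ms` | 2.0 / 1.5 | ms | 3.5 ms click window: signal rise plus roughly half the ~3.1 ms inter-pulse interval, excluding the second pulse |
| `start_offset_ms`, `segment_ms` | −2.0, 15 | ms | click segment relative to the waveform peak |
| `buffer_ms` | 25 | ms | silence between assembled codas |
| `spec_window_ms` | 5 | ms | spectrogram analysis window |
| `grid_offsets_ms` × `grid_durations_ms` | {−2.0, −1.5} × {3.0, 3.5, 4.0, 4.5, 5.0, 14.5, 15.0} | ms | 14 extraction cells of the formant grid |
| `lpc_ceilings_hz` | 5 values, log-spaced 7–13 kHz | Hz | candidate ceiling ladder |
| `lpc_order` | 6 | – | two expected resonances + spectral-tilt pair |
| `lpc_bw_cap_hz` | 800 | Hz | reject noise poles (true bandwidths ~400 Hz) |
| `gmm_k_range` | 1–5 | – | mixture orders compared by BIC |
| `bout_gap_s` | 10 | s | bout boundary (inclusive) |
| `sound_speed_m_s` | 343 | m/s | tube model constant (air) |

The band limits, separation, height floor, Welch window split, segment
defaults, buffer, spectrogram window, grid values, mixture range, bout gap
and sound speed reproduce the published analysis. The tracker internals
(ceilings, order, window/step, bandwidth cap, smoothness weight) are **not**
published in the main analysis text; the values above are this package's own
choices, fixed during development against synthetic fixtures: order 10
admitted spurious low-bandwidth noise poles on 3–5 ms click segments which
an order-6 model avoids, and an 800 Hz cap passes resonances of ~400 Hz
bandwidth after window broadening while rejecting noise. They are recorded
in every run manifest.

## The smoothest-path tracker

For each ceiling the signal is Fourier-resampled to twice the ceiling,
pre-emphasized from 50 Hz, windowed (Gaussian-like, 5 ms / 1 ms hop), and
fit by autocorrelation LPC; prediction-polynomial roots give
(frequency, bandwidth) candidates, of which the lowest one or two inside the
analysis band are the frame's F1/F2 proposal. A dynamic program then picks
one ceiling per frame minimizing

    Σ_t w · mean(bw/f)_t  +  Σ_t Σ_k |log f_k,t − log f_k,t−1|  +  0.5·|Δcount|

The count-change penalty (0.5 per formant appearing/disappearing between
frames) is our addition: without it the path can oscillate between one- and
two-formant analyses inside a single coda, which contradicts the
all-frames/no-frames classification rule. Empty frames cost a constant 5 so
the DP prefers any real candidate. Path optimality is verified in the tests
against exhaustive enumeration over ceiling assignments.

Classification is deliberately strict, as in the reference rule: *i* only if
every frame carries F1 and F2, *a* only if no frame carries F2, otherwise
unclassified ("?").

## What the generator emulates — and what it does not

`synthesize_coda()` drives cascaded two-pole resonators with impulse pulse
pairs (IPI 3.1 ms, second pulse at half amplitude), places clicks at
template ICIs (`1+1+3` long-long-short-short; `5R1`/`5R2` regular), moves
per-click resonance centres by a piecewise-linear trajectory law (the turn
at the middle click for rise–fall shapes), and adds white Gaussian noise at
a stated SNR (power measured over the click-active samples). Defaults state
the world the analysis assumes: *a* at 5,780 Hz, *i* at 3,757/6,579 Hz
(published means), 400 Hz bandwidths, 30 dB SNR, a 60/40 a/i mixture,
mostly level trajectories, 96 kHz fixture rate. Trajectory span (1,400 Hz)
is a free parameter: the source describes trajectories only qualitatively.
Between-coda centre spread is 400 Hz, and depth coupling is implemented by
mixing the standardized depth trace into the per-coda centre displacement
with coefficient ρ, so the population peak–depth correlation equals ρ (0 by
default; ρ = 0.6 emulates the observed depth regime).

Not emulated: spermaceti-organ propagation and directionality, multipath and
surface echo, distance/orientation filtering of non-focal clicks, coda-type
repertoire statistics, and any dependence of click amplitude on behaviour. A
green synthetic test therefore establishes that the *pipeline* recovers the
structure it assumes, at the stated SNR and resonator model — not that field
recordings contain that structure.

## Numerical choices and degenerate inputs

- Welch on a 3.5 ms window uses a single Hann segment (no averaging:
  splitting a 336-sample window would destroy the ~286 Hz resolution the
  peak constraints need). Zero-padding is available (`welch_nfft_pad`) but
  off by default to match the conventional estimator.
- Peak picking resolves plateaus to their first sample and applies the
  distance constraint greedily by descending height, matching the standard
  `find_peaks` behaviour; output is ordered by ascending frequency and the
  "two highest" are kept. Equivalence with a brute-force constrained filter
  is tested on 1,000 random PSDs.
- Segments crossing the recording edge are zero-padded and logged;
  all-constant segments skip normalization with a warning instead of
  producing NaN.
- Even a/i splits in a coda are labeled `tie` rather than coerced; the
  mismatch count is n/2.
- EM uses k-means initialization, 5 restarts, a relative tolerance of 1e-8
  and a variance floor of 1e-6·var(x) against component collapse; BIC is
  −2 log L + (3k − 1) ln n and "best" means **minimum** (note other packages
  report the negated convention).
- `c1dist`/`cndist` are **signed** (distributions centre at 0 with two-sided
  spread); clicks missing a peak are skipped with a count, and a coda
  contributes a peak index only when ≥ 2 clicks carry it.
- Tube model: the algebraic round-trip L ↔ f is exact; note 7,827 Hz maps to
  2.1915 cm, which prints as the published 2.2 cm only at one-decimal cm —
  the forward direction from exactly 2.2 cm gives 7,795 Hz. Tests assert at
  the printed precision.
- Annotated click times are quantized to the sample grid by the generator so
  that annotation invariants (peak ≥ click time) hold exactly at any rate.

## Open design decisions taken here

- **Annotation format**: CSV with header, seconds as floats — the source
  format is unspecified; CSV is the lowest-friction interchange.
- **Peak vs onset times**: when `peak_time_s` is absent it is derived as the
  |amplitude| maximum within 15 ms after the annotated time, since annotated
  times are not guaranteed to sit on the peak.
- **"Labeled in order"** is read as ascending frequency (consistent with
  F1 < F2 usage); heights are recorded alongside.
- **Formant-grid means** average frame means within a coda, then codas, then
  tied best parameter sets (ties all contribute, which is why reported
  `psetsN` can be large).
- **Correlation pooling**: clicks are pooled across whales by default;
  per-whale correlation is a matter of subsetting. Whale exclusions for the
  correlation stage are configuration, not hard-coded.
- **Dialogue triples**: when three codas fall within one overlap window the
  nearest pair is transcribed together and the surplus coda is flagged as a
  possible third whale, not resolved.

## Limitations

The tracker assumes at most two formants in band; the simulator's white
noise is optimistic about low-frequency flow noise on tags; mismatch
reference proportions (≈78/12/9%) and the published per-whale agreement
table depend on the field corpus and are documented reference numbers, not
test assertions; and trajectory-shape thresholds (`diphthong_flag`) default
to 200 Hz where the reference analysis classified shapes visually — the
GMM crossover (`gmm_crossover()`) offers a data-driven alternative.
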