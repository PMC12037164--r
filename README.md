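# silenttrack

Tools for quantifying **ocular and neural tracking of silent speech**: when
people watch a muted video of a talking face, their eye movements and their
cortical activity follow the *unheard* acoustic envelope of the speech. This
package implements the full analysis chain needed to measure that effect —
stimulus-feature extraction, spectral estimation, coherence, and
cluster-based permutation inference — together with a synthetic-cohort
generator so every stage can be exercised and validated without access to
original MEG recordings.

It is aimed at researchers analysing slow (delta-range) stimulus–response
coupling in continuous designs: channels-by-time recordings with one
blink-dominated ocular component, a forward (intelligible) versus backward
(time-reversed) condition contrast, and listening groups with different
auditory experience (hearing, acquired deaf/hard-of-hearing, congenitally
deaf).

## What it computes

**Speech envelope.** The audio is bandpass-filtered into nine bands that are
equidistant on the cochlear map (Liberman cat frequency–position map,
frequency-scaled so the basal end of the cochlea corresponds to 20 kHz; over
100–10,000 Hz the integer cutoffs are 101, 220, 402, 680, 1103, 1748, 2732,
4231, 6517, 10000 Hz). Per band a zero-phase 4th-order Butterworth filter and
the magnitude of the analytic (Hilbert) signal give a band envelope; band
envelopes are averaged and resampled to 150 Hz by FFT interpolation.

**Coherence.** After 0.1–12 Hz zero-phase FIR filtering and segmentation
into 6-s epochs, multitaper (DPSS, ±0.5 Hz smoothing, 5 tapers) Fourier
coefficients are evaluated on the grid 0.166–5 Hz in steps of 0.166 Hz. The
cross-spectral density over epochs and tapers yields magnitude-squared
coherence

    C_ab(f) = |S_ab(f)|^2 / (S_aa(f) S_bb(f)),

and **partial coherence** removes, per frequency, the linear contribution of
the ocular channel via the Schur complement
`S_xy|z = S_xy − S_xz S_zz⁻¹ S_zy`, isolating brain–stimulus coupling not
attributable to eye movements. For independent signals the expected
coherence estimate is `1/n_est` (the chance level).

**Statistics.** Forward-vs-backward differences are tested with a
cluster-based permutation dependent-samples *t* test (cluster-forming
threshold p = 0.01, cluster mass = summed *t*, null = maximal mass over
within-subject sign flips). Group comparisons use a mixed 2×3 ANOVA
(modality: lip vs envelope, within-subject; group, between-subject) on
forward−backward contrasts, cluster-corrected over frequency, plus Welch and
paired post hoc *t* tests.

## Worked example

```r
library(silenttrack)

spec <- cohort_spec(n_per_group = c(hearing = 5, dhh = 5, congenital = 5),
                    duration = 120, n_neural = 4)
cfg  <- run_config(cohort = spec, n_perm = 500, seed = 7)
bundle <- run_pipeline(cfg)
print(bundle)
```

Output (abridged) from this exact run:

```
forward vs backward, ocular envelope:
  significant cluster 0.17-1.00 Hz (mass 25.4, p = 0.0020)
forward vs backward, ocular lip:
  no significant cluster
forward vs backward, neural envelope:
  significant cluster 0.17-1.17 Hz (mass 113.5, p = 0.0020)
forward vs backward, neural envelope partial:
  significant cluster 0.17-1.17 Hz (mass 107.9, p = 0.0020)

band-averaged (0-1 Hz) ocular point ANOVA:
  group: F(2,12) = 26.14, p = 0.0000
  modality: F(1,12) = 73.54, p = 0.0000
  interaction: F(2,12) = 25.36, p = 0.0000

blink rate: 0.198 Hz forward, 0.197 Hz backward
```

Reading: the eyes track the unheard speech envelope below ~1 Hz only when
the video plays forward (the cluster covers the 0.33–0.83 Hz coupling band,
widened by the ±0.5 Hz spectral smoothing); lip-movement tracking shows no
condition difference; the neural effect survives partialization of the
ocular channel; and the group ANOVA separates the three listening groups on
the envelope contrast.

Individual stages are available as plain functions
(`make_speech_envelope()`, `extract_envelope()`, `fir_bandpass()`,
`mtm_spectra()`, `accumulate_csd()`, `coherence()`, `partial_coherence()`,
`cluster_perm_ttest()`, `cluster_perm_mixed_anova()`, `detect_blinks()`,
...) and on user-supplied data via `run_config(mode = "files", ...)` with
delimited-text recordings (`write_recording()` / `read_recording()` show the
format).

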