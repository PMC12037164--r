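---
title: "Measuring ocular and neural tracking of silent speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ocular and neural tracking of silent speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When a person watches a muted video of a speaker, several physiological
signals nevertheless follow the *acoustic* structure of the unheard speech:
cortical activity in temporal and motor regions, and — the focus here — eye
movements, whose vertical, blink-dominated component becomes coherent with
the slow (< 1 Hz) speech envelope when the video is intelligible (played
forward) but not when it is played backward. `silenttrack` implements the
analysis chain that measures this effect and the group comparisons that ask
how it depends on auditory experience (hearing participants, participants
who lost hearing after language acquisition, and congenitally deaf
participants).

Because such analyses are usually developed against large MEG datasets that
cannot ship with software, the package is built around a synthetic-cohort
generator with the statistical structure the analysis assumes. Every stage
is tested against that generator plus closed-form oracles.

# The model

## Stimulus features

The **speech envelope** is the average of band envelopes over nine bands
equidistant on the cochlear map. The frequency–position map is the Liberman
cat map `f(x) = A (10^{2.1 x} - 0.8)`, `x` the relative distance from the
apex, frequency-scaled so the basal end corresponds to the 20 kHz limit of
human hearing (`A ≈ 159.88`). Equidistant positions between the inverse map
at 100 and 10,000 Hz give cutoffs reported as integers via ceiling (so each
lower cutoff lies inside the analysis range): 101, 220, 402, 680, 1103,
1748, 2732, 4231, 6517, 10000 Hz. Band filtering uses a zero-phase 4th-order
Butterworth bandpass; the band envelope is the magnitude of the analytic
signal; the average is resampled to 150 Hz by FFT interpolation after a
low-pass guard at 75 Hz. The 50 Hz **lip-area** signal is FFT-upsampled to
the same rate.

A numerical note: the zero-phase Butterworth is applied in the frequency
domain through the squared magnitude response of the analog prototype,
`|H(f)|² = 1 / (1 + ((f² − f₀²)/(bw·f))^{2n})`. On interior samples this is
what a forward–backward (filtfilt) recursion converges to, and it remains
well-conditioned for the narrow 101–220 Hz band at audio rates, where the
transfer-function recursion is numerically fragile; the test suite checks
agreement with `signal::filtfilt` on an in-band tone (within 1%).

## Spectral estimation and coherence

Signals are band-limited to 0.1–12 Hz with a zero-phase Hamming-window FIR
(overlap-add; kernel length `6.6 / transition × rate`, with transitions
`min(hp, 2)` Hz and `0.25·lp` Hz — the kernel rule applied to the shortest
transition), then cut into 6-s epochs; stimulus features travel with the
channels so alignment is structural. At 0.1 Hz high-pass the kernel is 66 s,
so recordings must exceed that length; the error message reports the
minimum.

Multitaper estimation uses DPSS tapers with half-bandwidth W = 0.5 Hz: on
6-s epochs `NW = 3`, giving `K = floor(2·NW) − 1 = 5` orthonormal tapers
(computed from the tridiagonal matrix that commutes with the concentration
operator; concentrations all exceed 0.94). Fourier coefficients are
evaluated at exactly the grid frequencies 0.166–5 Hz (step 0.166 Hz = the
Rayleigh frequency of 6-s epochs; 30 bins). Epochs and tapers pool as
equally weighted estimates into the cross-spectral density, `n_est = epochs
× tapers`; coherence is `|S_ab|²/(S_aa S_bb)` and its chance level for
independent signals is `1/n_est`. Partial coherence applies the Schur
complement `S_xy|z = S_xy − S_xz S_zz⁻¹ S_zy` to the (a, a), (a, b), (b, b)
entries before forming the ratio; a zero-power partialization channel is
treated as a no-op with a warning, and degenerate bins propagate as `NA`
rather than 0 so they never enter band averages or cluster statistics.

## Inference

*Condition contrast.* Per bin, a paired t statistic on forward − backward;
clusters are maximal connected sets (1-D chain over frequency; for
frequency×space, the graph product with a spatial neighbour graph) of bins
beyond the two-sided critical t at the cluster-forming threshold (p = 0.01).
Cluster mass is the summed t; the null is the maximal absolute mass over
random within-subject sign flips; `p = (1 + #{null ≥ obs}) / (1 + n_perm)`,
so the smallest attainable p is `1/(1+n_perm)`. Positive and negative
clusters form separately and each is compared against α/2.

*Group comparison.* A mixed 2×3 ANOVA on forward−backward contrasts:
modality (lip vs envelope) within subjects, listening group between
subjects. The split-plot decomposition (subject means for the between
stratum, subject differences for the within stratum) vectorizes over bins
and matches `stats::aov` with Error strata exactly on worked data.
Permutation schemes: group labels permute across subjects for the group
effect; modality flips within subjects for the modality effect; the same
within-subject flips under fixed groups approximate the interaction null (an
exact interaction permutation does not exist — the p-values for the
interaction are therefore approximate). Single-bin/ROI versions are
parametric, with paired and Welch (Satterthwaite) post hoc tests.

# The synthetic cohort

The generator emulates exactly the features the analysis relies on:

* **Envelope**: a syllable pulse train with gamma-jittered inter-syllable
  intervals (mean rate 3.3 Hz, CV 0.3) convolved with a 100 ms Hann kernel,
  multiplied by a sentence-level on/off gate and lifted by a small positive
  noise floor. The gate alternates speech and pause segments with
  gamma-jittered durations (duty cycle 0.8, mean cycle 1/0.25 Hz). A
  deterministic periodic gate would put phase-locked harmonic lines into
  every realization and make *independent* signals coherent at 0.25 k Hz —
  coherence measures cross-epoch phase consistency — so stochastic segment
  durations are essential, not cosmetic. The modulation-spectrum argmax in
  2–5 Hz lands near the nominal syllable rate; renewal theory puts the peak
  of a jittered pulse train slightly above the mean rate, and the measured
  mean over seeds is ~3.4–3.5 Hz for a 3.3 Hz setting, within the ±0.3 Hz
  band the validation asserts.
* **Lip signal**: 50 Hz, correlated with the envelope at a target Pearson r
  (default 0.5). The shared component is the envelope's > 2.5 Hz
  syllable-band content only: mouth opening co-varies with the envelope at
  articulation rates, while the slow sentence-level power is not mirrored in
  lip area. This reproduces the key negative control — no forward/backward
  lip-tracking difference below 1 Hz — and the steep (order 8) cutoff keeps
  shared variance out of reach of the ±0.5 Hz multitaper smoothing.
* **Recordings**: each neural channel is `strength × z(band-filtered
  envelope) + 1/f noise`; the ocular channel adds a Poisson train (0.2 Hz)
  of stereotyped biphasic blink pulses (~300 ms, amplitude ≫ noise SD).
  Coupling is confined to 0.33–0.83 Hz. The backward condition drives the
  channels with the time-reversed envelope, mirroring a reversed-video
  manipulation, so coherence with the forward-order envelope is at chance.
  Optionally blinks are biased into envelope troughs in the forward
  condition (`blink_trough_bias`), emulating listeners withholding blinks
  while speech is on.
* **Cohort defaults** mirror the study conditions the pipeline targets:
  groups of 49/19/7 subjects (hearing/DHH/congenitally deaf), ~564 s per
  condition, forward-only coupling with strengths 0.30 / 0.45 / 0 — the DHH
  group tracks more strongly than the hearing group, the congenitally deaf
  group not at all. Effect magnitudes are free parameters (coherence
  magnitudes are rarely reported); these defaults were chosen once for
  comfortable desk-scale power.

What the generator does **not** emulate: volume conduction and sensor
mixing, inter-subject anatomy, heartbeat and movement artifacts, attention
fluctuations, or any nonlinearity in the visuo-phonological mapping. Passing
tests therefore demonstrate the correctness and calibration of the
*analysis* under the stated statistical structure, not properties of real
MEG data.

# Numerical and design choices

* "Spectral smoothing 0.5" is read as a half-bandwidth of ±0.5 Hz (the
  convention of common multitaper toolboxes); the NW reading would give zero
  tapers, which is impossible.
* The frequency grid is evaluated by explicit complex exponentials at the
  requested frequencies rather than nearest-FFT-bin lookup; at the Rayleigh
  spacing both agree, but exact evaluation generalizes to other grids.
* Band averages use the half-open convention `f_lo ≤ f < f_hi` (with a 1e-9
  Hz tolerance for grid round-off), matching "below 1 Hz" summaries.
* ROI peak selection maximizes the band-averaged forward−backward contrast
  (not raw coherence), with a deterministic first-wins tie-break; whether an
  original analysis would select on raw forward coherence instead is an
  interpretive choice and is isolated in one function.
* The coherence stimulus is always the forward-order envelope/lip signal;
  the condition manipulation lives in the generator's driver. With real
  data, supply the features of the forward stimulus for both conditions.
* One master seed spawns named substreams (cohort, each permutation test),
  so changing `n_perm` never changes the synthetic data and any partial
  rerun reproduces bit-identical results.
* Blink detection smooths with a 150 ms window before median/MAD z-scoring
  (blinks last ~300 ms and survive; fast noise does not), threshold 3 robust
  SDs, refractory 0.5 s resolved by keeping the stronger peak.

## Validation problem sizes

The test battery runs at desk scale, chosen so the whole suite stays in the
minutes range: 120-s recordings (20 epochs × 5 tapers = 100 estimates),
cohorts of 6–15 subjects, 200–500 permutations, 20-replicate Monte-Carlo
checks. Calibration checks include: chance-level coherence `≈ 1/n_est` for
independent channels; family-wise error of the cluster t test ≤ 0.08 at
α = 0.05 under a 200-replicate null; equivalence of the single-bin cluster
test with the exact sign-flip permutation test (full 2¹⁰ enumeration);
mixed-ANOVA F values against hand-computed sums of squares and `aov`; Welch
df against the Satterthwaite formula; and a three-level coupling-strength
scan (0.10/0.15/0.30) verifying monotone parameter recovery in both
band-averaged contrast and detection rate.

# Known limitations

* Partial coherence can exceed raw coherence under suppressor structure;
  no `partial ≤ raw` invariant is asserted or implied.
* The interaction permutation scheme is approximate (see above).
* With very few subjects per group (e.g. 2) the ANOVA is computable but
  underpowered; the generator refuses groups of 1 when statistics are
  requested.
* The FIR kernel at `hp = 0.1` Hz is 66 s; recordings must be longer, and
  the first/last kernel lengths rely on reflect-padding.
* Cluster p-values are permutation-resolution limited (`1/(1+n_perm)`).
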