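---
title: "Methods: frequency-tagged analysis of syllable and word processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-tagged analysis of syllable and word processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures implemented in `freqtag`,
the assumptions behind them, and the design decisions taken where several
reasonable implementations exist. It is the reference for *why* the code
does what it does; the README shows *how* to run it.

## The tagging model

The paradigm presents isochronous syllables every 250 ms (4 Hz) that form
disyllabic units at 2 Hz. Because stimulus tokens are assembled from
independently produced syllables, all acoustic energy is at the syllable
rate and its harmonics; any neural response at the 2 Hz unit rate must
reflect internal grouping of syllables into words. The analysis therefore
revolves around narrowband quantities at exactly 2 Hz and 4 Hz:

* **Evoked power.** Trials are averaged in the time domain first, so only
  phase-locked activity survives, then a single taper (Hann by default) is
  applied over the 0.5–9.5 s analysis window. The 9 s window gives a bin
  spacing of 1/9 Hz, which places 2 Hz and 4 Hz exactly on bin centers —
  this is a structural requirement, not a convenience, and
  `neighbor_bin_contrast()` refuses target frequencies that are off-grid
  by more than 1e-6 Hz. The first 0.5 s are excluded to avoid
  onset-transient contamination.
* **Neighbour-bin contrast.** A tagged response is quantified as the
  power at the target bin minus the mean of the bins at offsets
  {−3, −2, +2, +3}. The immediate neighbours (±1) are excluded because the
  taper's main lobe leaks target power into them; a ratio variant is
  available (`relative = TRUE`) but subtraction is the default because it
  keeps the statistic linear in power, which the cluster t statistics
  assume. Offsets are configurable.
* **Power scaling.** Spectra are scaled as squared sinusoid amplitude: a
  unit-amplitude phase-locked sinusoid at a bin center yields power 1.
  The rect-taper one-sided Parseval identity is pinned down by a test.

## The synthetic-data generator

The generator is first-class, tested code: every downstream stage is
validated against datasets whose ground truth it records.

**Stimuli.** `build_lexicon()` makes three corpus profiles. Structured
profiles (`native_like`, `foreign_like`) derive each word's second
syllable from its first through manner-preserving phoneme maps, so all six
phonological projections (identity, CV pattern, onset, manner, rime,
cross-boundary phoneme pair) are predictive within words; `foreign_like`
adds a fraction of irregular words to weaken the margin. The `random`
profile pairs syllables with equal probability of appearing at either
position, and `generate_sequence()` draws *fresh* pairings per sequence for
this profile — a fixed pseudo-word list would itself reintroduce grouping
statistics into the stimulus stream, which is exactly what this condition
must not contain. The manner-preserving maps also guarantee that plosive
onsets (whose tokens carry a 20 ms occlusion silence) are equally frequent
at odd and even positions, so the silences add no unit-rate acoustic cue.

**Audio.** Syllable tokens are band-limited noise bursts with
label-specific spectral centroids under identical raised-cosine windows,
peak-normalized per token. Only the amplitude envelope matters downstream,
so no articulatory detail is modelled; the cochlear modulation spectrum of
any synthesized sequence peaks at 4 Hz with no excess at 2 Hz (tested over
100 sequences). Token amplitudes can jitter multiplicatively with an AR(1)
profile across tokens (`token_jitter_sd`, `token_jitter_rho = 0.9`),
emulating slow natural loudness drift; because the jitter is independent
of syllable position it adds no 2 Hz energy, but its slow component is
what makes the 4 Hz envelope informative for the coupling analysis below.

**Forward model.** A parametric stand-in for an anatomical head model:
sensors on a 12 cm spherical cap, sources on a regular grid, and a
quasi-dipolar leadfield `(e × d)·n / |d|²` with distance decay and
orientation dependence (rank 2 per source, as for tangential-only MEG
sensitivity). The default grid uses 2 cm spacing: with tens of sensors
(rather than hundreds) a denser grid would make neighbouring leadfield
columns nearly collinear and every source-space result would be dominated
by cross-talk. Grid shape, spacing, and sensor count are arguments; the
ROI labelling keeps the non-auditory ROIs at least two grid steps from the
auditory patches because the toy beamformer's point-spread is about one
step.

**Trial simulation.** Each trial is a leadfield projection of
(a) envelope-driven, phase-locked 4 Hz responses in the auditory ROIs,
(b) 2 Hz responses in condition-dependent source sets whose instantaneous
amplitude is `1 + cfc_strength × (standardized 4 Hz envelope)`, and
(c) background noise. Three generator choices deserve comment:

* *Noise is projected brain noise.* Independent 1/f generators sit at the
  grid sources and reach the sensors through the leadfield (plus a 10%
  white sensor-noise floor). Sensor-space mixed noise looks like nothing
  in source space, so a beamformer can suppress it almost entirely and
  residual signal leakage then dominates every virtual channel;
  leadfield-projected noise gives each virtual channel an honest local
  noise floor, which is the regime real source analyses operate in.
* *2 Hz sources have fixed random carrier phases.* Different regions
  respond at different latencies; modelling them as phase-identical
  copies makes them perfectly coherent, and coherent sources partially
  cancel in minimum-variance beamformers. The phases are fixed across
  trials, so evoked power is unaffected.
* *Orientations are fixed random unit vectors per source* (a `"dominant"`
  option uses the leadfield's principal direction instead). Effective
  leadfield columns are unit-normalized so `snr` reads as a per-sensor
  amplitude ratio; `snr` values of 0.3–1 are used in the validation suite
  because single-trial evoked MEG responses genuinely sit at or below the
  1/f background.

The generator does **not** emulate: eye/heart artifacts (ICA removal is
out of scope), head movement, sensor dropout, coarticulation, or any
spectral detail of speech beyond the envelope. Passing tests therefore
demonstrate that the algorithms recover planted effects under realistic
SNR and leakage conditions — not that the pipeline is robust to every
artifact class of real recordings.

## Preprocessing

Butterworth filters are applied forward-and-reverse (zero phase; order 4
band-pass 1–160 Hz, order 4 band-stops at 50/100/150 ± 0.5 Hz). Artifact
z-scores are computed on the 110–140 Hz band (muscular) or on the absolute
first difference of the 9-sample running-median-filtered signal (jumps); a
median filter *preserves* steps, so differencing its output is what turns
a SQUID jump into a detectable spike. z-normalization uses mean/SD pooled
across all trials of the dataset (a per-trial scope is available, but a
trial-confined artifact inflates its own trial's SD so strongly that the
conventional thresholds of 15 and 30 become unreachable). Range rejection
flags trials whose per-channel min–max range exceeds 0.75e-5.
Epoching crops to −2.1–9.6 s and resamples with Fourier-domain resampling
(spectrum truncation), which is an ideal anti-aliasing low-pass with exact
passband amplitude; FIR polyphase resampling was rejected after measuring
6% passband ripple. Trial matching keeps correct-response trials and
subsamples every condition to the smallest count with a seeded draw.

## Source analysis

DICS filters are built from the cross-spectral density averaged over the
1.333–4.666 Hz band (so one *common* filter serves both tagging
frequencies and all conditions — condition contrasts can then not be
biased by filter estimation); LCMV filters use the band-limited (1.5–4.5
Hz) time-domain covariance. Regularization is `lambda` (default 10%)
times the mean of the real diagonal. Orientation is reduced to the
maximum-power direction: the leading eigenvector of `(Lᵀ C⁻¹ L)⁻¹`
restricted to the leadfield's non-degenerate subspace. Unit gain `w·l = 1`
is enforced by construction and verified in tests. No depth normalization
is applied because every statistic is a condition contrast through a
common filter.

## Cerebro-acoustic coherence

The acoustic envelope is the mean Hilbert magnitude of 8 Butterworth bands
(order 3, zero-phase) spaced equidistantly on the ERB-rate scale between
100 and 8000 Hz (log spacing is available; ERB is the default cochlear
map). Coherence at 4 Hz is computed sensor-wise from per-trial Fourier
coefficients and projected through the common DICS filter applied to both
the auto- and cross-spectral terms; the alternative (project trials first,
then compute coherence per source) is not the default because it requires
a time-domain filter. Fisher z = arctanh of the coherence magnitude is
applied before ROI averaging. The small-sample bias of coherence
(E[coh²] ≈ 1/n trials under independence) is reproduced by a test.

## Cross-frequency coupling

Source trials are downsampled to 100 Hz (the stated order: downsample,
then filter), band-passed 1.5–2.5 and 3.5–4.5 Hz (Butterworth order 4,
zero phase), Hilbert-enveloped per trial, and concatenated per condition.
Envelopes are copula-normalized (average ranks through the inverse normal
CDF) and mutual information uses the parametric Gaussian form
−0.5 log₂(1−r²) with the analytic psi-function bias correction. MI is
computed per seed-voxel/target pair and then averaged over the seed ROI
(`roi_mean_seed = TRUE` gives the alternative). Note the estimator's
sampling SE at n = 10⁴ and r = 0.9 is ≈ 0.013 bits, larger than its
systematic error; accuracy checks therefore average replicate draws.

Detecting planted coupling through a beamformer is the hardest recovery
problem in the suite, and the validation configuration reflects what it
needs: a single-layer "cortical sheet" grid (volumetric grids add an
unresolvable depth dimension that blurs the map), a compact planted
target block at the grid edge, the bilateral auditory seed (the coupling
modulator is the shared acoustic envelope), and trial counts around 45.
These are scientific statements about when such analyses can work at all:
with 30–60 sensors, source leakage — not estimator bias — is the binding
constraint.

## Cluster statistics

Node-level paired or two-sample t statistics are thresholded two-sided at
the cluster alpha (0.05); suprathreshold nodes need at least
`min_neighbors = 2` suprathreshold same-sign neighbours (single pruning
pass, also applied inside every permutation); connected components are
summed; and the observed sums are compared against the Monte Carlo
distribution of the per-permutation extreme cluster sums at the 2.5/97.5%
tails. p values are `(b + 1)/(n_perm + 1)`, never zero, with a relative
tie tolerance because the identity relabelling reproduces the observed
statistic exactly. For paired designs with `2^n ≤ n_perm` subjects the
sign flips are enumerated completely, making the test exact and invariant
to subject order. Grid sources use face connectivity (distance threshold
just above one grid step); the sensor rule (2 neighbours) is reused for
voxels and is configurable. The validation suite verifies
family-wise error within the nominal band on a 192-node lattice; on very
sparse graphs the
minimum-neighbour rule makes cluster formation itself so rare that the
test becomes strongly conservative — a property worth knowing before
running it on a handful of channels.

The ROI tests use Wilcoxon signed-rank / Mann-Whitney tests (exact for
small tie-free samples) with Bonferroni correction; identical paired
samples return p = 1 by convention. The mixed ANOVA is the classical
sums-of-squares decomposition via `aov()` with an
`Error(subject/(condition*hemisphere))` stratum, for balanced complete
designs only, with partial eta squared from each stratum's error term.
The learning analysis replaces a random-slope mixed model with orthogonal
polynomial OLS on the jackknife trial-wise power plus BIC model
comparison; this is a deliberate scope reduction, and group-level
inference should aggregate per-participant fits.

## Problem sizes

The validation suite simulates at 150–400 Hz sample rates with 10–60
trials, 30–60 sensors, and 48–90 sources; the full acquisition-rate chain
(1200 Hz → 500 Hz, 11.7 s epochs, 5850 samples) is exercised where the
arithmetic itself is the claim. These sizes were chosen so that each
planted effect is comfortably inside the detectable regime documented
above while a complete run stays within an ordinary desktop budget; they
are package choices, stated here once so that every test reads as a
scientific statement rather than a tuning artifact.

## Known limitations

* The toy forward model is not an electromagnetic head model; its purpose
  is ground-truth testing of algorithms, not anatomical realism.
* Table-style corpus values from external lexical databases are not
  reproducible here; the transition-probability machinery is validated on
  synthetic lexicons whose statistics are known by construction.
* The coupling analysis inherits beamformer leakage: top-decile MI maps
  are interpretable at the resolution of the grid, about one grid step.
* No ICA, no sensor interpolation, no head-movement correction.
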