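---
title: "Measuring the slow rhythm of Intonation Units: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the slow rhythm of Intonation Units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iurhythm)
```

## The question and the measurement model

Spontaneous speech is segmented into Intonation Units (IUs): prosodic
chunks of about a second that package at most one new idea each, delimited
by pitch reset, pauses, an IU-initial rush of syllables and IU-final
lengthening. If IU sequences have a characteristic pacing, IU onsets should
occur at consistent phases of the low-frequency components of the speech
amplitude envelope. `iurhythm` treats IU onsets as a point process and the
envelope as the field, and measures point–field synchronization per
frequency — the same logic used for spike–field coupling in
electrophysiology.

The chain is: envelope extraction → per-onset phase estimation →
per-speaker pairwise phase consistency (PPC) spectra → group average with
bootstrap confidence band → trough-constrained permutation null with FDR
control. Each stage is exposed as a function; `consistency_analysis()` and
`permutation_test()` run the composites.

## Envelope extraction

The wideband envelope is the average of narrowband Hilbert magnitudes over
a filterbank spaced equidistantly on the human cochlear map. Positions are
given by the Greenwood function $f(x) = 165.4\,(10^{0.06x} - 1)$ (Hz, $x$
in mm from the apex); `cochlear_band_edges()` places `n_bands + 1` edges at
uniform cochlear positions between `f_lo_hz` and `f_hi_hz` (defaults: 10
bands, 100–8000 Hz).

Band filtering uses a 4th-order Butterworth band-pass response and the
anti-alias stage an 8th-order low-pass at $0.4 \times$ the envelope rate,
both applied as zero-phase spectral filters: the signal's FFT is multiplied
by the squared magnitude response, which is exactly the response of a
forward–backward (filtfilt) application. Zero phase matters because the
whole analysis downstream is about phase; the spectral form is used because
direct transfer-function filtering is numerically unstable at the very low
normalized cutoffs involved (a 40 Hz cutoff on 16 kHz audio is 0.005 of
Nyquist, where an 8th-order recursion loses all precision). The cost is
circular (rather than linear) convolution at the recording edges, a few
filter time-constants wide — negligible for minutes-long recordings, and
windows near the edges are excluded anyway (below).

The envelope is resampled to 100 Hz by default. This is the minimal
common rate that preserves the 2–7 Hz syllable band with generous margin
and makes a 2-s analysis window exactly 200 samples, i.e. a 0.5 Hz bin
spacing. Per-recording `unit_max` normalization is the default because the
trough magnitude threshold (0.01) is defined on a 0–1 scale.

## Phase estimation and PPC

`extract_windows()` takes windows of `window_s` seconds (default 2)
centered on each onset, $[t - w/2, t + w/2)$. Onsets are snapped to the
nearest envelope sample (≤ 5 ms error at 100 Hz, negligible below 5 Hz).
Windows that would cross a recording boundary are dropped and counted —
there is no padding anywhere in the pipeline, so partial windows cannot be
estimated consistently. Each window is demeaned, multiplied by one
full-length symmetric Hann taper, and Fourier transformed without padding;
the analyzed bins are $k/w$ Hz for $k = 1, \dots$ (DC excluded, and for an
even-length window the Nyquist bin too, since its phase is degenerate).
Bins where a window has numerically zero amplitude (e.g. a constant
window) yield an undefined phase; the event is dropped from those bins
only, with the per-bin event count tracked.

For a speaker with $N$ retained onsets and phases $\theta_1, \dots,
\theta_N$ at a bin, the pairwise phase consistency is
$$\mathrm{PPC} = \frac{2}{N(N-1)} \sum_{j<k} \cos(\theta_j - \theta_k),$$
computed through the algebraically identical $O(N)$ form
$((\sum\cos\theta)^2 + (\sum\sin\theta)^2 - N) / (N(N-1))$. PPC estimates
the squared population phase-locking and its expectation does not depend on
$N$, which is what makes spectra comparable between speakers with very
different IU counts. Speakers enter only with strictly more than 5 retained
onsets (below that, 10 or fewer pairs make the estimate useless). In
multi-party recordings, windows that also contain other speakers' speech
are retained: overlap is part of conversation, and excluding such windows
would bias the sample toward monologue.

The group spectrum is the unweighted mean across speakers — speakers, not
IUs, are the exchangeable unit — with a percentile bootstrap (resampling
speakers with replacement, 1000 draws, 2.5/97.5 percentiles). Percentile
intervals were chosen as the simplest method valid for a mean of a small
number of bounded quantities; the interval is clamped to contain the point
estimate so degenerate cases (one speaker, identical spectra) behave.

## The trough-constrained null

A raw permutation of onset times would be too liberal: every IU onset is
necessarily a syllable boundary, and syllable boundaries sit in envelope
troughs, so even rhythm-free onsets are phase-aligned with the syllabic
structure. The null must preserve that association. `detect_troughs()`
finds local envelope minima (strict falling-to-rising sign changes) with
prominence at least `min_magnitude` (default 0.01 on the 0–1 scale) and
thins them greedily, deepest first, until no two retained troughs are
closer than `min_separation_s` (default 200 ms, the average syllable
scale). "Magnitude" is read as topographic prominence — depth relative to
the lower of the two key saddles — because an absolute-level reading would
make the threshold meaningless for loud passages; deepest-first thinning is
deterministic and order-independent. Separation comparisons carry a
sub-sample tolerance so minima spaced exactly at the bound are all kept.

Each surrogate dataset replaces every speaker's onsets with the same number
of trough times, drawn uniformly without replacement from the troughs of
the same recording whose analysis window fits the recording — preserving
per-speaker onset counts, recording assignment, and the window-boundary
selection applied to the observed data. Speakers permuted independently of
one another: the minimal permutation respecting PPC's per-speaker
structure. If a recording lacks enough eligible troughs for a speaker, the
speaker is excluded from both the observed and the surrogate analyses, so
the statistic and its null always see identical data. The per-bin p-value
over `n_perm` surrogate group means (default 1000) is $(r+1)/(n_\mathrm{perm}+1)$
with $r$ the count of surrogate means at least as large as the observed
one; p-values can therefore never be 0. Significance uses the
Benjamini–Hochberg step-up rule at `fdr_q` (default 0.01) across all
analyzed bins (default: up to 10 Hz). The trough phase matrix per recording
is computed once and indexed per surrogate, so 1000 surrogates cost about a
second at these problem sizes.

## Duration statistics and the robustness filter

`duration_stats()` summarizes IU durations pooled across speakers:
a 50 ms-bin probability histogram, the median, and a percentile bootstrap
CI of the median (1000 resamples of individual IUs). `filter_recent_iu()`
implements the stationarity control: keep only IUs whose silent gap since
the immediately preceding IU (offset-to-onset, in the same recording,
across speakers by default — turn-taking gaps are real gaps; a
`same_speaker_only` switch is provided) is below 1 s. Gaps are always
computed on the original sequence, which makes the filter a single pass and
idempotent; computing gaps on the filtered sequence would make the result
depend on iteration order. The filtered annotation feeds back into the
same spectrum/permutation pipeline unchanged.

## The synthetic generator

`generate_envelope()` emulates the statistical structure of conversational
speech envelopes rather than its acoustics: per speaker, IU onsets are laid
down with onset-to-onset intervals `iu_period_s` × a unit-mean log-normal
jitter (`period_jitter_cv`, default 0.1); each IU is a run of
raised-cosine syllable bursts whose count is uniform on 3–7, whose total
span is `n / syllable_rate_hz` (so the mean within-IU syllable rate is the
nominal 5 Hz), with the final syllable `final_lengthening`× longer within
that span and peak amplitudes decaying geometrically to `amplitude_decay`
(0.7) — the IU-initial reset and IU-final slowing. An exponential pause
(mean 0.2 s, truncated at 2 s) is fitted inside each interval; when an
interval cannot hold both its IU and the drawn pause, the pause is squeezed
first and the IU truncated second, and only an interval shorter than the
minimal IU is extended. This keeps the realized mean onset-to-onset
interval equal to `iu_period_s` (the parameter's meaning) and most
inter-IU gaps under 1 s. Setting jitter and pauses to zero produces an
exactly periodic train, the degenerate case used in tests.

Syllable durations and amplitudes additionally carry log-normal jitter
(`syllable_jitter_cv`, default 0.4, a realistic coefficient of variation
for spontaneous-speech syllables). This matters: without it every IU
presents the identical burst pattern, the two seconds around each onset are
nearly deterministic, and phase consistency becomes artificially broadband
instead of reflecting the IU rhythm. All speakers are generated as
independent simultaneous streams summed on a small constant floor
(`noise_floor` 0.005) and normalized to unit maximum.

`generate_audio()` amplitude-modulates band-limited noise (100–4000 Hz)
with the designed envelope, so the full audio→envelope→spectrum path can be
validated; `null_annotation()` places onsets at randomly chosen troughs to
create data that satisfy the null exactly, for calibration.

What the generator does **not** emulate: pitch, lexical content, formant
structure, turn-taking (speakers overlap freely), room acoustics and
recording noise, and speaker-specific rate variation. Passing tests on
synthetic data therefore demonstrate that the estimator and the test are
correct and calibrated under the assumed structure — not that any
particular real corpus has a 1 Hz IU rhythm.

## Problem sizes and test design

The validation suite runs the full pipeline on 300-s, 4-speaker synthetic
recordings (about 1200 IUs), the scale at which the group spectrum is
stable while a complete test run stays fast: ground-truth recovery over 10
generator seeds (argmax of group PPC below 4 Hz at the 1 Hz bin in at
least 9), a positive control with 1000 permutations (exceedance p =
1/1001 at the peak bin), and FDR calibration on 20 complete-null replicates
with 200 permutations each (realized false-discovery proportion within the
1% bound on average). PPC's $O(N)$ identity is checked against the explicit
pairwise sum to $10^{-10}$ on 1000 random inputs, phase extraction against
a directly evaluated tapered DFT, Greenwood band edges against numeric
inversion of the cochlear map, and the bootstrap CIs by coverage
simulation.

## Known limitations

- The cochlear filterbank is a fixed Butterworth-response approximation;
  gammatone/ERB filterbanks and loudness models are out of scope.
- Phase is estimated from a single Hann taper per window; multitaper
  estimates would trade variance for bias differently but change the bin
  structure.
- The bootstrap is percentile-based; for very few speakers (< ~8) its
  coverage is approximate.
- The trough "magnitude" is implemented as prominence only; depth-below-
  threshold readings would retain different trough sets on compressed
  recordings.
- Envelope values near recording edges inherit circular-filtering
  artifacts; windows and troughs within half a window of the edges are
  excluded from analysis, which also means recordings must be longer than
  the analysis window by a comfortable margin.
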