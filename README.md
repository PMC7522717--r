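# iurhythm

Quantifying the slow rhythm of prosodic segmentation in spontaneous speech.

Spontaneous speech is delivered in Intonation Units (IUs): prosodic chunks
of roughly one second, delimited by pitch reset, pauses, a rush of syllables
at the chunk start and lengthening at its end. `iurhythm` measures whether
IU onsets occur at consistent phases of the low-frequency components of the
speech amplitude envelope — that is, whether IU sequences form a ~1 Hz
rhythm sitting hierarchically above the ~5 Hz syllabic rhythm — and tests
that consistency against a surrogate null that respects the acoustics of
syllable boundaries.

## What it computes

1. **Wideband speech envelope.** Audio is filtered into bands spaced
   equidistantly on the human cochlear map (Greenwood function,
   default 10 bands over 100–8000 Hz); per band the envelope is the
   magnitude of the analytic (Hilbert) signal; the band envelopes are
   averaged, low-pass filtered, resampled (default 100 Hz) and scaled to a
   0–1 range.
2. **Pairwise phase consistency (PPC).** Around each IU onset a 2-s
   envelope window is demeaned, Hann-tapered and Fourier transformed,
   giving a phase per 0.5 Hz bin. Consistency of onset phases at frequency
   *f* over a speaker's *N* onsets is

   PPC(f) = 2 / (N(N−1)) · Σ_{j<k} cos(θ_j(f) − θ_k(f)),

   an estimator of squared phase locking that is unbiased by *N* (computed
   via the equivalent O(N) identity). Speakers with more than 5 IUs get a
   consistency spectrum; spectra are averaged across speakers with
   bootstrap 95% confidence bands.
3. **Trough-constrained permutation test.** Every IU onset is necessarily a
   syllable boundary, and syllable boundaries sit in envelope troughs. The
   null therefore permutes each speaker's onsets onto detected envelope
   troughs (local minima with prominence ≥ 0.01 on the 0–1 scale, ≥ 200 ms
   apart), rebuilding the group spectrum 1000 times. Per-bin p-values are
   exceedance proportions with the +1 correction; significance is declared
   with Benjamini–Hochberg FDR control at 1% across frequency bins.
4. **IU duration statistics.** 50 ms-bin probability histograms pooled
   across speakers, median with a bootstrap 95% CI, and a robustness filter
   that keeps only IUs following an inter-IU interval below 1 s.
5. **Synthetic conversations.** A generator produces envelope (or audio)
   with known ground truth: ~5 Hz raised-cosine syllable bursts grouped
   into IUs of ~1 s, with IU-initial amplitude reset, final lengthening,
   amplitude decay, pauses, and several simultaneous speakers — used to
   validate the full pipeline.

## Worked example

```r
library(iurhythm)

cfg <- synth_config(duration_s = 300, n_speakers = 4)  # 1 s IU period, 5 Hz syllables
sim <- generate_envelope(cfg, seed = 1)
sim$env
#> <envelope 'synthetic'> 30000 values @ 100 Hz (300.00 s), normalization=unit_max

res <- permutation_test(sim$env, sim$ann, n_perm = 1000, seed = 2)
res
#> <permutation result> 4 speakers, 1000 surrogates, 20 bins
#>   significant bins (FDR 0.01): 0.5, 1, 1.5, 2 Hz

duration_stats(iu_durations(sim$ann), seed = 3)
#> <duration stats> n=1196, median 0.884 s (95% CI 0.860-0.903 s)
```

The group PPC spectrum peaks at the 1 Hz bin — the generator's IU
onset-to-onset period — with permutation p = 1/1001 (< 0.001), and the
significant band (0.5–2 Hz) sits below the syllable rate: the IU rhythm is
detected in the delta range, not as a harmonic of the 5 Hz syllabic
modulation. The duration median near 0.9 s matches the generator's IU
duration distribution.

For real recordings, start from `read_waveform()` + `compute_envelope()`
and `read_annotations()` (CSV with `onset_s, offset_s, speaker_id`, or
Praat TextGrid interval tiers, one tier per speaker).

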