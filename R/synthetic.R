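#' Configuration for the synthetic conversation generator
#'
#' Describes a simulated multi-speaker recording in which each speaker
#' produces a stream of Intonation Units (IUs): runs of syllable-scale
#' raised-cosine amplitude bursts, with an amplitude reset at the IU start,
#' lengthening of the final syllable, amplitude decay toward the IU end,
#' and silent inter-IU pauses.
#'
#' @param duration_s Recording duration in seconds (default 300).
#' @param n_speakers Number of simultaneous speakers (default 4).
#' @param syllable_rate_hz Average syllable rate within an IU, Hz
#'   (default 5; must lie in [2, 7], the range of strong amplitude
#'   modulations in speech).
#' @param syllables_per_iu Integer range `c(min, max)` from which the
#'   syllable count of each IU is drawn uniformly (default 3-7).
#' @param iu_period_s Target mean onset-to-onset interval between
#'   successive IUs of a speaker, seconds (default 1.0 — a ~1 Hz IU rhythm).
#' @param period_jitter_cv Coefficient of variation of the log-normal
#'   multiplicative jitter on the onset-to-onset interval (default 0.1).
#' @param final_lengthening Duration multiplier of an IU's last syllable
#'   relative to the others (default 1.5); the lengthening is accommodated
#'   within the IU, so the average syllable rate stays `syllable_rate_hz`.
#' @param amplitude_decay Peak-amplitude ratio of the last syllable to the
#'   first (default 0.7); intermediate syllables decay geometrically.
#' @param syllable_jitter_cv Coefficient of variation of the log-normal
#'   jitter on individual syllable durations and peak amplitudes
#'   (default 0.4). Spontaneous speech has substantial syllable-level
#'   variability; without it every IU would present an identical burst
#'   pattern and the envelope would carry artificial broadband structure.
#' @param pause_mean_s Mean of the exponential inter-IU pause distribution,
#'   seconds (default 0.2; 0 disables pauses).
#' @param pause_max_s Truncation point of the pause distribution (default
#'   2 s), keeping most inter-IU intervals below 1 s as in conversational
#'   speech.
#' @param noise_floor Constant envelope floor (default 0.005, relative to a
#'   unit burst peak before normalization).
#' @param env_rate_hz Sample rate of the generated envelope (default 100).
#' @param seed Optional integer seed stored in the config and used by the
#'   generators.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 300, n_speakers = 4,
                         syllable_rate_hz = 5.0, syllables_per_iu = c(3L, 7L),
                         iu_period_s = 1.0, period_jitter_cv = 0.1,
                         final_lengthening = 1.5, amplitude_decay = 0.7,
                         syllable_jitter_cv = 0.4,
                         pause_mean_s = 0.2, pause_max_s = 2.0,
                         noise_floor = 0.005, env_rate_hz = 100,
                         seed = NULL) {
  stopifnot(duration_s > 0, n_speakers >= 0,
            syllable_rate_hz >= 2, syllable_rate_hz <= 7,
            length(syllables_per_iu) == 2, syllables_per_iu[1] >= 1,
            syllables_per_iu[1] <= syllables_per_iu[2],
            period_jitter_cv >= 0, final_lengthening >= 1,
            amplitude_decay > 0, amplitude_decay <= 1,
            syllable_jitter_cv >= 0,
            pause_mean_s >= 0, noise_floor >= 0, env_rate_hz > 0)
  min_iu_s <- syllables_per_iu[1] / syllable_rate_hz
  if (iu_period_s < min_iu_s) {
    warning(sprintf(
      "iu_period_s (%g s) shorter than the shortest IU (%g s); extended",
      iu_period_s, min_iu_s))
    iu_period_s <- min_iu_s
  }
  structure(
    list(duration_s = duration_s, n_speakers = as.integer(n_speakers),
         syllable_rate_hz = syllable_rate_hz,
         syllables_per_iu = as.integer(syllables_per_iu),
         iu_period_s = iu_period_s, period_jitter_cv = period_jitter_cv,
         final_lengthening = final_lengthening,
         amplitude_decay = amplitude_decay,
         syllable_jitter_cv = syllable_jitter_cv,
         pause_mean_s = pause_mean_s, pause_max_s = pause_max_s,
         noise_floor = noise_floor, env_rate_hz = env_rate_hz, seed = seed),
    class = "synth_config"
  )
}

# Draw one speaker's IU schedule: data frame of onset, offset, syllable
# count. Intervals between onsets are iu_period_s times a log-normal jitter
# with unit mean; the drawn pause is shortened (and, if needed, the IU
# truncated) when the interval cannot accommodate both.
draw_iu_schedule <- function(cfg, t0) {
  sdlog <- sqrt(log(1 + cfg$period_jitter_cv^2))
  meanlog <- log(cfg$iu_period_s) - sdlog^2 / 2
  d_min <- cfg$syllables_per_iu[1] / cfg$syllable_rate_hz
  onset <- offset <- n_syll <- numeric(0)
  t <- t0
  repeat {
    iv <- stats::rlnorm(1, meanlog, sdlog)
    n <- sample(cfg$syllables_per_iu[1]:cfg$syllables_per_iu[2], 1)
    d_nom <- n / cfg$syllable_rate_hz
    p <- if (cfg$pause_mean_s > 0) {
      min(stats::rexp(1, 1 / cfg$pause_mean_s), cfg$pause_max_s)
    } else 0
    if (iv >= d_nom + p) {
      d <- d_nom
    } else if (iv >= d_nom) {
      d <- d_nom                       # pause squeezed to iv - d_nom
    } else if (iv >= d_min) {
      d <- iv                          # IU truncated to fill the interval
    } else {
      iv <- d_min                      # interval extended to fit a minimal IU
      d <- d_min
    }
    if (t + d > cfg$duration_s) break
    onset <- c(onset, t)
    offset <- c(offset, t + d)
    n_syll <- c(n_syll, n)
    t <- t + iv
  }
  data.frame(onset = onset, offset = offset, n_syll = n_syll)
}

# Add one IU's raised-cosine syllable bursts to the envelope accumulator.
# Base syllable duration is d = D / (n - 1 + final_lengthening); the last
# syllable lasts final_lengthening * d; peak amplitudes decay geometrically
# from 1 to amplitude_decay across the IU. Durations and amplitudes carry
# multiplicative log-normal jitter (syllable_jitter_cv); durations are
# rescaled so the IU still spans exactly dur.
add_iu_bursts <- function(acc, onset, dur, n, cfg) {
  rate <- cfg$env_rate_hz
  d_base <- dur / (n - 1 + cfg$final_lengthening)
  lens <- c(rep(d_base, n - 1), cfg$final_lengthening * d_base)
  amps <- if (n == 1) 1 else cfg$amplitude_decay^((seq_len(n) - 1) / (n - 1))
  if (cfg$syllable_jitter_cv > 0) {
    sdl <- sqrt(log(1 + cfg$syllable_jitter_cv^2))
    lens <- lens * stats::rlnorm(n, -sdl^2 / 2, sdl)
    lens <- lens * (dur / sum(lens))
    amps <- amps * stats::rlnorm(n, -sdl^2 / 2, sdl)
  }
  starts <- onset + c(0, cumsum(lens))[seq_len(n)]
  for (j in seq_len(n)) {
    i0 <- round(starts[j] * rate)
    i1 <- round((starts[j] + lens[j]) * rate)
    if (i1 <= i0) next
    idx <- (i0:(i1 - 1)) + 1L
    idx <- idx[idx >= 1 & idx <= length(acc)]
    ph <- ((idx - 1) / rate - starts[j]) / lens[j]
    acc[idx] <- acc[idx] + amps[j] * 0.5 * (1 - cos(2 * pi * ph))
  }
  acc
}

#' Generate a synthetic speech envelope with ground-truth IU annotations
#'
#' Lays down each speaker's IU onsets with onset-to-onset intervals of
#' `iu_period_s` times a unit-mean log-normal jitter; realizes each IU as a
#' run of raised-cosine syllable bursts (final syllable lengthened, peak
#' amplitudes decaying); sums all speakers' bursts onto a constant noise
#' floor; and normalizes the result to a maximum of 1.
#'
#' @param cfg A [synth_config()].
#' @param seed Optional integer seed (overrides `cfg$seed`).
#' @param recording_id Label for the generated recording.
#' @return A list with elements `env` (an [envelope_signal()]) and `ann`
#'   (the ground-truth [iu_annotation()]).
#' @export
generate_envelope <- function(cfg = synth_config(), seed = NULL,
                              recording_id = "synthetic") {
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed)) set.seed(seed)
  n_env <- round(cfg$duration_s * cfg$env_rate_hz)
  acc <- numeric(n_env)
  onsets <- offsets <- numeric(0)
  speakers <- character(0)
  for (s in seq_len(cfg$n_speakers)) {
    t0 <- stats::runif(1, 0, cfg$iu_period_s)
    sched <- draw_iu_schedule(cfg, t0)
    for (i in seq_len(nrow(sched))) {
      acc <- add_iu_bursts(acc, sched$onset[i],
                           sched$offset[i] - sched$onset[i],
                           sched$n_syll[i], cfg)
    }
    onsets <- c(onsets, sched$onset)
    offsets <- c(offsets, sched$offset)
    speakers <- c(speakers, rep(sprintf("S%02d", s), nrow(sched)))
  }
  acc <- acc + cfg$noise_floor
  m <- max(acc)
  if (m > 0) acc <- acc / m
  env <- envelope_signal(acc, cfg$env_rate_hz, recording_id, "unit_max")
  ord <- order(onsets)
  ann <- if (length(onsets)) {
    iu_annotation(onsets[ord], offsets[ord], speakers[ord], recording_id)
  } else {
    validate_annotation(data.frame(
      recording_id = character(0), speaker_id = character(0),
      onset_s = numeric(0), offset_s = numeric(0)))
  }
  list(env = env, ann = ann)
}

#' Generate synthetic audio realizing a designed envelope
#'
#' The designed envelope (from the same IU schedule as
#' [generate_envelope()]) amplitude-modulates band-limited noise in the
#' speech band (100-4000 Hz), so that [compute_envelope()] applied to the
#' audio recovers the designed envelope up to filter smoothing.
#'
#' @param cfg A [synth_config()].
#' @param audio_rate_hz Audio sample rate (default 16000).
#' @param seed Optional integer seed (overrides `cfg$seed`).
#' @param recording_id Label for the generated recording.
#' @return A list with `wave` (a [waveform()]), `env` (the designed
#'   [envelope_signal()]) and `ann` (the ground-truth [iu_annotation()]).
#' @export
generate_audio <- function(cfg = synth_config(), audio_rate_hz = 16000,
                           seed = NULL, recording_id = "synthetic") {
  seed <- if (!is.null(seed)) seed else cfg$seed
  if (!is.null(seed)) set.seed(seed)
  ge <- generate_envelope(cfg, seed = NULL, recording_id = recording_id)
  n_audio <- round(cfg$duration_s * audio_rate_hz)
  if (cfg$n_speakers == 0) {
    return(list(wave = waveform(numeric(n_audio), audio_rate_hz,
                                recording_id),
                env = ge$env, ann = ge$ann))
  }
  carrier <- fft_butterworth(stats::rnorm(n_audio), audio_rate_hz,
                             order = 4, f_lo = 100, f_hi = 4000)
  t_audio <- (seq_len(n_audio) - 1) / audio_rate_hz
  env_up <- stats::approx(envelope_times(ge$env), ge$env$values,
                          xout = t_audio, rule = 2)$y
  x <- carrier * env_up
  x <- 0.9 * x / max(abs(x))
  list(wave = waveform(x, audio_rate_hz, recording_id),
       env = ge$env, ann = ge$ann)
}

#' Null annotations: IU onsets placed at random envelope troughs
#'
#' Builds a complete-null annotation set for calibration of the permutation
#' test: each requested onset is a trough time drawn uniformly without
#' replacement (per speaker) from the envelope's troughs, so the observed
#' data satisfy the null hypothesis that IU onsets carry no rhythm beyond
#' their association with troughs.
#'
#' @param env An [envelope_signal()].
#' @param n_onsets Integer vector of onset counts, one per speaker; names
#'   are used as speaker labels (defaults `N01`, `N02`, ...).
#' @param iu_dur_s Nominal IU duration used for the offsets (0.5 s), clipped
#'   to the recording end.
#' @param min_magnitude,min_separation_s Trough parameters, see
#'   [detect_troughs()].
#' @param seed Optional integer seed.
#' @return An [iu_annotation()].
#' @export
null_annotation <- function(env, n_onsets, iu_dur_s = 0.5,
                            min_magnitude = 0.01, min_separation_s = 0.2,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- detect_troughs(env, min_magnitude, min_separation_s)
  k <- length(tr$times_s)
  if (k < max(n_onsets)) {
    stop("envelope has ", k, " troughs; cannot place ", max(n_onsets),
         " null onsets")
  }
  labs <- names(n_onsets)
  if (is.null(labs)) labs <- sprintf("N%02d", seq_along(n_onsets))
  dur_total <- length(env$values) / env$sample_rate_hz
  onset <- numeric(0)
  speaker <- character(0)
  for (i in seq_along(n_onsets)) {
    onset <- c(onset, sort(tr$times_s[sample.int(k, n_onsets[i])]))
    speaker <- c(speaker, rep(labs[i], n_onsets[i]))
  }
  offset <- pmin(onset + iu_dur_s, dur_total)
  ok <- offset > onset
  ord <- order(onset[ok])
  iu_annotation(onset[ok][ord], offset[ok][ord], speaker[ok][ord],
                env$recording_id)
}
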