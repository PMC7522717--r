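test_that("degenerate config gives a strictly periodic IU train", {
  cfg <- synth_config(duration_s = 60, n_speakers = 1, pause_mean_s = 0,
                      period_jitter_cv = 0)
  g <- generate_envelope(cfg, seed = 3)
  n <- nrow(g$ann)
  expect_true(n %in% c(59, 60))
  expect_equal(diff(g$ann$onset_s), rep(1, n - 1))
  expect_true(all(g$ann$offset_s > g$ann$onset_s))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(duration_s = 40, n_speakers = 2)
  g1 <- suppressMessages(generate_envelope(cfg, seed = 12))
  g2 <- suppressMessages(generate_envelope(cfg, seed = 12))
  expect_identical(g1$env$values, g2$env$values)
  expect_identical(g1$ann$onset_s, g2$ann$onset_s)

  a1 <- suppressMessages(generate_audio(
    synth_config(duration_s = 5, n_speakers = 1), seed = 12))
  a2 <- suppressMessages(generate_audio(
    synth_config(duration_s = 5, n_speakers = 1), seed = 12))
  expect_identical(a1$wave$samples, a2$wave$samples)
})

test_that("generated envelopes are unit-normalized with plausible structure", {
  g <- suppressMessages(generate_envelope(seed = 2))
  expect_equal(max(g$env$values), 1)
  expect_true(all(g$env$values >= 0))
  expect_length(g$env$values, 300 * 100)
  counts <- table(g$ann$speaker_id)
  expect_length(counts, 4)
  expect_true(all(counts > 5))
  # mean onset-to-onset interval per speaker tracks iu_period_s
  per_speaker <- sapply(split(g$ann$onset_s, g$ann$speaker_id),
                        function(o) mean(diff(o)))
  expect_true(all(abs(per_speaker - 1) < 0.1))
})

test_that("envelope spectrum has local maxima at the IU and syllable rates", {
  g <- suppressMessages(generate_envelope(seed = 5))
  v <- g$env$values - mean(g$env$values)
  p <- Mod(stats::fft(v))^2
  freqs <- (seq_along(v) - 1) / (length(v) / g$env$sample_rate_hz)
  bandpow <- function(lo, hi) mean(p[freqs >= lo & freqs <= hi])
  # syllable rate ~5 Hz: band power around 5 Hz exceeds both flanks
  expect_gt(bandpow(4, 6), bandpow(2.5, 3.5))
  expect_gt(bandpow(4, 6), bandpow(7.5, 8.5))
  # IU rhythm ~1 Hz: band power around 1 Hz exceeds the 1.5-3 Hz dip
  expect_gt(bandpow(0.6, 1.4), bandpow(1.6, 3))
})

test_that("annotated onsets coincide with a local envelope rise", {
  g <- generate_envelope(synth_config(duration_s = 60, n_speakers = 1),
                         seed = 7)
  rate <- g$env$sample_rate_hz
  rises <- sapply(g$ann$onset_s, function(on) {
    i0 <- round(on * rate) + 1
    i1 <- min(i0 + round(0.05 * rate), length(g$env$values))
    max(diff(g$env$values[i0:i1]))
  })
  expect_true(all(rises > 0))
})

test_that("audio realizes the designed envelope", {
  cfg <- synth_config(duration_s = 20, n_speakers = 2)
  a <- suppressMessages(generate_audio(cfg, seed = 9))
  env <- compute_envelope(a$wave, cochlear_band_edges(6, 100, 4000),
                          env_rate_hz = 100)
  expect_gt(stats::cor(env$values, a$env$values), 0.8)
  # syllable-rate modulation survives the acoustic round trip
  v <- env$values - mean(env$values)
  p <- Mod(stats::fft(v))^2
  freqs <- (seq_along(v) - 1) / (length(v) / 100)
  bandpow <- function(lo, hi) mean(p[freqs >= lo & freqs <= hi])
  expect_gt(bandpow(4, 6), bandpow(7.5, 8.5))
})

test_that("zero-speaker audio is silent", {
  cfg <- synth_config(duration_s = 2, n_speakers = 0)
  a <- generate_audio(cfg, seed = 1)
  expect_true(all(a$wave$samples == 0))
  expect_equal(nrow(a$ann), 0)
})

test_that("null annotations sit on troughs, uniformly and reproducibly", {
  g <- suppressMessages(generate_envelope(
    synth_config(duration_s = 120, n_speakers = 2), seed = 14))
  tr <- detect_troughs(g$env)
  k <- length(tr$times_s)

  ann_all <- null_annotation(g$env, k, seed = 2)
  expect_equal(ann_all$onset_s, tr$times_s)

  a1 <- null_annotation(g$env, c(A = 20, B = 30), seed = 3)
  a2 <- null_annotation(g$env, c(A = 20, B = 30), seed = 3)
  expect_identical(a1$onset_s, a2$onset_s)
  expect_equal(as.vector(table(a1$speaker_id)), c(20, 30))
  expect_true(all(a1$onset_s %in% tr$times_s))

  expect_error(null_annotation(g$env, k + 1), "troughs")
})
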