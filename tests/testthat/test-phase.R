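test_that("window extraction centers on onsets and drops boundary cases", {
  env <- envelope_signal(seq(0, 1, length.out = 1000), 100, "r")
  w <- extract_windows(env, 5.0, window_s = 2)
  expect_equal(nrow(w), 200)
  # [4.0, 6.0) s -> samples 401..600 of the ramp
  expect_equal(w[, 1], env$values[401:600])

  expect_message(w2 <- extract_windows(env, c(0.5, 5.0), window_s = 2),
                 "dropped")
  expect_equal(ncol(w2), 1)
  expect_equal(attr(w2, "n_dropped"), 1)
  expect_error(extract_windows(env, 0.5, window_s = 2), "no onset")

  w4 <- extract_windows(env, 5.0, window_s = 4)
  expect_equal(nrow(w4), 400)
})

test_that("frequency bins are spaced at exactly 1/window_s", {
  env <- envelope_signal(rep(c(0, 1), 500), 100, "r")
  w2 <- extract_windows(env, 5.0, window_s = 2)
  f2 <- attr(iurhythm:::unit_phase_matrix(w2, 2), "frequencies")
  expect_identical(diff(f2), rep(0.5, length(f2) - 1))
  expect_identical(f2[1], 0.5)        # DC excluded
  w4 <- extract_windows(env, 5.0, window_s = 4)
  f4 <- attr(iurhythm:::unit_phase_matrix(w4, 4), "frequencies")
  expect_identical(diff(f4), rep(0.25, length(f4) - 1))
  expect_identical(f4[1], 0.25)
})

test_that("window phases match a direct tapered DFT oracle", {
  t <- seq(0, 2 - 0.01, by = 0.01)
  for (case in list(list(x = cos(2 * pi * t), expected = 0),
                    list(x = sin(2 * pi * t), expected = -pi / 2))) {
    ph <- window_phases(case$x, 2)
    got <- ph$phase_rad[ph$frequency_hz == 1]
    expect_equal(got, case$expected, tolerance = 0.01)
    # oracle: demean, symmetric Hann, direct DFT sum at bin k = 2
    x <- case$x - mean(case$x)
    n <- length(x)
    x <- x * 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    expect_lt(abs(got - Arg(dft_bin(x, 2))), 1e-12)
  }
})

test_that("constant windows have undefined phases everywhere", {
  ph <- window_phases(rep(0.7, 200), 2)
  expect_true(all(is.na(ph$phase_rad)))
})

test_that("PPC matches brute-force pairwise sums and known values", {
  expect_equal(ppc(c(0, pi / 2, pi)), -1 / 3)
  expect_equal(ppc(rep(1.2, 17)), 1)
  expect_error(ppc(0.5), "at least 2")

  set.seed(7)
  for (i in 1:50) {
    n <- sample(2:200, 1)
    a <- runif(n, -pi, pi)
    expect_equal(ppc(a), ppc_bruteforce(a), tolerance = 1e-10)
  }
})

test_that("PPC is near zero under uniform phases, independent of N", {
  set.seed(11)
  m10 <- mean(replicate(2000, ppc(runif(10, -pi, pi))))
  m100 <- mean(replicate(2000, ppc(runif(100, -pi, pi))))
  expect_lt(abs(m10), 0.01)
  expect_lt(abs(m100), 0.01)
  expect_lt(abs(m10 - m100), 0.015)
})

test_that("speakers need strictly more than min_events retained onsets", {
  env <- make_periodic_envelope(30)
  on5 <- seq(2, 10, by = 2)
  on6 <- seq(2, 12, by = 2)
  ann <- iu_annotation(c(on5, on6), c(on5, on6) + 0.5,
                       rep(c("p5", "p6"), c(5, 6)), "periodic")
  expect_error(speaker_spectrum(env, ann, "p5"), "excluded")
  sp <- speaker_spectrum(env, ann, "p6")
  expect_equal(sp$n_events, 6)
  expect_true(all(sp$ppc >= -1 & sp$ppc <= 1))
})

test_that("strictly periodic onsets maximize consistency at their rate", {
  env <- make_periodic_envelope(120, period_s = 1)
  onsets <- seq(2, 117, by = 1)
  ann <- iu_annotation(onsets, onsets + 0.5, "S", "periodic")
  sp <- speaker_spectrum(env, ann, "S")
  p1 <- sp$ppc[sp$frequency_hz == 1]
  others <- sp$ppc[sp$frequency_hz >= 2.5 & sp$frequency_hz <= 5 &
                     abs(sp$frequency_hz %% 1) > 1e-9]
  expect_true(all(p1 > others))
})

test_that("group spectra average speakers and degenerate CIs collapse", {
  env <- make_periodic_envelope(60)
  onsets <- seq(2, 57, by = 1)
  ann <- iu_annotation(onsets, onsets + 0.5, "S", "periodic")
  sp <- speaker_spectrum(env, ann, "S")

  g1 <- group_spectrum(list(sp), n_boot = 100, seed = 1)
  expect_equal(g1$mean_ppc, sp$ppc)
  expect_equal(g1$ci_low, sp$ppc)
  expect_equal(g1$ci_high, sp$ppc)

  g2 <- group_spectrum(list(sp, sp), n_boot = 100, seed = 1)
  expect_equal(g2$ci_high - g2$ci_low, rep(0, length(sp$ppc)))

  sp2 <- sp
  sp2$frequency_hz <- sp$frequency_hz + 0.1
  expect_error(group_spectrum(list(sp, sp2)), "frequency grid")
})

test_that("bootstrap CI of the group mean has near-nominal coverage", {
  set.seed(23)
  mu <- 0.3
  hits <- replicate(200, {
    vals <- rnorm(20, mu, 0.15)
    spectra <- lapply(vals, function(v) {
      structure(list(frequency_hz = 1, ppc = v, n_events = 10L,
                     speaker_id = "x", recording_id = "r", window_s = 2),
                class = "consistency_spectrum")
    })
    g <- group_spectrum(spectra, n_boot = 300)
    g$ci_low <= mu && mu <= g$ci_high
  })
  expect_gte(mean(hits), 0.88)
})

test_that("windows with overlapping speech from other speakers are retained", {
  env <- make_periodic_envelope(60)
  on_a <- seq(2, 50, by = 2)
  on_b <- on_a + 0.3  # B speaks inside A's windows
  ann <- iu_annotation(c(on_a, on_b), c(on_a, on_b) + 0.4,
                       rep(c("A", "B"), each = length(on_a)), "periodic")
  sp <- speaker_spectrum(env, ann, "A")
  expect_equal(sp$n_events, length(on_a))
})
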