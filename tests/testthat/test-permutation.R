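test_that("cosine envelope troughs are enumerated and all retained", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  env <- envelope_signal(0.5 * (1 + cos(2 * pi * 5 * t)), 100, "cos5")
  tr <- detect_troughs(env)
  # oracle: direct enumeration of strict interior sign changes
  x <- env$values
  oracle <- which(diff(x)[-(length(x) - 1)] < 0 & diff(x)[-1] > 0) + 1
  expect_equal(tr$indices, oracle)
  expect_length(tr$times_s, 50)
  expect_equal(tr$times_s, seq(0.1, 9.9, by = 0.2))
  # spacing sits exactly at the 200 ms separation bound; none removed
  expect_equal(diff(tr$times_s), rep(0.2, 49))
})

test_that("constant envelopes have no troughs", {
  env <- envelope_signal(rep(0.4, 500), 100, "flat")
  expect_length(detect_troughs(env)$times_s, 0)
})

test_that("thinning keeps the deeper of two close troughs", {
  # two minima 0.15 s apart with depths 0.3 and 0.2 below their saddles
  v <- rep(0.5, 100)
  v[30] <- 0.2   # deeper (prominence 0.3)
  v[45] <- 0.3   # shallower (prominence 0.2), 0.15 s away
  env <- envelope_signal(v, 100, "two")
  tr <- detect_troughs(env)
  expect_equal(tr$indices, 30)
})

test_that("shallow ripples below the magnitude threshold are ignored", {
  t <- seq(0, 5 - 0.01, by = 0.01)
  v <- 0.5 + 0.004 * cos(2 * pi * 3 * t)  # prominence 0.008 < 0.01
  env <- envelope_signal(v, 100, "ripple")
  expect_length(detect_troughs(env)$times_s, 0)
})

test_that("surrogate onsets are exhaustive, deterministic, and uniform", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  env <- envelope_signal(0.5 * (1 + cos(2 * pi * 5 * t)), 100, "cos5")
  tr <- detect_troughs(env)
  k <- length(tr$times_s)

  expect_equal(surrogate_onsets(tr, k, seed = 1), tr$times_s)
  expect_identical(surrogate_onsets(tr, 10, seed = 5),
                   surrogate_onsets(tr, 10, seed = 5))
  expect_error(surrogate_onsets(tr, k + 3), "short by 3")

  set.seed(9)
  draws <- replicate(10000, surrogate_onsets(tr, 1)) # single-trough draws
  freq <- table(factor(draws, levels = tr$times_s)) / 10000
  expect_true(all(abs(freq - 1 / k) < 0.01))
})

test_that("BH step-up rule matches hand evaluation", {
  # thresholds at q = 0.01 over 3 bins: 0.00333, 0.00667, 0.01
  expect_identical(bh_fdr(c(0.001, 0.02, 0.5), 0.01),
                   c(TRUE, FALSE, FALSE))
  expect_identical(bh_fdr(rep(1, 5), 0.01), rep(FALSE, 5))
  expect_identical(bh_fdr(rep(0.01 / 4, 4), 0.01), rep(TRUE, 4))
  expect_identical(bh_fdr(numeric(0), 0.01), logical(0))
})

test_that("permutation p-values use the +1 exceedance correction", {
  g <- suppressMessages(generate_envelope(
    synth_config(duration_s = 80, n_speakers = 2), seed = 4))
  pr <- suppressMessages(
    permutation_test(g$env, g$ann, n_perm = 50, seed = 1))
  expect_true(all(pr$p_value >= 1 / 51))
  expect_true(all(pr$p_value <= 1))
  r <- colSums(sweep(pr$surrogate_means, 2, pr$observed_mean_ppc, `>=`))
  expect_equal(pr$p_value, (r + 1) / 51)
  expect_identical(pr$significant, bh_fdr(pr$p_value, 0.01))
})

test_that("observed and surrogate analyses use identical speakers", {
  g <- suppressMessages(generate_envelope(
    synth_config(duration_s = 60, n_speakers = 2), seed = 6))
  # a speaker with too few IUs must be excluded from both sides
  extra <- iu_annotation(c(10, 20, 30), c(10.5, 20.5, 30.5), "tiny",
                         g$env$recording_id)
  ann <- validate_annotation(rbind(as.data.frame(g$ann),
                                   as.data.frame(extra)))
  pr <- suppressMessages(
    permutation_test(g$env, ann, n_perm = 20, seed = 1))
  expect_true(any(grepl("tiny", pr$excluded_speakers)))
  expect_equal(pr$n_speakers, 2)
})

test_that("more permutations refine p but leave the observed statistic fixed", {
  g <- suppressMessages(generate_envelope(
    synth_config(duration_s = 60, n_speakers = 2), seed = 8))
  pr1 <- suppressMessages(permutation_test(g$env, g$ann, n_perm = 20,
                                           seed = 1))
  pr2 <- suppressMessages(permutation_test(g$env, g$ann, n_perm = 100,
                                           seed = 2))
  expect_identical(pr1$observed_mean_ppc, pr2$observed_mean_ppc)
})
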