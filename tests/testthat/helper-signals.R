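# Shared fixtures, all built in code.

# Pure (optionally amplitude-modulated) tone as a waveform.
make_tone <- function(freq_hz, dur_s = 2, rate = 16000, am_hz = NULL,
                      amp = 0.5) {
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  x <- amp * sin(2 * pi * freq_hz * t)
  if (!is.null(am_hz)) x <- x * 0.5 * (1 + sin(2 * pi * am_hz * t))
  waveform(x, rate, "tone")
}

# Envelope with strictly periodic structure: raised-cosine bumps every
# period_s seconds, plus measurement noise so that bins without signal
# power carry random phases (a noise-free periodic envelope would make
# every window identical and consistency trivially 1 at every bin).
make_periodic_envelope <- function(dur_s = 60, period_s = 1, rate = 100,
                                   bump_s = 0.3, noise_sd = 0.05,
                                   seed = 101) {
  set.seed(seed)
  t <- seq(0, dur_s - 1 / rate, by = 1 / rate)
  ph <- (t %% period_s) / bump_s
  v <- ifelse(ph < 1, 0.5 * (1 - cos(2 * pi * ph)), 0)
  v <- pmax(v + stats::rnorm(length(v), 0, noise_sd), 0)
  envelope_signal(v + 0.005, rate, "periodic", "none")
}

# Independent brute-force PPC: mean cosine of the angular difference over
# all distinct pairs.
ppc_bruteforce <- function(angles) {
  n <- length(angles)
  s <- 0
  for (j in seq_len(n - 1)) {
    s <- s + sum(cos(angles[j] - angles[(j + 1):n]))
  }
  2 * s / (n * (n - 1))
}

# Independent direct DFT at one bin: sum_j x_j exp(-2 pi i j k / n).
dft_bin <- function(x, k) {
  n <- length(x)
  j <- 0:(n - 1)
  sum(x * exp(-2i * pi * j * k / n))
}
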