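test_that("zero-phase high-pass rejects DC without edge transients", {
  y <- zero_phase_filter(rep(5, 2000), 2000, "highpass", 100, 3)
  core <- y[100:1900]
  expect_lt(max(abs(core)), 1e-3 * 5)
})

test_that("two-pass low-pass matches the squared Butterworth response", {
  sr <- 50000
  t <- (0:(sr / 2)) / sr
  x <- sin(2 * pi * 1000 * t)
  y <- zero_phase_filter(x, sr, "lowpass", 2000, 3)
  # |H(f)|^2 of a 3rd-order Butterworth at f/fc = 0.5, applied twice
  gain_expected <- 1 / (1 + (1000 / 2000)^(2 * 3))
  core <- seq(2000, length(x) - 2000)
  gain_measured <- sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2))
  expect_equal(gain_measured, gain_expected, tolerance = 0.02)
})

test_that("zero-phase filtering commutes with time reversal", {
  set.seed(42)
  x <- cumsum(rnorm(3000))
  sr <- 1000
  y1 <- zero_phase_filter(x, sr, "lowpass", 100, 3)
  y2 <- rev(zero_phase_filter(rev(x), sr, "lowpass", 100, 3))
  core <- 200:2800
  expect_lt(max(abs(y1[core] - y2[core])), 1e-6 * max(abs(x)))
})

test_that("too-short inputs are rejected, not truncated", {
  expect_error(zero_phase_filter(rnorm(10), 1000, "lowpass", 100, 3),
               "too short")
})

test_that("bin_rms matches brute-force enumeration and known values", {
  expect_equal(as.numeric(bin_rms(rep(3, 1000), 1000, 0.01, 0.005)),
               rep(3, bin_count(1000, 10, 5)))
  # unit sine, whole cycles per bin
  sr <- 50000
  x <- sin(2 * pi * 500 * (0:(sr / 10)) / sr)
  r <- bin_rms(x, sr, 0.002, 0.001)  # 2 ms = one full cycle at 500 Hz
  expect_true(all(abs(r - 1 / sqrt(2)) < 1e-3))
  # count formula vs brute force, incl. the 50k/100/50 case
  for (p in list(c(50000, 100, 50), c(997, 40, 13), c(100, 100, 1))) {
    n <- p[1]; w <- p[2]; h <- p[3]
    brute <- 0L
    k <- 0L
    while (k * h + w <= n) { brute <- brute + 1L; k <- k + 1L }
    expect_identical(bin_count(n, w, h), brute)
  }
  expect_identical(bin_count(50000, 100, 50), 999L)
  # sign-flip invariance
  set.seed(7)
  z <- rnorm(500)
  expect_equal(as.numeric(bin_rms(z, 1000, 0.01, 0.005)),
               as.numeric(bin_rms(-z, 1000, 0.01, 0.005)))
  expect_warning(bin_rms(rnorm(5), 1000, 0.01, 0.005), "shorter")
})

test_that("assembled features share one grid and satisfy p_t identity", {
  f <- small_run()$analysis$features
  expect_equal(f$p_t, f$p_b - f$p_icas)
  hops <- diff(f$bin_center_t)
  expect_true(all(abs(hops - attr(f, "hop")) < 1e-9))
})

test_that("silence yields noise-floor RMS and no f_o; ramps rise monotonically", {
  run <- small_run()
  f <- run$analysis$features
  quiet <- f$p_b < 0.05 & f$p_icas < 0.05
  expect_lt(stats::median(f$rms_sound[quiet]), 3e-5)  # noise_rms = 1e-5
  expect_true(all(is.na(f$f_o[quiet])))
  segs <- run$analysis$segments
  for (i in seq_len(nrow(segs))) {
    # interior of the ramp: the last bins straddle the drop back to zero
    pb <- f$p_b[segs$start_bin[i]:(segs$end_bin[i] - 3L)]
    # monotone within one bin's worth of ramp (plus sensor noise)
    expect_true(all(diff(pb) > -0.005))
  }
})

test_that("filtering then binning a zero signal yields exactly zero features", {
  sr <- 20000
  rec <- multichannel_recording(rep(0, sr), rep(0, sr), rep(0, sr),
                                rep(0, sr), sr)
  f <- assemble_features(rec)
  expect_true(all(f$rms_sound == 0))
  expect_true(all(f$p_t == 0))
  expect_true(all(is.na(f$f_o)))
})
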