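test_that("ramp segmentation recovers the protocol structure", {
  run <- small_run()
  segs <- run$analysis$segments
  expect_equal(nrow(segs), length(run$protocol$picas_levels))
  expect_equal(sort(segs$picas_setpoint), sort(run$protocol$picas_levels),
               tolerance = 0.03)
  expect_equal(segs$ramp_rate_est, rep(run$protocol$ramp_rate, nrow(segs)),
               tolerance = 0.05)
  # protocol hint with wrong ramp count is a hard error
  bad <- small_protocol()
  bad$picas_levels <- c(bad$picas_levels, 2.0)
  expect_error(segment_ramps(run$analysis$features, bad), "segmentation")
})

test_that("an all-silence recording yields no segments", {
  sr <- 20000
  rec <- multichannel_recording(rnorm(sr, 0, 1e-5), rnorm(sr, 0, 1e-3),
                                rnorm(sr, 0, 1e-3), rep(0, sr), sr)
  f <- assemble_features(rec)
  expect_equal(nrow(segment_ramps(f)), 0L)
})

test_that("PTP detection reads the crossing bin and is threshold-monotone", {
  run <- small_run()
  f <- run$analysis$features
  segs <- run$analysis$segments
  th <- run$analysis$threshold
  seg <- segs[which.max(segs$picas_setpoint), ]  # onset above ptp_b
  p <- detect_ptp(seg, f, th)
  expect_true(p$phonated)
  # 1.5 kPa setpoint: onset where p_t reaches 0.15, i.e. p_b = 1.65
  expect_equal(p$ptp_b, 1.65, tolerance = 0.01 / 1.65)
  expect_equal(p$ptp_t, p$ptp_b - p$ptp_icas)
  # onset bin never moves earlier as the threshold rises
  ths <- th * c(1, 2, 5, 20, 100)
  onsets <- vapply(ths, function(tt) detect_ptp(seg, f, tt)$onset_bin,
                   integer(1))
  expect_true(all(diff(onsets) >= 0))
  # sub-threshold ramp reports no phonation
  quiet_seg <- segs[which.min(segs$picas_setpoint), ]  # p_icas = 0 ramp
  expect_false(detect_ptp(quiet_seg, f, th)$phonated)
})

test_that("run summaries aggregate onsets as means and boundaries as minima", {
  mk <- function(phonated, pb = NA, picas = NA, f0 = NA)
    structure(list(phonated = phonated, ptp_b = pb, ptp_icas = picas,
                   ptp_t = pb - picas, onset_bin = 1L, onset_f0 = f0),
              class = "ptp_result")
  f <- small_run()$analysis$features
  segs <- small_run()$analysis$segments[1:2, ]
  th <- small_run()$analysis$threshold
  ptps <- list(mk(TRUE, 1.2, 0.5, 480), mk(TRUE, 1.0, 0.7, 520))
  s <- summarize_run(ptps, f, segs, th)
  expect_equal(s$minimal_f0, 500)  # mean of onsets
  expect_equal(s$ptp_b, 1.0)      # boundary minimum
  expect_equal(s$ptp_icas_min, 0.5)
  expect_equal(s$n_phonating_ramps, 2L)
  # single phonating ramp: minimal f_o is its onset f_o
  s1 <- summarize_run(list(mk(TRUE, 1.0, 0.5, 511), mk(FALSE)), f, segs, th)
  expect_equal(s1$minimal_f0, 511)
  expect_message(
    s0 <- summarize_run(list(mk(FALSE), mk(FALSE)), f, segs, th),
    "no phonating")
  expect_true(is.na(s0$minimal_f0))
  expect_equal(s0$n_phonating_ramps, 0L)
})

test_that("full-run summary recovers the preset ground truth", {
  run <- small_run()
  gt <- ground_truth(syrinx_preset(), run$protocol)
  s <- run$analysis$summary
  expect_equal(s$minimal_f0, gt$minimal_f0, tolerance = 10 / gt$minimal_f0)
  expect_equal(s$ptp_b, gt$ptp_b, tolerance = 0.01 / gt$ptp_b)
  expect_equal(s$ptp_t_min, gt$ptp_t_min, tolerance = 0.05)
  expect_equal(s$minimal_SL, gt$minimal_SL, tolerance = 1 / gt$minimal_SL)
})

test_that("control-space maps conserve counts and degrade gracefully", {
  run <- small_run()
  f <- run$analysis$features
  segs <- run$analysis$segments
  th <- run$analysis$threshold
  cfg <- pipeline_config()
  m <- build_map(f, segs, "f_o", th, cfg = cfg)
  # counts sum to the number of steady phonating bins with data
  mask <- phonating_mask(f, th, cfg$ptp$guard_bins)$steady
  in_seg <- rep(FALSE, nrow(f))
  for (i in seq_len(nrow(segs)))
    in_seg[segs$start_bin[i]:segs$end_bin[i]] <- TRUE
  expect_equal(sum(m$count), sum(mask & in_seg & !is.na(f$f_o)))
  # one giant cell reproduces the global mean
  g <- build_map(f, segs, "f_o", th, pb_step = 10, picas_step = 10,
                 cfg = cfg)
  expect_equal(sum(g$count > 0), 1L)
  expect_equal(g$mean[g$count > 0],
               mean(f$f_o[mask & in_seg], na.rm = TRUE))
  # cells without data are missing, not zero
  expect_true(all(is.na(m$mean[m$count == 0])))
  expect_error(build_map(f, segs, "f_o", th, pb_step = -1, cfg = cfg),
               "> 0")
  expect_error(build_map(f, segs, "nope", th, cfg = cfg), "unknown feature")
})

test_that("f_o increases toward lower p_icas at fixed p_b (p_t direction)", {
  run <- small_run()
  m <- run$analysis$maps$f_o
  # within each p_b row, mean f_o must not increase with p_icas
  for (i in seq_len(nrow(m$mean))) {
    v <- m$mean[i, ]
    v <- v[!is.na(v)]
    if (length(v) >= 2) expect_true(all(diff(v) < 0))
  }
})
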