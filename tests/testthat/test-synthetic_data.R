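test_that("protocols are seeded permutations of the level grid", {
  p <- make_protocol()
  expect_length(p$picas_levels, 13L)
  expect_equal(sort(p$picas_levels), seq(0, 3, by = 0.25))
  expect_equal(diff(sort(p$picas_levels)), rep(0.25, 12))
  expect_identical(make_protocol(seed = 42)$picas_levels,
                   make_protocol(seed = 42)$picas_levels)
  expect_false(identical(make_protocol(seed = 1)$picas_levels,
                         make_protocol(seed = 2)$picas_levels))
  # the 0.23 kPa spacing variant and the single-ramp degenerate case
  p23 <- make_protocol(picas_spacing = 0.23)
  expect_equal(diff(sort(p23$picas_levels)), rep(0.23, 12))
  expect_length(make_protocol(picas_levels = 0)$picas_levels, 1L)
  expect_error(make_protocol(picas_levels = -1), ">= 0")
})

test_that("the simulator is bit-reproducible under a fixed seed", {
  prot <- make_protocol(picas_levels = c(1.0), pause_s = 0.2,
                        lead_in_s = 0.2, sample_rate = 20000, seed = 5)
  a <- simulate_run(syrinx_preset(), prot, seed = 7)
  b <- simulate_run(syrinx_preset(), prot, seed = 7)
  expect_identical(a$sound, b$sound)
  expect_identical(a$p_b, b$p_b)
  expect_identical(a$flow, b$flow)
  c <- simulate_run(syrinx_preset(), prot, seed = 8)
  expect_false(identical(a$sound, c$sound))
})

test_that("generated f_o is continuous at the breakpoint and monotone in p_t", {
  pre <- syrinx_preset()
  eps <- 1e-9
  expect_lt(abs(syrinxspace:::f0_of_pt(pre$breakpoint + eps, pre) -
                syrinxspace:::f0_of_pt(pre$breakpoint - eps, pre)), 1e-3)
  expect_equal(syrinxspace:::f0_of_pt(pre$ptp_t, pre), pre$f_min)
  pts <- seq(pre$ptp_t, pre$pt_max, by = 0.01)
  expect_true(all(diff(syrinxspace:::f0_of_pt(pts, pre)) > 0))
  # measured per-bin f_o through a ramp never jumps between bins
  run <- small_run()
  f <- run$analysis$features
  seg <- run$analysis$segments[
    which.max(run$analysis$segments$picas_setpoint), ]
  idx <- seg$start_bin:seg$end_bin
  tr <- f$f_o[idx]
  ok <- which(!is.na(tr))
  ok <- ok[seq(30, length(ok) - 10)]  # steady phonation interior
  steps <- diff(tr[ok])
  expect_lt(max(abs(steps)), 1.5)
  # monotone in p_t (rank correlation: the relation is piecewise linear,
  # with a slope change at the 0.75 kPa breakpoint)
  expect_gt(stats::cor(f$p_t[idx][ok], tr[ok], method = "spearman"), 0.99)
})

test_that("noiseless onset detection recovers the programmed pressure", {
  pre <- syrinx_preset(ptp_b = 1.00, ptp_icas = 0.2, ptp_t = 0.05,
                       noise_rms = 0, pressure_noise = 0, flow_noise = 0)
  prot <- make_protocol(picas_levels = 0.5, pause_s = 0.3, lead_in_s = 0.3,
                        sample_rate = 20000, seed = 2)
  rec <- simulate_run(pre, prot, seed = 1)
  cfg <- pipeline_config()
  f <- assemble_features(rec, cfg)
  seg <- segment_ramps(f, cfg = cfg)
  p <- detect_ptp(seg[1, ], f, detection_threshold(f, cfg))
  expect_true(p$phonated)
  # resolution limit: 1 kPa/s ramp, 1 ms hop
  expect_equal(p$ptp_b, 1.00, tolerance = 0.0015)
})

test_that("phonation stays inside the programmed pressure region", {
  run <- small_run()
  f <- run$analysis$features
  pre <- syrinx_preset()
  mask <- phonating_mask(f, run$analysis$threshold)$raw
  tol <- 0.02
  expect_true(all(f$p_t[mask] >= pre$ptp_t - tol))
  expect_true(all(f$p_t[mask] <= pre$pt_max + tol))
  expect_true(all(f$p_b[mask] >= pre$ptp_b - tol))
  expect_true(all(f$p_icas[mask] >= pre$ptp_icas - tol))
})

test_that("ground truth reports the preset's defining quantities", {
  pre <- syrinx_preset()
  prot <- make_protocol(seed = 4)
  gt <- ground_truth(pre, prot)
  expect_equal(gt$ptp_t_min, pre$ptp_t)
  expect_equal(gt$s1, pre$s1)
  expect_equal(gt$f_min, pre$f_min)
  # a ramp onsets exactly at ptp_b, so the boundary and minimal SL anchor
  expect_equal(gt$ptp_b, pre$ptp_b)
  expect_equal(gt$minimal_SL, pre$sl_min)
  # ramps below the air-sac threshold or topping out never phonate
  expect_equal(gt$n_phonating_ramps,
               sum(prot$picas_levels >= pre$ptp_icas &
                   pmax(pre$ptp_b, prot$picas_levels + pre$ptp_t) <=
                     prot$pb_max))
  expect_error(syrinx_preset("no-such-preset"), "unknown preset")
})

test_that("report_table produces one tidy row per run and metric", {
  run <- small_run()
  meta <- data.frame(subject_id = c("b1", "b1"), side = c("left", "right"),
                     sex = "male", age_dph = 100L)
  tab <- report_table(list(run$analysis, run$analysis), meta)
  expect_equal(nrow(tab), 2 * 7)
  expect_equal(sum(tab$metric == "minimal_f0"), 2L)
  meta_dup <- meta
  meta_dup$side <- "left"
  expect_error(report_table(list(run$analysis, run$analysis), meta_dup),
               "duplicate")
  empty <- report_table(list(), meta[0, ])
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("subject_id", "metric", "value") %in% names(empty)))
})

test_that("config files round trip and reject unknown keys", {
  path <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("bin_width: 0.004", "hop: 0.002",
               "ptp:", "  guard_bins: 5"), path)
  cfg <- read_config(path)
  expect_equal(cfg$bin_width, 0.004)
  expect_equal(cfg$ptp$guard_bins, 5)
  expect_equal(cfg$ptp$absolute_floor, 0.25e-3)  # untouched default
  writeLines("bogus_key: 1", path)
  expect_error(read_config(path), "unknown config key")
  writeLines(c("ptp:", "  bogus: 2"), path)
  expect_error(read_config(path), "unknown config key")
  unlink(path)
  # a wider bin shrinks the feature table per the count formula
  rec <- small_run()$recording
  n <- length(rec$sound)
  f4 <- assemble_features(rec, pipeline_config(bin_width = 0.004,
                                               hop = 0.002))
  expect_equal(nrow(f4), bin_count(n, round(0.004 * rec$sample_rate),
                                   round(0.002 * rec$sample_rate)))
})
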