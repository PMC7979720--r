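#' Ground-truth parameter set for the forward hemi-syrinx simulator
#'
#' Defaults are the adult cohort means for the in vitro preparation:
#' phonation thresholds `ptp_b` = 1.01 kPa, `ptp_icas` = 0.45 kPa,
#' `ptp_t` = 0.15 kPa; piecewise f_o slopes 189 and 55 Hz/kPa around a
#' 0.75 kPa breakpoint; minimal source level 45 dB re 20 uPa at 1 m with a
#' 4 dB/kPa (left) or 5 dB/kPa (right) rise in bronchial pressure. Named
#' presets set the side-specific minimal f_o (left male 511 Hz, right male
#' 513 Hz, left female 529 Hz, right female 568 Hz). `aspiration_db` (the
#' turbulence-noise level of the voiced source relative to its total RMS)
#' and `flow_conductance` are calibrated once so the full pipeline reports
#' a Wiener entropy near -1.8 dB and a mean mechanical efficiency near
#' -35 dB on the default preset; `harmonic_rolloff` sets the source
#' spectral slope (6 dB per partial, a typical voiced-source decay).
#'
#' @param name Preset name: `"adult-male-left"`, `"adult-male-right"`,
#'   `"adult-female-left"`, `"adult-female-right"`.
#' @param ... Field overrides (see Details for the full list).
#' @return A `syrinx_preset` list.
#' @export
syrinx_preset <- function(name = "adult-male-left", ...) {
  presets <- list(
    "adult-male-left"    = list(f_min = 511, sl_slope = 4, side = "left",
                                sex = "male"),
    "adult-male-right"   = list(f_min = 513, sl_slope = 5, side = "right",
                                sex = "male"),
    "adult-female-left"  = list(f_min = 529, sl_slope = 4, side = "left",
                                sex = "female"),
    "adult-female-right" = list(f_min = 568, sl_slope = 5, side = "right",
                                sex = "female"))
  if (!name %in% names(presets))
    stop("unknown preset: ", name, " (available: ",
         paste(names(presets), collapse = ", "), ")")
  base <- list(
    name = name,
    ptp_b = 1.01, ptp_icas = 0.45, ptp_t = 0.15,
    s1 = 189, s2 = 55, breakpoint = 0.75, pt_max = 2.0,
    sl_min = 45,
    harmonic_count = 8L, harmonic_rolloff = 6, aspiration_db = -54,
    flow_conductance = 8.0e-7, leak_fraction = 0.02,
    noise_rms = 1e-5, pressure_noise = 0.002, flow_noise = 1e-9,
    amp_ramp_s = 0.005)
  p <- utils::modifyList(c(base, presets[[name]]), list(...))
  stopifnot(p$f_min > 0, p$ptp_b > p$ptp_t, p$ptp_t >= 0,
            is.finite(p$s1), is.finite(p$s2), p$harmonic_count >= 1)
  structure(p, class = "syrinx_preset")
}

#' Ramp protocol for one run
#'
#' One run applies a bronchial-pressure ramp 0 to `pb_max` kPa at
#' `ramp_rate` kPa/s for each air-sac setpoint, in a seeded random order,
#' with silent pauses (both pressures 0) between ramps and a silent lead-in
#' used for noise-floor estimation. The default grid is 13 equidistant
#' levels spanning 0-3 kPa (0.25 kPa spacing); `picas_spacing = 0.23`
#' reproduces a 0.23 kPa grid instead.
#'
#' @param ramp_rate Ramp rate (kPa/s).
#' @param pb_max Ramp top (kPa).
#' @param picas_levels Air-sac setpoints (kPa); overrides the grid.
#' @param n_levels Number of grid levels when `picas_levels` is `NULL`.
#' @param picas_spacing Grid spacing (kPa); `NULL` spans `0..pb_max`
#'   equidistantly.
#' @param pause_s Pause between ramps (s).
#' @param lead_in_s Silent lead-in (s).
#' @param sample_rate Sample rate (Hz); 50 kHz default, 20 kHz is the usual
#'   fast profile.
#' @param seed Seed for the level-order permutation.
#' @return A `ramp_protocol` list.
#' @export
make_protocol <- function(ramp_rate = 1.0, pb_max = 3.0,
                          picas_levels = NULL, n_levels = 13L,
                          picas_spacing = NULL, pause_s = 2.0,
                          lead_in_s = 1.0, sample_rate = 50000,
                          seed = 1L) {
  stopifnot(ramp_rate > 0, pb_max > 0, pause_s >= 0, lead_in_s >= 0,
            sample_rate > 0)
  if (is.null(picas_levels)) {
    picas_levels <- if (is.null(picas_spacing))
      seq(0, pb_max, length.out = n_levels)
    else seq(0, by = picas_spacing, length.out = n_levels)
  }
  if (!length(picas_levels) || any(picas_levels < 0))
    stop("picas_levels must be non-empty and >= 0")
  old <- .Random.seed_exists()  # keep caller RNG state untouched
  set.seed(seed)
  perm <- sample.int(length(picas_levels))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(ramp_rate = ramp_rate, pb_max = pb_max,
                 picas_levels = picas_levels[perm],
                 pause_s = pause_s, lead_in_s = lead_in_s,
                 sample_rate = sample_rate, order_seed = seed),
            class = "ramp_protocol")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

# piecewise-linear f_o(p_t), anchored so f_o(ptp_t) = f_min; continuous at
# the breakpoint by construction
f0_of_pt <- function(pt, preset) {
  preset$f_min +
    preset$s1 * (pmin(pt, preset$breakpoint) - preset$ptp_t) +
    preset$s2 * pmax(0, pt - preset$breakpoint)
}

sl_of_pb <- function(pb, preset) {
  preset$sl_min + preset$sl_slope * (pb - preset$ptp_b)
}

# inverse of the source-level definition: RMS pressure at the microphone
rms_from_sl <- function(sl, r = 0.15, P0 = 20e-6) {
  P0 * 10^(sl / 20) / r
}

smooth_gate <- function(mask, ramp_n) {
  env <- as.numeric(mask)
  if (ramp_n < 2L || !any(mask)) return(env)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  half <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
  for (i in which(r$values)) {
    len <- r$lengths[i]
    k <- min(ramp_n, len %/% 2L)
    if (k >= 1L) {
      env[starts[i]:(starts[i] + k - 1L)] <- half[seq_len(k)]
      env[(ends[i] - k + 1L):ends[i]] <- rev(half[seq_len(k)])
    }
  }
  env
}

#' Simulate one hemi-syrinx run
#'
#' Forward model generating a protocol-conformant recording with known
#' ground truth. Bronchial pressure follows the commanded ramps and the
#' air-sac pressure the setpoints; phonation is active iff
#' `p_b >= ptp_b`, `p_icas >= ptp_icas` and `ptp_t <= p_t <= pt_max`.
#' While phonating, the sound is a harmonic stack (continuous phase,
#' `harmonic_rolloff` dB decay per partial, partials capped below the 10 kHz
#' anti-alias band) whose fundamental follows the piecewise-linear
#' f_o(p_t) and whose RMS realizes the linear SL(p_b) through the inverse
#' source-level relation; flow is `flow_conductance * p_b` while phonating
#' with a small leak otherwise; 5 ms amplitude ramps at on/offsets prevent
#' spectral splatter; Gaussian sensor noise is added to every channel.
#' Identical seeds give identical recordings.
#'
#' @param preset A [syrinx_preset()].
#' @param protocol A [make_protocol()] result.
#' @param seed Seed for the sensor noise.
#' @return A [multichannel_recording()] with the preset name in the
#'   metadata.
#' @export
simulate_run <- function(preset = syrinx_preset(),
                         protocol = make_protocol(), seed = 1L) {
  stopifnot(inherits(preset, "syrinx_preset"),
            inherits(protocol, "ramp_protocol"))
  sr <- protocol$sample_rate
  ramp_n <- round(protocol$pb_max / protocol$ramp_rate * sr)
  pause_n <- round(protocol$pause_s * sr)
  lead_n <- round(protocol$lead_in_s * sr)
  ramp_pb <- seq(0, protocol$pb_max, length.out = ramp_n)

  pb <- c(rep(0, lead_n),
          unlist(lapply(protocol$picas_levels,
                        function(l) c(ramp_pb, rep(0, pause_n)))))
  picas <- c(rep(0, lead_n),
             unlist(lapply(protocol$picas_levels,
                           function(l) c(rep(l, ramp_n), rep(0, pause_n)))))
  pt <- pb - picas
  phon <- pb >= preset$ptp_b & picas >= preset$ptp_icas &
    pt >= preset$ptp_t & pt <= preset$pt_max

  f0 <- f0_of_pt(pt, preset)
  f0[!phon] <- preset$f_min            # fill for phase continuity only
  phase <- 2 * pi * cumsum(f0) / sr
  hlimit <- min(10000, 0.98 * sr / 2)  # anti-alias band / Nyquist guard
  amps <- 10^(-preset$harmonic_rolloff * (seq_len(preset$harmonic_count) - 1)
              / 20)
  stack <- numeric(length(pb))
  norm2 <- numeric(length(pb))
  for (n in seq_len(preset$harmonic_count)) {
    ok <- n * f0 < hlimit
    a <- amps[n] * ok
    stack <- stack + a * sin(n * phase)
    norm2 <- norm2 + a^2 / 2
  }
  env <- smooth_gate(phon, round(preset$amp_ramp_s * sr))
  target <- rms_from_sl(sl_of_pb(pb, preset))
  # aspiration (turbulence) noise rides on the voiced source; the split
  # keeps the total RMS equal to the SL target
  asp_frac2 <- 10^(preset$aspiration_db / 10)
  voiced <- sqrt(1 - asp_frac2) * target * stack /
    sqrt(pmax(norm2, .Machine$double.eps))

  flow <- preset$flow_conductance * pb *
    (env + preset$leak_fraction * (1 - env))

  set.seed(seed)
  n <- length(pb)
  aspiration <- sqrt(asp_frac2) * target * stats::rnorm(n)
  sound <- env * (voiced + aspiration) + stats::rnorm(n, 0, preset$noise_rms)
  pb_rec <- pb + stats::rnorm(n, 0, preset$pressure_noise)
  picas_rec <- picas + stats::rnorm(n, 0, preset$pressure_noise)
  flow_rec <- pmax(flow + stats::rnorm(n, 0, preset$flow_noise), 0)

  meta <- recording_meta(subject_id = paste0(preset$name, "-seed", seed),
                         side = preset$side, sex = preset$sex)
  multichannel_recording(sound, pb_rec, picas_rec, flow_rec, sr, meta)
}

#' Analytic ground truth for a preset under a protocol
#'
#' Computes, without simulation, the run summary the pipeline should
#' recover: per-ramp phonation onsets (onset `p_b` is
#' `max(ptp_b, p_icas + ptp_t)` where phonation is reachable within the
#' ramp), the run-level phonation-boundary pressures, the expected mean
#' onset f_o ("minimal f_o"), minimal SL, and the generating slopes.
#'
#' @param preset A [syrinx_preset()].
#' @param protocol A [make_protocol()] result.
#' @return List with `per_ramp` (data frame) and the expected run-level
#'   scalars: `minimal_f0`, `minimal_SL`, `ptp_b`, `ptp_icas_min`,
#'   `ptp_t_min`, `n_phonating_ramps`, `s1`, `s2`, `sl_slope`, and
#'   `f_min`.
#' @export
ground_truth <- function(preset = syrinx_preset(),
                         protocol = make_protocol()) {
  lv <- protocol$picas_levels
  onset_pb <- pmax(preset$ptp_b, lv + preset$ptp_t)
  phonates <- lv >= preset$ptp_icas & onset_pb <= protocol$pb_max
  onset_pt <- onset_pb - lv
  onset_f0 <- f0_of_pt(onset_pt, preset)
  per_ramp <- data.frame(picas = lv, phonated = phonates,
                         onset_pb = ifelse(phonates, onset_pb, NA),
                         onset_pt = ifelse(phonates, onset_pt, NA),
                         onset_f0 = ifelse(phonates, onset_f0, NA))
  ph <- which(phonates)
  list(per_ramp = per_ramp,
       minimal_f0 = if (length(ph)) mean(onset_f0[ph]) else NA_real_,
       minimal_SL = if (length(ph))
         sl_of_pb(min(onset_pb[ph]), preset) else NA_real_,
       ptp_b = if (length(ph)) min(onset_pb[ph]) else NA_real_,
       ptp_icas_min = if (length(ph)) min(lv[ph]) else NA_real_,
       ptp_t_min = if (length(ph)) min(onset_pt[ph]) else NA_real_,
       n_phonating_ramps = length(ph),
       s1 = preset$s1, s2 = preset$s2, sl_slope = preset$sl_slope,
       f_min = preset$f_min)
}
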