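# Shared fixtures, built lazily and cached for the whole test run.
.fx <- new.env(parent = emptyenv())

# Small three-level run at the 20 kHz fast profile: one ramp below the
# air-sac threshold (no phonation), one onsetting at ptp_b, one at higher
# p_icas. Short pauses keep it quick; ramp rate and pressures are the
# protocol defaults.
small_protocol <- function(sr = 20000) {
  make_protocol(picas_levels = c(0.5, 1.5, 0), pause_s = 0.5,
                lead_in_s = 0.5, sample_rate = sr, seed = 3)
}

small_run <- function() {
  if (is.null(.fx$run)) {
    prot <- small_protocol()
    rec <- simulate_run(syrinx_preset(), prot, seed = 1)
    .fx$run <- list(protocol = prot, recording = rec,
                    analysis = analyze_recording(rec, protocol_hint = prot))
  }
  .fx$run
}

# harmonic test frame with deterministic phases
harmonic_frame <- function(f0, sr, dur = 0.025, n_harm = 8,
                           amps = 1 / seq_len(n_harm), rms = 0.02,
                           phases = rep(0, n_harm)) {
  t <- (seq_len(round(dur * sr)) - 1) / sr
  x <- Reduce(`+`, lapply(seq_len(n_harm), function(k)
    amps[k] * sin(2 * pi * k * f0 * t + phases[k])))
  x * rms / sqrt(mean(x^2))
}

# independent pitch oracle: maximum of the normalized autocorrelation over
# the lag band, with parabolic refinement; aperiodicity = 1 - peak value
acf_f0_oracle <- function(frame, sr, f_min = 150, f_max = 8000) {
  n <- length(frame)
  lags <- max(2, floor(sr / f_max)):ceiling(sr / f_min)
  r <- vapply(lags, function(tau) {
    a <- frame[1:(n - tau)]
    b <- frame[(1 + tau):n]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  # the autocorrelation of a periodic frame peaks at every multiple of the
  # period, and integer-lag sampling can favour a multiple: take the
  # smallest-lag local maximum within tolerance of the global maximum
  loc <- which(diff(sign(diff(r))) < 0) + 1L
  loc <- loc[r[loc] >= max(r) - 0.05]
  k <- if (length(loc)) loc[1] else which.max(r)
  lag <- lags[k]
  if (k > 1 && k < length(lags)) {
    y1 <- r[k - 1]; y2 <- r[k]; y3 <- r[k + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 0) lag <- lag + 0.5 * (y1 - y3) / den
  }
  list(f_o = sr / lag, aperiodicity = 1 - max(r))
}
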