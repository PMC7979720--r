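#' Configuration for per-bin fundamental frequency estimation
#'
#' @param aperiodicity_max Accept threshold on YIN aperiodicity (the
#'   cumulative-mean-normalized difference at the chosen lag); candidate f_o
#'   values above it are reported missing. Typical tuning range 0.05-0.2.
#' @param power_min Accept threshold on frame RMS sound pressure (Pa);
#'   typical tuning range 0.25-5 mPa.
#' @param power_floor RMS floor (Pa) below which bins are skipped outright.
#' @param f_min,f_max Search band for f_o (Hz).
#' @param window Analysis window for the YIN difference function (s). The
#'   2 ms feature bin is far too short for f_o near 500 Hz, so f_o is
#'   estimated on this longer window centered on the bin.
#' @param cmnd_threshold Dip-selection threshold on the CMND curve (standard
#'   YIN practice), distinct from the reporting gate `aperiodicity_max`.
#' @return An `f0_config` list.
#' @export
f0_config <- function(aperiodicity_max = 0.15, power_min = 0.5e-3,
                      power_floor = 0.25e-3, f_min = 150, f_max = 8000,
                      window = 0.025, cmnd_threshold = 0.15) {
  stopifnot(aperiodicity_max > 0, aperiodicity_max < 1, power_min > 0,
            power_floor > 0, f_min > 0, f_max > f_min, window > 0)
  structure(list(aperiodicity_max = aperiodicity_max, power_min = power_min,
                 power_floor = power_floor, f_min = f_min, f_max = f_max,
                 window = window, cmnd_threshold = cmnd_threshold),
            class = "f0_config")
}

#' YIN fundamental-frequency estimate for one frame
#'
#' Implements the YIN estimator: squared difference function, cumulative
#' mean normalization (CMND), first dip below the threshold, and parabolic
#' interpolation of the selected lag. The CMND value at the selected lag is
#' reported as the aperiodicity. f_o is reported only when the aperiodicity
#' passes `cfg$aperiodicity_max` and the frame RMS passes `cfg$power_min`;
#' otherwise it is missing while the aperiodicity is still returned.
#'
#' @param frame Sound samples (Pa).
#' @param sample_rate Sample rate (Hz).
#' @param cfg An [f0_config()].
#' @return List with elements `f_o` (Hz or `NA`) and `aperiodicity`.
#' @export
yin_f0 <- function(frame, sample_rate, cfg = f0_config()) {
  max_lag <- ceiling(sample_rate / cfg$f_min)
  min_lag <- max(2L, floor(sample_rate / cfg$f_max))
  if (length(frame) < 2L * max_lag)
    stop("frame too short: need >= ", 2L * max_lag, " samples for f_min = ",
         cfg$f_min, " Hz, got ", length(frame))
  rms <- sqrt(mean(frame^2))
  if (rms == 0) return(list(f_o = NA_real_, aperiodicity = 1))
  cmnd <- yin_cmnd(frame, as.integer(max_lag))
  idx <- seq.int(min_lag, max_lag)
  vals <- cmnd[idx]
  below <- which(vals < cfg$cmnd_threshold)
  if (length(below)) {
    # descend from the first sub-threshold lag to its local minimum
    k <- below[1L]
    while (k < length(vals) && vals[k + 1L] < vals[k]) k <- k + 1L
  } else {
    k <- which.min(vals)
  }
  lag <- idx[k]
  ap <- vals[k]
  # parabolic interpolation over the full CMND curve around the chosen lag
  if (lag > 1L && lag < max_lag) {
    y1 <- cmnd[lag - 1L]; y2 <- cmnd[lag]; y3 <- cmnd[lag + 1L]
    denom <- y1 - 2 * y2 + y3
    if (is.finite(denom) && abs(denom) > .Machine$double.eps) {
      delta <- 0.5 * (y1 - y3) / denom
      if (abs(delta) <= 1) lag <- lag + delta
    }
  }
  f_o <- sample_rate / lag
  gated <- ap > cfg$aperiodicity_max || rms < cfg$power_min
  list(f_o = if (gated) NA_real_ else f_o, aperiodicity = ap)
}

#' Source level at 1 m re 20 uPa
#'
#' `SL = 20 log10(p_rms / P0) + 20 log10(r)`: the measured RMS sound
#' pressure referenced to `P0` and back-propagated from the microphone
#' distance `r` to 1 m assuming spherical spreading.
#'
#' @param p_rms RMS sound pressure (Pa), >= 0. Zero maps to `-Inf`.
#' @param r Microphone distance (m).
#' @param P0 Reference pressure (Pa), default 20 uPa.
#' @return Source level (dB re 20 uPa at 1 m).
#' @export
source_level <- function(p_rms, r = 0.15, P0 = 20e-6) {
  stopifnot(r > 0, P0 > 0)
  if (any(p_rms < 0, na.rm = TRUE)) stop("p_rms must be >= 0")
  20 * log10(p_rms / P0) + 20 * log10(r)
}

#' Wiener entropy of an amplitude spectrum
#'
#' `WE = log10(geomean(Px) / mean(Px))`; 0 for a flat (white) spectrum and
#' strongly negative for tonal sounds. Spectral values are floored at
#' machine epsilon times the spectral maximum so the geometric mean stays
#' defined.
#'
#' @param Px Amplitude spectrum (non-negative).
#' @return Wiener entropy (dB, <= 0), or `NA` if the spectrum is all zero.
#' @export
we_from_spectrum <- function(Px) {
  stopifnot(all(Px >= 0))
  m <- max(Px)
  if (m == 0) return(NA_real_)
  Px <- pmax(Px, .Machine$double.eps * m)
  mean(log10(Px)) - log10(mean(Px))
}

#' Wiener entropy of a sound frame
#'
#' Computes the amplitude spectrum by the periodogram method with a Hann
#' taper (frames shorter than `fft_size` are zero-padded; longer frames are
#' averaged over `fft_size` segments with the given overlap, i.e. Welch
#' averaging), restricts it to frequencies in (0, `fmax`], and applies
#' [we_from_spectrum()]. The taper keeps the inter-harmonic floor set by the
#' signal, not by spectral leakage.
#'
#' @param frame Sound samples (Pa).
#' @param sample_rate Sample rate (Hz).
#' @param fft_size FFT size (samples), default 2048.
#' @param overlap Segment overlap (samples) for frames longer than
#'   `fft_size`, default 1024.
#' @param fmax Upper analysis frequency (Hz); defaults to the 10 kHz
#'   anti-alias band of the acquisition chain.
#' @return Wiener entropy (dB, <= 0), or `NA` for an all-zero frame.
#' @export
wiener_entropy <- function(frame, sample_rate, fft_size = 2048,
                           overlap = 1024, fmax = 10000) {
  n <- length(frame)
  if (n == 0L) stop("empty frame")
  if (all(frame == 0)) return(NA_real_)
  if (n <= fft_size) {
    segs <- list(c(frame, rep(0, fft_size - n)))
  } else {
    step <- fft_size - overlap
    starts <- seq(1L, n - fft_size + 1L, by = step)
    segs <- lapply(starts, function(s) frame[s:(s + fft_size - 1L)])
  }
  nbin <- fft_size %/% 2L
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(fft_size) / (fft_size + 1))
  amp <- rowMeans(vapply(segs, function(s)
    Mod(stats::fft(s * taper))[2:(nbin + 1L)], numeric(nbin)))
  freq <- (1:nbin) * sample_rate / fft_size
  we_from_spectrum(amp[freq <= fmax])
}

#' Fundamental frequency from a measured harmonic
#'
#' Reading a higher harmonic and dividing by its order increases f_o
#' resolution on spectrograms: `f_o = f_n / n`.
#'
#' @param f_n Frequency of the n-th harmonic (Hz), > 0.
#' @param n Harmonic number (integer >= 1).
#' @return f_o (Hz).
#' @export
f0_from_harmonic <- function(f_n, n) {
  if (any(n < 1) || any(n != round(n))) stop("n must be a positive integer")
  stopifnot(all(f_n > 0))
  f_n / n
}
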