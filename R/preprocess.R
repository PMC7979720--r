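#' Zero-phase Butterworth filter
#'
#' Forward-backward Butterworth filtering with odd-reflection edge padding,
#' so the output has zero phase shift and no startup transients. The filter
#' is designed with [signal::butter()] and applied twice (once in each
#' direction), which squares its magnitude response.
#'
#' @param x Numeric series.
#' @param sample_rate Sample rate (Hz).
#' @param kind `"highpass"` or `"lowpass"`.
#' @param cutoff Cutoff frequency (Hz), in (0, sample_rate/2).
#' @param order Filter order (>= 1).
#' @return Filtered series, same length as `x`.
#' @export
zero_phase_filter <- function(x, sample_rate,
                              kind = c("highpass", "lowpass"),
                              cutoff, order = 3L) {
  kind <- match.arg(kind)
  stopifnot(order >= 1, cutoff > 0, cutoff < sample_rate / 2)
  n <- length(x)
  pad <- 3L * (order + 1L)  # odd-reflection padding per pass
  if (n <= pad + 1L)
    stop("input too short for stable forward-backward filtering: need > ",
         pad + 1L, " samples, got ", n)
  bt <- signal::butter(order, 2 * cutoff / sample_rate,
                       type = if (kind == "highpass") "high" else "low")
  head_pad <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(head_pad, x, tail_pad)
  y <- signal::filter(bt, xp)
  y <- rev(signal::filter(bt, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Number of sliding bins covering a series
#'
#' @param n Number of samples.
#' @param width Bin width in samples.
#' @param hop Hop in samples.
#' @return `floor((n - width) / hop) + 1`, or 0 if `n < width`.
#' @export
bin_count <- function(n, width, hop) {
  if (n < width) return(0L)
  as.integer((n - width) %/% hop) + 1L
}

bin_stat <- function(x, width, hop, stat = c("rms", "mean")) {
  stat <- match.arg(stat)
  nb <- bin_count(length(x), width, hop)
  if (nb == 0L) return(numeric(0))
  starts <- (seq_len(nb) - 1L) * hop  # 0-based sample offsets
  if (stat == "rms") {
    cs <- c(0, cumsum(x * x))
    sqrt((cs[starts + width + 1L] - cs[starts + 1L]) / width)
  } else {
    cs <- c(0, cumsum(x))
    (cs[starts + width + 1L] - cs[starts + 1L]) / width
  }
}

#' Per-bin RMS over a sliding window
#'
#' Bin `k` (0-based) covers samples in time `[k * hop, k * hop + bin_width)`;
#' bins start at t = 0 of the recording.
#'
#' @param x Numeric series.
#' @param sample_rate Sample rate (Hz).
#' @param bin_width Bin duration (s), default 2 ms.
#' @param hop Hop between bin starts (s), default 1 ms.
#' @return Numeric vector of per-bin RMS values with attribute
#'   `bin_center_t` (bin centers in seconds).
#' @export
bin_rms <- function(x, sample_rate, bin_width = 0.002, hop = 0.001) {
  stopifnot(hop > 0, bin_width >= hop)
  w <- round(bin_width * sample_rate)
  h <- round(hop * sample_rate)
  if (length(x) < w) {
    warning("recording shorter than one bin; returning empty series")
    return(structure(numeric(0), bin_center_t = numeric(0)))
  }
  out <- bin_stat(x, w, h, "rms")
  centers <- ((seq_along(out) - 1L) * h + w / 2) / sample_rate
  structure(out, bin_center_t = centers)
}

#' Assemble the per-bin feature table for a recording
#'
#' Conditions the channels (zero-phase high-pass on sound, low-pass on
#' pressures and flow), bins everything on a shared time grid, and computes
#' per-bin acoustic and aerodynamic features: RMS sound pressure, mean
#' pressures and flow, transmural pressure `p_t = p_b - p_icas`, YIN
#' fundamental frequency with aperiodicity/power gating, source level (SL),
#' Wiener entropy (WE) and mechanical efficiency (ME).
#'
#' Pressure and flow are summarized per bin by their mean (they are slow,
#' non-negative signals; a difference of RMS values would be ill-defined for
#' signed signals); sound by its RMS. YIN and WE are evaluated only on bins
#' whose sound RMS reaches `cfg$f0$power_floor`; quieter bins are power-gated
#' to missing f_o regardless, and carry missing aperiodicity/WE.
#'
#' @param rec A [multichannel_recording()].
#' @param cfg A [pipeline_config()].
#' @return A data frame of class `binned_features` with attributes
#'   `bin_width`, `hop`, `sample_rate`, `meta` and `config`.
#' @export
assemble_features <- function(rec, cfg = pipeline_config()) {
  stopifnot(inherits(rec, "multichannel_recording"))
  sr <- rec$sample_rate
  sound <- zero_phase_filter(rec$sound, sr, "highpass",
                             cfg$filter$sound_highpass_hz,
                             cfg$filter$sound_order)
  p_b <- zero_phase_filter(rec$p_b, sr, "lowpass",
                           cfg$filter$slow_lowpass_hz, cfg$filter$slow_order)
  p_icas <- zero_phase_filter(rec$p_icas, sr, "lowpass",
                              cfg$filter$slow_lowpass_hz,
                              cfg$filter$slow_order)
  flow <- zero_phase_filter(rec$flow, sr, "lowpass",
                            cfg$filter$slow_lowpass_hz, cfg$filter$slow_order)

  w <- round(cfg$bin_width * sr)
  h <- round(cfg$hop * sr)
  rms_sound <- bin_stat(sound, w, h, "rms")
  nb <- length(rms_sound)
  if (nb == 0L) stop("recording shorter than one analysis bin")
  centers_s <- ((seq_len(nb) - 1L) * h + w / 2) / sr

  df <- data.frame(
    bin_center_t = centers_s,
    rms_sound = rms_sound,
    p_b = bin_stat(p_b, w, h, "mean"),
    p_icas = bin_stat(p_icas, w, h, "mean"),
    flow = bin_stat(flow, w, h, "mean"))
  df$p_t <- df$p_b - df$p_icas

  # f_o / aperiodicity on a longer centered window; WE on the bin itself
  active <- which(df$rms_sound >= cfg$f0$power_floor)
  df$f_o <- NA_real_
  df$aperiodicity <- NA_real_
  df$WE <- NA_real_
  if (length(active)) {
    half <- round(cfg$f0$window * sr / 2)
    n <- length(sound)
    for (i in active) {
      c_idx <- round((i - 1L) * h + w / 2)
      lo <- max(1L, c_idx - half)
      hi <- min(n, c_idx + half - 1L)
      res <- yin_f0(sound[lo:hi], sr, cfg$f0)
      df$f_o[i] <- res$f_o
      df$aperiodicity[i] <- res$aperiodicity
      # WE per bin from an fft_size-sample window centered on the bin
      wlo <- max(1L, c_idx - cfg$we$fft_size %/% 2L)
      whi <- min(n, wlo + cfg$we$fft_size - 1L)
      df$WE[i] <- wiener_entropy(sound[wlo:whi], sr,
                                 fft_size = cfg$we$fft_size,
                                 overlap = cfg$we$overlap,
                                 fmax = cfg$we$fmax)
    }
  }

  meta <- rec$meta
  df$SL <- ifelse(df$rms_sound > 0,
                  source_level(pmax(df$rms_sound, .Machine$double.xmin),
                               meta$mic_distance_r, meta$ref_pressure_P0),
                  NA_real_)
  p_ac <- acoustic_power(df$rms_sound, meta$mic_distance_r,
                         meta$air_density_rho, meta$sound_speed_v,
                         cfg$me$solid_angle_factor)
  ok_flow <- df$flow >= cfg$me$flow_floor & df$p_b > 0
  df$ME <- NA_real_
  p_aero <- aerodynamic_power(pmax(df$p_b, 0) * 1000,  # kPa -> Pa here
                              pmax(df$flow, 0))
  me <- mechanical_efficiency(p_ac, p_aero)
  df$ME[ok_flow] <- me[ok_flow]

  structure(df, class = c("binned_features", "data.frame"),
            bin_width = cfg$bin_width, hop = cfg$hop, sample_rate = sr,
            meta = meta, config = cfg)
}
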