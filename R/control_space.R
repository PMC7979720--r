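#' Sound-power detection threshold for phonation
#'
#' The onset threshold is anchored to the recording's own noise floor:
#' `max(noise_floor_multiple * median pre-ramp RMS, absolute_floor)`, where
#' the pre-ramp bins are those with both pressures near zero. The absolute
#' floor defaults to 0.25 mPa, the lower bound of the customary power-gating
#' range.
#'
#' @param features A `binned_features` table.
#' @param cfg A [pipeline_config()].
#' @return Threshold on per-bin RMS sound pressure (Pa).
#' @export
detection_threshold <- function(features, cfg = pipeline_config()) {
  quiet <- features$p_b < cfg$segment$pb_on &
    features$p_icas < cfg$segment$pb_on
  floor_est <- if (any(quiet)) {
    stats::median(features$rms_sound[quiet])
  } else {
    stats::quantile(features$rms_sound, 0.05, names = FALSE)
  }
  max(cfg$ptp$noise_floor_multiple * floor_est, cfg$ptp$absolute_floor)
}

#' Segment bronchial-pressure ramps
#'
#' Finds maximal stretches of bins where `p_b` is raised above baseline while
#' `p_icas` holds a piecewise-constant setpoint; inter-ramp pauses (both
#' pressures near zero) separate segments.
#'
#' @param features A `binned_features` table.
#' @param protocol_hint Optional [make_protocol()]; if given, the number of
#'   detected segments must equal the protocol's ramp count.
#' @param cfg A [pipeline_config()].
#' @return A data frame (class `ramp_segments`), one row per segment:
#'   `start_bin`, `end_bin`, `picas_setpoint`, `ramp_rate_est`.
#' @export
segment_ramps <- function(features, protocol_hint = NULL,
                          cfg = pipeline_config()) {
  on <- features$p_b > cfg$segment$pb_on
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$segment$min_bins
  segs <- data.frame(start_bin = starts[keep], end_bin = ends[keep])
  if (nrow(segs)) {
    hop <- attr(features, "hop")
    segs$picas_setpoint <- vapply(seq_len(nrow(segs)), function(i) {
      idx <- segs$start_bin[i]:segs$end_bin[i]
      # trim the segment edges where the setpoint is still settling
      core <- idx[seq(max(1L, round(0.1 * length(idx))),
                      round(0.9 * length(idx)))]
      stats::median(features$p_icas[core])
    }, numeric(1))
    segs$ramp_rate_est <- vapply(seq_len(nrow(segs)), function(i) {
      idx <- segs$start_bin[i]:segs$end_bin[i]
      stats::coef(stats::lm(features$p_b[idx] ~ features$bin_center_t[idx]))[2]
    }, numeric(1))
  } else {
    segs$picas_setpoint <- numeric(0)
    segs$ramp_rate_est <- numeric(0)
  }
  if (!is.null(protocol_hint)) {
    expected <- length(protocol_hint$picas_levels)
    if (nrow(segs) != expected)
      stop("segmentation error: found ", nrow(segs), " ramp(s), protocol ",
           "declares ", expected, "; candidates at bins ",
           paste(segs$start_bin, collapse = ", "))
  }
  structure(segs, class = c("ramp_segments", "data.frame"))
}

#' Detect the phonation threshold pressure on one ramp
#'
#' Scans the segment's bins in time order; at the first bin whose RMS sound
#' pressure reaches the threshold, the bin's `p_b`, `p_icas` and `p_t` are
#' recorded (the onset pressure is read from the crossing bin, not
#' interpolated).
#'
#' The onset f_o needs more care than the onset pressures: pitch estimates
#' at the crossing bin itself are biased by the growing amplitude envelope
#' (a rising envelope tilts the difference function toward shorter lags),
#' while bins well after onset reflect a higher driving pressure. The onset
#' f_o is therefore read from a short local regression of f_o on time over
#' the first clean bins after the transient, extrapolated back to the
#' crossing bin. With fewer than 5 clean estimates it falls back to the
#' first non-missing f_o at or after the crossing.
#'
#' @param segment One row of [segment_ramps()] output (data frame or list).
#' @param features A `binned_features` table.
#' @param threshold Sound-power threshold (Pa RMS), e.g. from
#'   [detection_threshold()].
#' @param f0_lookahead Bins after the transient used for the onset-f_o
#'   regression (and, as fallback, searched for the first non-missing f_o).
#' @return A `ptp_result` list: `phonated`, `ptp_b`, `ptp_icas`, `ptp_t`,
#'   `onset_bin`, `onset_f0`.
#' @export
detect_ptp <- function(segment, features, threshold, f0_lookahead = 40L) {
  idx <- segment$start_bin:segment$end_bin
  cross <- which(features$rms_sound[idx] >= threshold)
  if (!length(cross)) {
    return(structure(list(phonated = FALSE, ptp_b = NA_real_,
                          ptp_icas = NA_real_, ptp_t = NA_real_,
                          onset_bin = NA_integer_, onset_f0 = NA_real_),
                     class = "ptp_result"))
  }
  onset <- idx[cross[1L]]
  # bins whose f_o window still overlaps the onset transient are skipped
  cfg <- attr(features, "config")
  hop <- attr(features, "hop") %||% 0.001
  win <- if (!is.null(cfg)) cfg$f0$window else 0.025
  skip <- ceiling((win / 2 + 0.005) / hop)
  clean <- (onset + skip):min(onset + skip + f0_lookahead, segment$end_bin)
  clean <- clean[!is.na(features$f_o[clean])]
  f0 <- if (length(clean) >= 5L) {
    fit <- stats::lm(features$f_o[clean] ~ features$bin_center_t[clean])
    unname(stats::coef(fit)[1L] +
             stats::coef(fit)[2L] * features$bin_center_t[onset])
  } else {
    ahead <- onset:min(onset + skip + f0_lookahead, segment$end_bin)
    hit <- ahead[!is.na(features$f_o[ahead])]
    if (length(hit)) features$f_o[hit[1L]] else NA_real_
  }
  structure(list(phonated = TRUE,
                 ptp_b = features$p_b[onset],
                 ptp_icas = features$p_icas[onset],
                 ptp_t = features$p_b[onset] - features$p_icas[onset],
                 onset_bin = onset, onset_f0 = f0),
            class = "ptp_result")
}

#' Phonating-bin masks for a run
#'
#' `raw`: bins whose RMS sound pressure reaches the threshold (the mask used
#' for onset detection). `steady`: the raw mask eroded by `guard_bins` at
#' every boundary, dropping bins whose analysis window straddles a phonation
#' on/offset and therefore carries partial-window RMS; level statistics
#' (minimal SL, WE/ME means, maps) use this mask.
#'
#' @param features A `binned_features` table.
#' @param threshold Sound-power threshold (Pa RMS).
#' @param guard_bins Erosion width in bins.
#' @return List of two logical vectors, `raw` and `steady`.
#' @export
phonating_mask <- function(features, threshold, guard_bins = 10L) {
  raw <- features$rms_sound >= threshold
  steady <- raw
  if (guard_bins > 0L && any(raw)) {
    r <- rle(raw)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      steady[starts[i]:min(ends[i], starts[i] + guard_bins - 1L)] <- FALSE
      steady[max(starts[i], ends[i] - guard_bins + 1L):ends[i]] <- FALSE
    }
  }
  list(raw = raw, steady = steady)
}

#' Summarize one run (one hemi-syrinx, one protocol)
#'
#' Run-level scalars: `minimal_f0` is the mean onset f_o over phonating
#' ramps (the f_o at the first threshold crossing of each ramp);
#' `minimal_SL` the lowest SL over steady phonating bins; `mean_WE` /
#' `mean_ME` their means over steady phonating bins. The run-level phonation
#' threshold pressures are the boundary values of the phonation region:
#' the minimum onset `p_b`, `p_icas` and `p_t` over phonating ramps.
#'
#' @param ptps List of [detect_ptp()] results, one per segment.
#' @param features A `binned_features` table.
#' @param segments [segment_ramps()] output.
#' @param threshold Sound-power threshold (Pa RMS).
#' @param cfg A [pipeline_config()].
#' @return A `run_summary` list.
#' @export
summarize_run <- function(ptps, features, segments, threshold,
                          cfg = pipeline_config()) {
  stopifnot(nrow(segments) >= 1L, length(ptps) == nrow(segments))
  phon <- vapply(ptps, `[[`, logical(1), "phonated")
  if (!any(phon)) {
    message("no phonating ramps; summary is all missing")
    return(structure(list(minimal_f0 = NA_real_, minimal_SL = NA_real_,
                          mean_WE = NA_real_, mean_ME = NA_real_,
                          ptp_b = NA_real_, ptp_icas_min = NA_real_,
                          ptp_t_min = NA_real_, n_phonating_ramps = 0L),
                     class = "run_summary"))
  }
  onset_f0 <- vapply(ptps[phon], `[[`, numeric(1), "onset_f0")
  mask <- phonating_mask(features, threshold, cfg$ptp$guard_bins)$steady
  in_seg <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(segments)))
    in_seg[segments$start_bin[i]:segments$end_bin[i]] <- TRUE
  use <- mask & in_seg
  structure(list(
    minimal_f0 = if (any(!is.na(onset_f0))) mean(onset_f0, na.rm = TRUE)
                 else NA_real_,
    minimal_SL = if (any(use & !is.na(features$SL)))
                   min(features$SL[use], na.rm = TRUE) else NA_real_,
    mean_WE = mean(features$WE[use], na.rm = TRUE),
    mean_ME = mean(features$ME[use], na.rm = TRUE),
    ptp_b = min(vapply(ptps[phon], `[[`, numeric(1), "ptp_b")),
    ptp_icas_min = min(vapply(ptps[phon], `[[`, numeric(1), "ptp_icas")),
    ptp_t_min = min(vapply(ptps[phon], `[[`, numeric(1), "ptp_t")),
    n_phonating_ramps = sum(phon)),
    class = "run_summary")
}

#' Map a feature over the p_b x p_icas control space
#'
#' Grids the steady phonating bins of a run on the bronchial by air-sac
#' pressure plane and reports per-cell mean, standard deviation and count of
#' the chosen feature. Cells without data stay missing, never zero.
#'
#' @param features A `binned_features` table.
#' @param segments [segment_ramps()] output (bins outside segments are
#'   ignored).
#' @param feature_name Column of `features` to map (e.g. `"f_o"`, `"SL"`).
#' @param threshold Sound-power threshold (Pa RMS).
#' @param pb_step,picas_step Cell sizes (kPa); the air-sac step defaults to
#'   the protocol's level spacing.
#' @param cfg A [pipeline_config()].
#' @return A `control_space_map` with matrices `mean`, `sd`, `count` and the
#'   grid edge vectors.
#' @export
build_map <- function(features, segments, feature_name, threshold,
                      pb_step = NULL, picas_step = NULL,
                      cfg = pipeline_config()) {
  if (!feature_name %in% names(features))
    stop("unknown feature: ", feature_name)
  pb_step <- pb_step %||% cfg$map$pb_step
  picas_step <- picas_step %||% cfg$map$picas_step
  if (pb_step <= 0 || picas_step <= 0) stop("grid steps must be > 0")
  mask <- phonating_mask(features, threshold, cfg$ptp$guard_bins)$steady
  in_seg <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(segments)))
    in_seg[segments$start_bin[i]:segments$end_bin[i]] <- TRUE
  use <- which(mask & in_seg & !is.na(features[[feature_name]]))
  pb <- features$p_b[use]
  picas <- features$p_icas[use]
  val <- features[[feature_name]][use]
  pb_edges <- seq(0, max(pb, pb_step) + pb_step, by = pb_step)
  picas_edges <- seq(-picas_step / 2,
                     max(picas, 0) + picas_step, by = picas_step)
  ib <- findInterval(pb, pb_edges, rightmost.closed = TRUE)
  ij <- findInterval(picas, picas_edges, rightmost.closed = TRUE)
  nb <- length(pb_edges) - 1L
  nj <- length(picas_edges) - 1L
  idx <- (ij - 1L) * nb + ib
  count <- matrix(0L, nb, nj)
  mean_m <- matrix(NA_real_, nb, nj)
  sd_m <- matrix(NA_real_, nb, nj)
  if (length(idx)) {
    tab <- tapply(val, idx, length)
    count[as.integer(names(tab))] <- tab
    mu <- tapply(val, idx, mean)
    mean_m[as.integer(names(mu))] <- mu
    sdv <- tapply(val, idx, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_)
    sd_m[as.integer(names(sdv))] <- sdv
  }
  structure(list(feature = feature_name, pb_edges = pb_edges,
                 picas_edges = picas_edges, mean = mean_m, sd = sd_m,
                 count = count),
            class = "control_space_map")
}

#' @export
print.control_space_map <- function(x, ...) {
  cat(sprintf("<control_space_map> %s: %d x %d cells, %d populated\n",
              x$feature, nrow(x$count), ncol(x$count), sum(x$count > 0)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
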