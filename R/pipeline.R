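#' Run the full analysis pipeline on one recording
#'
#' Conditions and bins the channels, detects the sound-power threshold,
#' segments the bronchial-pressure ramps, detects per-ramp phonation
#' thresholds, summarizes the run, fits the piecewise f_o-p_t and linear
#' SL-p_b regressions on steady phonating bins pooled across ramps, and
#' runs the delta-BIC driving-pressure selection for both responses.
#'
#' @param rec A [multichannel_recording()], e.g. from [read_recording()] or
#'   [simulate_run()].
#' @param cfg A [pipeline_config()].
#' @param protocol_hint Optional [make_protocol()] result; enforces the
#'   expected ramp count during segmentation.
#' @param maps Character vector of feature columns to map over the control
#'   space (default f_o, SL, WE, ME).
#' @return A `run_analysis` list: `features`, `threshold`, `segments`,
#'   `ptp` (data frame, one row per ramp), `summary`, `fits` (list with
#'   `f0_piecewise`, `sl_linear`, `bic_f0`, `bic_sl`), `maps`.
#' @export
analyze_recording <- function(rec, cfg = pipeline_config(),
                              protocol_hint = NULL,
                              maps = c("f_o", "SL", "WE", "ME")) {
  features <- assemble_features(rec, cfg)
  threshold <- detection_threshold(features, cfg)
  segments <- segment_ramps(features, protocol_hint, cfg)
  if (!nrow(segments)) stop("no bronchial-pressure ramps found")
  ptps <- lapply(seq_len(nrow(segments)), function(i)
    detect_ptp(segments[i, ], features, threshold))
  ptp_df <- do.call(rbind, lapply(seq_along(ptps), function(i)
    data.frame(ramp = i, picas_setpoint = segments$picas_setpoint[i],
               phonated = ptps[[i]]$phonated, ptp_b = ptps[[i]]$ptp_b,
               ptp_icas = ptps[[i]]$ptp_icas, ptp_t = ptps[[i]]$ptp_t,
               onset_bin = ptps[[i]]$onset_bin,
               onset_f0 = ptps[[i]]$onset_f0)))
  summary <- summarize_run(ptps, features, segments, threshold, cfg)

  mask <- phonating_mask(features, threshold, cfg$ptp$guard_bins)$steady
  in_seg <- rep(FALSE, nrow(features))
  for (i in seq_len(nrow(segments)))
    in_seg[segments$start_bin[i]:segments$end_bin[i]] <- TRUE
  use <- mask & in_seg
  fits <- list(f0_piecewise = NULL, sl_linear = NULL,
               bic_f0 = NULL, bic_sl = NULL)
  okf <- use & !is.na(features$f_o)
  if (sum(okf) >= 10L) {
    fits$f0_piecewise <- tryCatch(
      fit_piecewise(features$p_t[okf], features$f_o[okf],
                    cfg$fits$breakpoint, cfg$fits$upper_limit),
      error = function(e) NULL)
    fits$bic_f0 <- delta_bic(features$f_o[okf],
                             list(p_b = features$p_b[okf],
                                  p_icas = features$p_icas[okf],
                                  p_t = features$p_t[okf]))
  }
  oks <- use & !is.na(features$SL)
  if (sum(oks) >= 10L) {
    fits$sl_linear <- fit_linear(features$p_b[oks], features$SL[oks])
    fits$bic_sl <- delta_bic(features$SL[oks],
                             list(p_b = features$p_b[oks],
                                  p_icas = features$p_icas[oks],
                                  p_t = features$p_t[oks]))
  }
  map_list <- lapply(maps, function(nm)
    build_map(features, segments, nm, threshold, cfg = cfg))
  names(map_list) <- maps
  structure(list(features = features, threshold = threshold,
                 segments = segments, ptp = ptp_df, summary = summary,
                 fits = fits, maps = map_list),
            class = "run_analysis")
}

#' @export
print.run_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<run_analysis> %d ramps (%d phonating)\n",
           "  threshold    %.3g Pa RMS\n",
           "  minimal f_o  %.1f Hz\n",
           "  PTP_b        %.3f kPa (PTP_icas >= %.3f, PTP_t >= %.3f)\n",
           "  minimal SL   %.1f dB re 20 uPa at 1 m\n",
           "  mean WE      %.2f dB, mean ME %.1f dB\n"),
    nrow(x$segments), s$n_phonating_ramps, x$threshold, s$minimal_f0,
    s$ptp_b, s$ptp_icas_min, s$ptp_t_min, s$minimal_SL, s$mean_WE,
    s$mean_ME))
  if (!is.null(x$fits$f0_piecewise))
    cat(sprintf("  f_o ~ p_t    S1 %.0f Hz/kPa, S2 %.0f Hz/kPa (best: %s)\n",
                x$fits$f0_piecewise$s1_slope, x$fits$f0_piecewise$s2_slope,
                attr(x$fits$bic_f0, "best")))
  if (!is.null(x$fits$sl_linear))
    cat(sprintf("  SL ~ p_b     %.1f dB/kPa (best: %s)\n",
                x$fits$sl_linear$slope, attr(x$fits$bic_sl, "best")))
  invisible(x)
}

#' Tidy long-format table of run summaries
#'
#' One row per subject x side x age x metric, suitable as direct input to
#' external mixed-model tooling. Duplicate subject/side/age keys are an
#' error.
#'
#' @param analyses Named list of `run_analysis` objects (or `run_summary`
#'   objects) keyed by run id.
#' @param meta Data frame with one row per run: `subject_id`, `side`,
#'   `sex`, `age_dph` (rows align with `analyses`).
#' @return Data frame: `subject_id`, `side`, `sex`, `age_dph`, `metric`,
#'   `value`.
#' @export
report_table <- function(analyses, meta) {
  stopifnot(length(analyses) == nrow(meta))
  key <- paste(meta$subject_id, meta$side, meta$age_dph)
  if (anyDuplicated(key))
    stop("duplicate subject/side/age keys: ",
         paste(key[duplicated(key)], collapse = "; "))
  metrics <- c("minimal_f0", "minimal_SL", "mean_WE", "mean_ME", "ptp_b",
               "ptp_icas_min", "ptp_t_min")
  rows <- lapply(seq_along(analyses), function(i) {
    a <- analyses[[i]]
    s <- if (inherits(a, "run_analysis")) a$summary else a
    data.frame(subject_id = meta$subject_id[i], side = meta$side[i],
               sex = meta$sex[i], age_dph = meta$age_dph[i],
               metric = metrics,
               value = vapply(metrics, function(m)
                 as.numeric(s[[m]] %||% NA_real_), numeric(1)),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(subject_id = character(0), side = character(0),
                      sex = character(0), age_dph = integer(0),
                      metric = character(0), value = numeric(0))
  out
}
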