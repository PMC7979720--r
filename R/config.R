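#' Pipeline configuration
#'
#' Bundles every tunable of the analysis pipeline with its shipped default.
#' Defaults follow the conventions of the in vitro protocol: 0.1 kHz 3rd
#' order high-pass on sound (0.3 kHz is the usual in vivo variant), 2 kHz
#' 3rd order low-pass on pressures and flow, 2 ms bins with 1 ms hop.
#'
#' @param bin_width Analysis bin duration (s).
#' @param hop Bin hop (s).
#' @param filter List: `sound_highpass_hz`, `sound_order`,
#'   `slow_lowpass_hz`, `slow_order`.
#' @param f0 An [f0_config()].
#' @param we List: `fft_size`, `overlap`, `fmax` for Wiener entropy.
#' @param me List: `solid_angle_factor`, `flow_floor` (m^3 s^-1) below which
#'   ME is left missing.
#' @param ptp List: `noise_floor_multiple`, `absolute_floor` (Pa) defining
#'   the sound-power detection threshold
#'   `max(noise_floor_multiple * pre-ramp median RMS, absolute_floor)`, and
#'   `guard_bins`, the erosion applied at phonation boundaries before level
#'   statistics (bins whose window straddles an on/offset carry
#'   partial-window RMS).
#' @param map List: `pb_step`, `picas_step` (kPa) for control-space maps.
#' @param fits List: `breakpoint`, `upper_limit` (kPa) for the piecewise
#'   f_o fit.
#' @param segment List: `pb_on` (kPa) level above which a ramp is considered
#'   active, `picas_tolerance` (kPa) allowed wobble around the setpoint,
#'   `min_bins` minimum segment length.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(bin_width = 0.002, hop = 0.001,
                            filter = list(), f0 = f0_config(), we = list(),
                            me = list(), ptp = list(), map = list(),
                            fits = list(), segment = list()) {
  merge_block <- function(defaults, user, block) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop("unknown config key(s) in '", block, "': ",
           paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    bin_width = bin_width, hop = hop,
    filter = merge_block(list(sound_highpass_hz = 100, sound_order = 3L,
                              slow_lowpass_hz = 2000, slow_order = 3L),
                         filter, "filter"),
    f0 = if (inherits(f0, "f0_config")) f0 else do.call(f0_config, f0),
    we = merge_block(list(fft_size = 2048L, overlap = 1024L, fmax = 10000),
                     we, "we"),
    me = merge_block(list(solid_angle_factor = 4, flow_floor = 1e-7),
                     me, "me"),
    ptp = merge_block(list(noise_floor_multiple = 6, absolute_floor = 0.25e-3,
                           guard_bins = 10L),
                      ptp, "ptp"),
    map = merge_block(list(pb_step = 0.1, picas_step = 0.25), map, "map"),
    fits = merge_block(list(breakpoint = 0.75, upper_limit = 2.0),
                       fits, "fits"),
    segment = merge_block(list(pb_on = 0.05, picas_tolerance = 0.05,
                               min_bins = 50L),
                          segment, "segment"))
  stopifnot(cfg$hop > 0, cfg$bin_width >= cfg$hop,
            cfg$filter$sound_highpass_hz > 0, cfg$filter$slow_lowpass_hz > 0,
            cfg$ptp$noise_floor_multiple > 0, cfg$ptp$absolute_floor > 0,
            cfg$map$pb_step > 0, cfg$map$picas_step > 0,
            cfg$fits$breakpoint > 0,
            cfg$fits$breakpoint < cfg$fits$upper_limit)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("bin_width", "hop", "filter", "f0", "we", "me", "ptp", "map",
             "fits", "segment")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, raw)
}
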