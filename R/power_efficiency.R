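#' Radiated acoustic power
#'
#' `P_acoustic = solid_angle_factor * pi * r^2 * p_rms^2 / (rho * v)`. The
#' default `solid_angle_factor = 4` reproduces the conventional
#' `4 pi r^2 p^2 / (rho v)` form; a factor of 2 is available for a literal
#' half-sphere radiation assumption. The factor is deliberately exposed
#' rather than fixed.
#'
#' @param p_rms RMS sound pressure at the microphone (Pa), >= 0.
#' @param r Microphone distance (m), > 0.
#' @param rho Air density (kg m^-3), > 0.
#' @param v Speed of sound (m s^-1), > 0.
#' @param solid_angle_factor Dimensionless radiation factor, default 4.
#' @return Acoustic power (W).
#' @export
acoustic_power <- function(p_rms, r = 0.15, rho = 1.2, v = 344,
                           solid_angle_factor = 4) {
  if (r <= 0 || rho <= 0 || v <= 0 || solid_angle_factor <= 0)
    stop("r, rho, v and solid_angle_factor must be > 0")
  if (any(p_rms < 0, na.rm = TRUE)) stop("p_rms must be >= 0")
  solid_angle_factor * pi * r^2 * p_rms^2 / (rho * v)
}

#' Aerodynamic power of the driving airflow
#'
#' `P_aerodynamic = p_b * V` with the bronchial pressure in Pa (callers
#' convert kPa to Pa at this boundary) and the volumetric flow in m^3 s^-1.
#'
#' @param p_b Bronchial pressure (Pa), >= 0.
#' @param flow Volumetric flow (m^3 s^-1), >= 0; back-flow is excluded
#'   upstream and rejected here.
#' @return Aerodynamic power (W).
#' @export
aerodynamic_power <- function(p_b, flow) {
  if (any(p_b < 0, na.rm = TRUE)) stop("p_b must be >= 0 (in Pa)")
  if (any(flow < 0, na.rm = TRUE)) stop("negative flow (back-flow) not allowed")
  p_b * flow
}

#' Mechanical efficiency of sound production
#'
#' `ME = 10 log10(P_acoustic / P_aerodynamic)` (dB): the fraction of the
#' power carried by the driving airflow that is radiated as sound.
#'
#' @param P_acoustic Acoustic power (W), >= 0.
#' @param P_aerodynamic Aerodynamic power (W); non-positive values yield
#'   missing ME (vectorized, so degenerate bins are dropped, not fatal).
#' @return ME (dB); `NA` where undefined, `-Inf` where `P_acoustic` is 0.
#' @export
mechanical_efficiency <- function(P_acoustic, P_aerodynamic) {
  if (any(P_acoustic < 0, na.rm = TRUE)) stop("P_acoustic must be >= 0")
  out <- rep(NA_real_, length(P_acoustic))
  ok <- !is.na(P_aerodynamic) & P_aerodynamic > 0 & !is.na(P_acoustic)
  out[ok] <- 10 * log10(P_acoustic[ok] / P_aerodynamic[ok])
  out
}
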