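#' Acquisition metadata for a multichannel recording
#'
#' Holds the calibration constants needed to convert the raw channels into
#' source-referenced acoustic quantities: microphone distance, reference sound
#' pressure, air density and speed of sound.
#'
#' @param subject_id Subject identifier.
#' @param side Hemi-syrinx side, `"left"` or `"right"`.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param age_dph Age in days post hatch, or `NA` if unknown.
#' @param mic_distance_r Microphone distance from the tracheal outlet (m).
#' @param ref_pressure_P0 Reference sound pressure (Pa), 20 uPa in air.
#' @param air_density_rho Air density (kg m^-3).
#' @param sound_speed_v Speed of sound (m s^-1).
#' @return A `recording_meta` list.
#' @export
recording_meta <- function(subject_id = "unknown",
                           side = c("left", "right"),
                           sex = c("unknown", "male", "female"),
                           age_dph = NA_integer_,
                           mic_distance_r = 0.15,
                           ref_pressure_P0 = 20e-6,
                           air_density_rho = 1.2,
                           sound_speed_v = 344) {
  side <- match.arg(side)
  sex <- match.arg(sex)
  stopifnot(mic_distance_r > 0, ref_pressure_P0 > 0,
            air_density_rho > 0, sound_speed_v > 0)
  structure(
    list(subject_id = as.character(subject_id), side = side, sex = sex,
         age_dph = as.integer(age_dph), mic_distance_r = mic_distance_r,
         ref_pressure_P0 = ref_pressure_P0, air_density_rho = air_density_rho,
         sound_speed_v = sound_speed_v),
    class = "recording_meta")
}

#' Synchronized multichannel recording
#'
#' Container for one run: sound pressure (Pa), bronchial pressure `p_b` (kPa),
#' interclavicular air-sac pressure `p_icas` (kPa) and volumetric flow
#' (m^3 s^-1), sampled synchronously.
#'
#' @param sound Sound pressure series (Pa).
#' @param p_b Bronchial pressure series (kPa).
#' @param p_icas Air-sac pressure series (kPa).
#' @param flow Volumetric flow series (m^3 s^-1).
#' @param sample_rate Sample rate (Hz).
#' @param meta A [recording_meta()] object.
#' @return A `multichannel_recording` object.
#' @export
multichannel_recording <- function(sound, p_b, p_icas, flow, sample_rate,
                                   meta = recording_meta()) {
  n <- length(sound)
  if (n < 1L) stop("channels must have length >= 1")
  if (length(p_b) != n || length(p_icas) != n || length(flow) != n)
    stop("integrity error: channel lengths differ (sound=", n,
         ", p_b=", length(p_b), ", p_icas=", length(p_icas),
         ", flow=", length(flow), ")")
  if (!is.numeric(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be > 0")
  if (!inherits(meta, "recording_meta")) stop("meta must be a recording_meta")
  structure(
    list(sample_rate = as.numeric(sample_rate),
         sound = as.numeric(sound), p_b = as.numeric(p_b),
         p_icas = as.numeric(p_icas), flow = as.numeric(flow),
         meta = meta),
    class = "multichannel_recording")
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf(
    "<multichannel_recording> %d samples @ %g Hz (%.2f s), subject %s/%s\n",
    length(x$sound), x$sample_rate, length(x$sound) / x$sample_rate,
    x$meta$subject_id, x$meta$side))
  invisible(x)
}

# ---- minimal RIFF/WAVE float32 layer -------------------------------------
# No installed R package reads or writes WAV here, so the package carries a
# minimal IEEE-float (format code 3) multichannel implementation. Channel
# semantics and units live in the JSON sidecar, never in channel order alone.

.wav_channel_order <- c("sound", "p_b", "p_icas", "flow")

write_wav_float32 <- function(channels, sample_rate, path) {
  n_chan <- length(channels)
  n <- length(channels[[1L]])
  inter <- as.numeric(do.call(rbind, channels))  # interleaved frames
  data_bytes <- n * n_chan * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(18L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")        # IEEE float
  writeBin(n_chan, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_chan * 4L), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_chan * 4L), con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")        # cbSize
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(inter, con, size = 4, endian = "little")
  invisible(path)
}

read_wav_float32 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("format error: not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("format error: not WAVE")
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        code = readBin(con, integer(), size = 2, endian = "little"),
        n_chan = readBin(con, integer(), size = 2, endian = "little"),
        sample_rate = readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, raw(), n = sz - 8L))
    } else if (identical(id, "data")) {
      dat <- readBin(con, numeric(), n = sz %/% 4L, size = 4,
                     endian = "little")
      break
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("format error: missing fmt/data chunk")
  if (fmt$code != 3L) stop("format error: only IEEE float WAV supported")
  m <- matrix(dat, nrow = fmt$n_chan)
  list(channels = lapply(seq_len(fmt$n_chan), function(i) m[i, ]),
       sample_rate = fmt$sample_rate, n_chan = fmt$n_chan)
}

sidecar_path <- function(path) sub("\\.wav$", ".json", path)

#' Write a recording as a float32 WAV plus JSON sidecar
#'
#' The waveform file holds the four channels interleaved as 32-bit IEEE
#' floats; the sidecar documents channel names, units, sample rate and the
#' calibration metadata. Pressures are stored in kPa, sound in Pa, flow in
#' m^3 s^-1 (no rescaling on either side of the round trip).
#'
#' @param rec A [multichannel_recording()].
#' @param path Output path ending in `.wav`; the sidecar is written next to
#'   it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "multichannel_recording"))
  if (!grepl("\\.wav$", path)) path <- paste0(path, ".wav")
  write_wav_float32(rec[.wav_channel_order], rec$sample_rate, path)
  sidecar <- list(
    format = "syrinxspace-recording",
    sample_rate = rec$sample_rate,
    channels = .wav_channel_order,
    units = list(sound = "Pa", p_b = "kPa", p_icas = "kPa",
                 flow = "m3 s-1"),
    meta = unclass(rec$meta))
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the `.wav` file; the `.json` sidecar must sit next to
#'   it. Channel identity is taken from the sidecar, never guessed from
#'   position.
#' @return A [multichannel_recording()].
#' @export
read_recording <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path))
    stop("missing metadata sidecar: ", sc_path,
         " (units are never assumed)")
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  wav <- read_wav_float32(path)
  chan_names <- as.character(sc$channels)
  if (wav$n_chan != length(chan_names))
    stop("integrity error: sidecar declares ", length(chan_names),
         " channels but file holds ", wav$n_chan)
  missing <- setdiff(.wav_channel_order, chan_names)
  if (length(missing))
    stop("format error: missing channel(s): ",
         paste(missing, collapse = ", "))
  names(wav$channels) <- chan_names
  meta <- do.call(recording_meta, sc$meta[names(sc$meta) != "age_dph"])
  age <- suppressWarnings(as.integer(sc$meta$age_dph))
  meta$age_dph <- if (length(age) == 1L) age else NA_integer_
  multichannel_recording(
    sound = wav$channels$sound, p_b = wav$channels$p_b,
    p_icas = wav$channels$p_icas, flow = wav$channels$flow,
    sample_rate = sc$sample_rate, meta = meta)
}

#' Export a binned feature table as CSV
#'
#' One row per analysis bin, comma-separated, UTF-8, with a mandatory header.
#' Missing values (for example gated fundamental frequency) are written as
#' empty fields, never as 0. Column order is fixed:
#' `bin_center_t, rms_sound, p_b, p_icas, flow, p_t, f_o, aperiodicity,
#' SL, WE, ME`.
#'
#' @param features A `binned_features` data frame from [assemble_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  cols <- c("bin_center_t", "rms_sound", "p_b", "p_icas", "flow", "p_t",
            "f_o", "aperiodicity", "SL", "WE", "ME")
  stopifnot(all(cols %in% names(features)))
  out <- as.data.frame(features)[, cols]
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return A data frame with empty fields restored as `NA`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"),
                        fileEncoding = "UTF-8")
  df[] <- lapply(df, as.numeric)
  df
}
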