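#' Optical and acquisition geometry configuration
#'
#' Bundles the optical parameters of the in-line holographic recording and the
#' microchannel geometry. Defaults reproduce the reference acquisition: 635 nm
#' laser, 20x magnification giving 1 um/pixel over an 800 x 800 px field of
#' view, hologram plane 200 um below the channel floor, reconstruction planes
#' every 5 um through a 330 um deep channel, and a sheath-confined sample core
#' about 500 um wide in the 800 um wide channel.
#'
#' @param wavelength Laser wavelength in vacuum, um.
#' @param pixel_pitch Object-plane pixel size, um/px.
#' @param fov_px Field of view in pixels, `c(rows, cols)` = (y, x).
#' @param recording_distance Distance from channel floor to hologram plane, um.
#' @param plane_spacing Axial spacing between reconstruction planes, um.
#' @param channel_width Channel width (cross-stream, y), um.
#' @param channel_height Channel depth (axial, z), um.
#' @param sample_core_width Width of the sheath-confined sample core, um.
#' @param medium_refractive_index Refractive index of the suspending medium;
#'   propagation uses the effective in-medium wavelength.
#'
#' @return An object of class `optical_config`.
#' @examples
#' opt <- optical_config()
#' max(plane_distances(opt))  # 530 um: recording distance + channel depth
#' @export
optical_config <- function(wavelength = 0.635,
                           pixel_pitch = 1,
                           fov_px = c(800L, 800L),
                           recording_distance = 200,
                           plane_spacing = 5,
                           channel_width = 800,
                           channel_height = 330,
                           sample_core_width = 500,
                           medium_refractive_index = 1.33) {
  fov_px <- as.integer(rep_len(fov_px, 2L))
  lens <- c(wavelength = wavelength, pixel_pitch = pixel_pitch,
            recording_distance = recording_distance,
            plane_spacing = plane_spacing, channel_width = channel_width,
            channel_height = channel_height,
            sample_core_width = sample_core_width)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths in optical_config must be finite and > 0")
  if (any(fov_px < 4L)) stop("fov_px too small")
  if (sample_core_width > channel_width)
    stop("sample_core_width must not exceed channel_width")
  if (medium_refractive_index < 1) stop("medium_refractive_index must be >= 1")
  structure(list(
    wavelength = wavelength, pixel_pitch = pixel_pitch, fov_px = fov_px,
    recording_distance = recording_distance, plane_spacing = plane_spacing,
    channel_width = channel_width, channel_height = channel_height,
    sample_core_width = sample_core_width,
    medium_refractive_index = medium_refractive_index
  ), class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat("In-line holography configuration\n")
  cat(sprintf("  wavelength: %g um (n = %g), pixel pitch: %g um/px, FOV: %d x %d px\n",
              x$wavelength, x$medium_refractive_index, x$pixel_pitch,
              x$fov_px[1], x$fov_px[2]))
  cat(sprintf("  recording distance: %g um, plane spacing: %g um (%d planes)\n",
              x$recording_distance, x$plane_spacing, length(plane_distances(x))))
  cat(sprintf("  channel W x H: %g x %g um, sample core: %g um\n",
              x$channel_width, x$channel_height, x$sample_core_width))
  invisible(x)
}

#' Flow and acquisition-rate configuration
#'
#' Sample and sheath volumetric flow rates and the camera frame rate. Defaults
#' give the reference operating point: 2.5 mL/min sample flow flanked by two
#' 0.5 mL/min sheath streams (3.5 mL/min total) recorded at 420 fps, where
#' 10100 frames sample 1 mL of suspension.
#'
#' @param sample_flow_rate Sample stream flow rate, mL/min.
#' @param sheath_flow_rate_per_stream Flow rate of each sheath stream, mL/min.
#' @param n_sheath_streams Number of sheath streams.
#' @param frame_rate Camera frame rate, frames/s.
#' @param n_frames Default number of frames per acquisition.
#' @return An object of class `flow_config` with derived field
#'   `total_flow_rate` (mL/min).
#' @examples
#' fl <- flow_config()
#' fl$total_flow_rate  # 3.5 mL/min
#' @export
flow_config <- function(sample_flow_rate = 2.5,
                        sheath_flow_rate_per_stream = 0.5,
                        n_sheath_streams = 2L,
                        frame_rate = 420,
                        n_frames = 10100L) {
  if (sample_flow_rate <= 0 || sheath_flow_rate_per_stream < 0)
    stop("flow rates must be positive")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  structure(list(
    sample_flow_rate = sample_flow_rate,
    sheath_flow_rate_per_stream = sheath_flow_rate_per_stream,
    n_sheath_streams = as.integer(n_sheath_streams),
    total_flow_rate = sample_flow_rate +
      n_sheath_streams * sheath_flow_rate_per_stream,
    frame_rate = frame_rate,
    n_frames = as.integer(n_frames)
  ), class = "flow_config")
}

#' @export
print.flow_config <- function(x, ...) {
  cat(sprintf("Flow: sample %g + %d x %g sheath = %g mL/min; %g fps, %d frames\n",
              x$sample_flow_rate, x$n_sheath_streams,
              x$sheath_flow_rate_per_stream, x$total_flow_rate,
              x$frame_rate, x$n_frames))
  invisible(x)
}

#' Multiple-count removal criteria
#'
#' Proximity thresholds used to recognize the same cell detected again in the
#' next frame: cross-stream agreement within `dy_max` and axial agreement
#' within `dz_max`. The axial criterion is deliberately lenient because axial
#' localization is less precise than lateral localization.
#'
#' @param dy_max Maximum cross-stream displacement between frames, um.
#' @param dz_max Maximum axial displacement between frames, um.
#' @param max_frame_gap Frame separation over which duplicates are sought
#'   (1 = consecutive frames only).
#' @return An object of class `dedup_config`.
#' @export
dedup_config <- function(dy_max = 3, dz_max = 50, max_frame_gap = 1L) {
  if (dy_max <= 0 || dz_max <= 0 || max_frame_gap < 1)
    stop("dedup thresholds must be positive")
  structure(list(dy_max = dy_max, dz_max = dz_max,
                 max_frame_gap = as.integer(max_frame_gap)),
            class = "dedup_config")
}

#' Reconstruction plane distances
#'
#' Propagation distances of the reconstruction planes, spanning from the
#' channel floor (the recording distance) to the channel ceiling in steps of
#' `plane_spacing`, both endpoints included. The default geometry yields 67
#' planes from 200 um to 530 um.
#'
#' @param optics An [optical_config()].
#' @return Numeric vector of propagation distances, um.
#' @export
plane_distances <- function(optics) {
  seq(optics$recording_distance,
      optics$recording_distance + optics$channel_height,
      by = optics$plane_spacing)
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON) file with optional `optics`, `flow` and `dedup`
#' sections whose entries mirror the arguments of [optical_config()],
#' [flow_config()] and [dedup_config()]; omitted entries keep their defaults.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return List with elements `optics`, `flow`, `dedup` and any extra sections
#'   passed through untouched.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  out <- cfg
  out$optics <- do.call(optical_config, as.list(cfg$optics))
  out$flow <- do.call(flow_config, as.list(cfg$flow))
  out$dedup <- do.call(dedup_config, as.list(cfg$dedup))
  out
}
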