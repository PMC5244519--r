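# Stimulus and screen-geometry model for phase-encoded retinotopic mapping.
#
# Conventions used throughout the package:
#   * Screen pixel coordinates are continuous, origin at the top-left corner,
#     x increasing rightward, y increasing DOWNWARD (image convention).
#     The screen center is (width_px/2, height_px/2).
#   * Azimuth is positive toward increasing screen x, 0 at screen center.
#   * Elevation is positive upward, 0 at screen center.
#   * Response phase increases with time-of-response within the stimulus
#     cycle: a pixel responding at cycle time t has phase 2*pi*t/period.

#' Screen geometry for visual stimulation
#'
#' Describes the stimulation monitor and its placement relative to the eye.
#' The eye is assumed to sit on the screen-center normal at `distance_cm`,
#' with the screen tilted `tilt_deg` from vertical toward the animal
#' (rotation about the horizontal axis through the screen center).
#'
#' The default corresponds to a 27-inch 2560x1440 panel (active area
#' 596.7 x 335.7 mm) at 20 cm, tilted 17.5 degrees, which covers roughly
#' 110 x 75 degrees of visual field.
#'
#' @param width_px,height_px Screen resolution in pixels.
#' @param width_mm,height_mm Physical active-area size in mm.
#' @param distance_cm Perpendicular eye-to-screen-center distance in cm.
#' @param tilt_deg Tilt from vertical toward the animal, degrees.
#' @return An object of class `screen_geometry`.
#' @export
screen_geometry <- function(width_px = 2560L, height_px = 1440L,
                            width_mm = 596.7, height_mm = 335.7,
                            distance_cm = 20, tilt_deg = 17.5) {
  stopifnot(width_px > 0, height_px > 0, width_mm > 0, height_mm > 0,
            distance_cm > 0)
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 width_mm = width_mm, height_mm = height_mm,
                 distance_cm = distance_cm, tilt_deg = tilt_deg),
            class = "screen_geometry")
}

#' Periodic visual stimulus specification
#'
#' Three stimulus kinds are supported: a bar sweeping horizontally
#' (`bar_azimuth`), a bar sweeping vertically (`bar_elevation`), and a
#' central grating patch whose drift velocity steps within each cycle
#' (`grating_patch`). All are periodic with cycle length `period_s`;
#' the stimulus frequency is `1/period_s`.
#'
#' Defaults follow a standard widefield mapping protocol: 8-s cycles,
#' 50 cycles per run; azimuth sweep covering 110 degrees, elevation sweep
#' covering 75 degrees; grating patch 50 degrees in diameter at
#' 0.04 cycles/degree, drifting at 0 deg/s for 6 s then 50 deg/s for 2 s.
#'
#' @param kind One of `"bar_azimuth"`, `"bar_elevation"`, `"grating_patch"`.
#' @param period_s Cycle duration, seconds.
#' @param n_cycles Number of stimulus cycles in a run.
#' @param sweep_range_deg Length-2 numeric, degrees swept by bar kinds.
#' @param patch_diameter_deg Grating patch diameter, degrees.
#' @param spatial_freq_cpd Grating spatial frequency, cycles/degree.
#' @param velocity_profile List of `c(duration_s, deg_per_s)` pairs; their
#'   durations must sum to `period_s` (grating kind only).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("bar_azimuth", "bar_elevation",
                                   "grating_patch"),
                          period_s = 8, n_cycles = 50L,
                          sweep_range_deg = NULL,
                          patch_diameter_deg = 50,
                          spatial_freq_cpd = 0.04,
                          velocity_profile = list(c(6, 0), c(2, 50))) {
  kind <- match.arg(kind)
  stopifnot(period_s > 0, n_cycles >= 1)
  if (is.null(sweep_range_deg)) {
    sweep_range_deg <- switch(kind,
      bar_azimuth   = c(-55, 55),
      bar_elevation = c(-37.5, 37.5),
      grating_patch = NULL)
  }
  if (kind == "grating_patch") {
    durs <- vapply(velocity_profile, `[`, numeric(1), 1L)
    if (abs(sum(durs) - period_s) > 1e-9) {
      stop("velocity_profile durations must sum to period_s")
    }
  } else {
    if (length(sweep_range_deg) != 2L || !is.numeric(sweep_range_deg)) {
      stop("bar stimuli need a length-2 numeric sweep_range_deg")
    }
  }
  structure(list(kind = kind, period_s = period_s,
                 n_cycles = as.integer(n_cycles),
                 sweep_range_deg = sweep_range_deg,
                 patch_diameter_deg = patch_diameter_deg,
                 spatial_freq_cpd = spatial_freq_cpd,
                 velocity_profile = velocity_profile),
            class = "stimulus_spec")
}

#' Stimulus frequency of a periodic stimulus
#' @param spec A [stimulus_spec()].
#' @return Frequency in Hz (`1/period_s`).
#' @export
stimulus_frequency <- function(spec) 1 / spec$period_s

#' Convert screen pixel coordinates to visual angle
#'
#' Applies the flat-screen arctangent correction: a point at horizontal
#' offset `x` mm and vertical offset `y` mm from the screen center, viewed
#' from distance `d`, has azimuth `atan(x/d)` and elevation
#' `atan(y'/sqrt(x^2 + z^2))` where `(y', z)` are the point's vertical and
#' depth coordinates after rotating the screen plane by `tilt_deg` about
#' the horizontal axis (top of the screen moves toward the eye).
#'
#' @param px Numeric length-2 `(x_px, y_px)` or an n-by-2 matrix of pixel
#'   coordinates (top-left origin, y down).
#' @param geom A [screen_geometry()].
#' @return Named numeric `(azimuth_deg, elevation_deg)`, or an n-by-2 matrix.
#' @export
pixel_to_visual_degrees <- function(px, geom) {
  p <- if (is.matrix(px)) px else matrix(px, ncol = 2L)
  if (any(p[, 1] < 0 | p[, 1] > geom$width_px |
          p[, 2] < 0 | p[, 2] > geom$height_px)) {
    stop("pixel coordinates out of screen bounds")
  }
  mm_x <- geom$width_mm / geom$width_px
  mm_y <- geom$height_mm / geom$height_px
  x <- (p[, 1] - geom$width_px / 2) * mm_x
  y_up <- (geom$height_px / 2 - p[, 2]) * mm_y       # up-positive
  d <- geom$distance_cm * 10                          # mm
  th <- geom$tilt_deg * pi / 180
  # rotate screen plane about horizontal axis: top toward the eye
  y_r <- y_up * cos(th)
  z_r <- d - y_up * sin(th)
  azi <- atan2(x, z_r) * 180 / pi
  ele <- atan2(y_r, sqrt(x^2 + z_r^2)) * 180 / pi
  out <- cbind(azimuth_deg = azi, elevation_deg = ele)
  if (is.matrix(px)) out else c(azimuth_deg = azi, elevation_deg = ele)
}

#' Bar position at a given time
#'
#' The bar sweeps linearly from `sweep_range_deg[1]` to `sweep_range_deg[2]`
#' over one period and wraps.
#'
#' @param t Time in seconds (vectorized; may exceed one period).
#' @param spec A bar-kind [stimulus_spec()].
#' @return Swept position in degrees.
#' @export
stimulus_position_at <- function(t, spec) {
  if (spec$kind == "grating_patch") {
    stop("stimulus_position_at is undefined for grating_patch stimuli")
  }
  u <- t %% spec$period_s
  r <- spec$sweep_range_deg
  r[1] + (r[2] - r[1]) * u / spec$period_s
}

#' Grating drift velocity at a given time
#'
#' Piecewise-constant lookup within the cycle of the grating's velocity
#' profile.
#'
#' @param t Time in seconds, `>= 0` (vectorized).
#' @param spec A `grating_patch` [stimulus_spec()].
#' @return Drift velocity in deg/s.
#' @export
grating_velocity_at <- function(t, spec) {
  if (spec$kind != "grating_patch") stop("spec is not a grating_patch")
  if (any(t < 0)) stop("negative time")
  u <- t %% spec$period_s
  durs <- vapply(spec$velocity_profile, `[`, numeric(1), 1L)
  vels <- vapply(spec$velocity_profile, `[`, numeric(1), 2L)
  edges <- cumsum(durs)
  idx <- findInterval(u, c(0, edges), rightmost.closed = FALSE,
                      left.open = TRUE)
  idx[u == 0] <- 1L
  idx[idx > length(vels)] <- length(vels)
  vels[idx]
}

#' Convert response phase to time within the stimulus cycle
#'
#' Phase increases with time-of-response within the cycle;
#' `t = (phase/(2*pi) * period_s - delay_s) mod period_s`. The delay is the
#' hemodynamic lag between the driving stimulus and the optical response
#' (plus any fixed waveform offset), which appears as a constant phase
#' offset and is subtracted here.
#'
#' @param phase_rad Response phase in radians (vectorized).
#' @param spec A [stimulus_spec()].
#' @param delay_s Response delay in seconds (default 0).
#' @return Time within the cycle, seconds, in `[0, period_s)`.
#' @export
phase_to_stimulus_time <- function(phase_rad, spec, delay_s = 0) {
  (phase_rad / (2 * pi) * spec$period_s - delay_s) %% spec$period_s
}

# --- JSON (de)serialization of the metadata sidecar -------------------------

SIDECAR_SCHEMA_VERSION <- "1.0"

#' Serialize stimulus and geometry metadata to a JSON sidecar
#'
#' @param spec A [stimulus_spec()].
#' @param geom A [screen_geometry()].
#' @param extra Named list of additional metadata (animal id, frame rate,
#'   frame count, ...).
#' @param path Output file path.
#' @export
write_sidecar <- function(spec, geom, extra = list(), path) {
  obj <- c(list(schema_version = SIDECAR_SCHEMA_VERSION,
                stimulus = unclass(spec),
                screen = unclass(geom)),
           extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON metadata sidecar
#'
#' @param path Sidecar file path.
#' @return List with elements `stimulus` ([stimulus_spec()]), `screen`
#'   ([screen_geometry()]), and any extra metadata fields.
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) stop("missing sidecar: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (is.null(obj$schema_version)) stop("sidecar has no schema_version")
  s <- obj$stimulus
  vp <- s$velocity_profile
  if (!is.null(vp)) vp <- lapply(vp, as.numeric)
  spec <- stimulus_spec(kind = s$kind, period_s = s$period_s,
                        n_cycles = s$n_cycles,
                        sweep_range_deg = unlist(s$sweep_range_deg),
                        patch_diameter_deg = s$patch_diameter_deg %||% 50,
                        spatial_freq_cpd = s$spatial_freq_cpd %||% 0.04,
                        velocity_profile = vp %||% list(c(6, 0), c(2, 50)))
  g <- obj$screen
  geom <- screen_geometry(g$width_px, g$height_px, g$width_mm, g$height_mm,
                          g$distance_cm, g$tilt_deg)
  extra <- obj[setdiff(names(obj), c("schema_version", "stimulus", "screen"))]
  c(list(stimulus = spec, screen = geom), extra)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
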