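# Per-pixel Fourier analysis at the stimulus frequency.
#
# Phase convention (used everywhere): the coefficient is the single-bin
# discrete Fourier sum of the mean-subtracted pixel time course under the
# e^{+i 2 pi f t} kernel,
#     coeff[p] = (2/T) * sum_t x_p[t] * exp(+i 2 pi f t_k),
# so the phase of a response peaking at cycle time t0 is +2*pi*f*t0: phase
# increases with time-of-response, and phase_to_stimulus_time() inverts it
# directly. The intrinsic signal is a reflectance DIP on activation;
# passing `invert = TRUE` analyses (mean - x) so that phase tracks the
# activation peak rather than the reflectance minimum shifted by pi.

#' Extract the per-pixel complex response at the stimulus frequency
#'
#' @param movie A [binned_movie()] or [raw_movie()].
#' @param f_stim_hz Stimulus frequency, Hz; must be below the movie's
#'   Nyquist frequency, and the movie must cover at least 2 cycles.
#' @param invert Analyse `mean - x` instead of `x - mean` (intrinsic-dip
#'   convention; default FALSE).
#' @param t0_offset_s Time assigned to the first frame (e.g. the binning
#'   centroid offset `(t_bin - 1) / (2 * raw_rate)`; default 0).
#' @return An object of class `complex_response_map`: `coeff` (H x W
#'   complex), `f_stim_hz`, `n_frames_used`, `mean_image`,
#'   `frame_rate_hz`.
#' @export
extract_response <- function(movie, f_stim_hz, invert = FALSE,
                             t0_offset_s = 0) {
  stopifnot(inherits(movie, c("binned_movie", "raw_movie")))
  d <- dim(movie$data)
  h <- d[1]; w <- d[2]; nt <- d[3]
  rate <- movie$frame_rate_hz
  if (f_stim_hz >= rate / 2) {
    stop("f_stim at or above the Nyquist frequency of the movie")
  }
  if (nt / rate < 2 / f_stim_hz) {
    stop("movie covers fewer than 2 stimulus cycles")
  }
  x <- matrix(as.numeric(movie$data), h * w, nt)
  mean_px <- rowMeans(x)
  xc <- x - mean_px
  if (invert) xc <- -xc
  tk <- (seq_len(nt) - 1L) / rate + t0_offset_s
  re <- as.vector(xc %*% cos(2 * pi * f_stim_hz * tk)) * (2 / nt)
  im <- as.vector(xc %*% sin(2 * pi * f_stim_hz * tk)) * (2 / nt)
  structure(list(coeff = matrix(complex(real = re, imaginary = im), h, w),
                 f_stim_hz = f_stim_hz, n_frames_used = nt,
                 mean_image = matrix(mean_px, h, w),
                 frame_rate_hz = rate),
            class = "complex_response_map")
}

#' Magnitude map of a complex response
#'
#' @param map A [extract_response()] result.
#' @param fractional Divide by the pixel's temporal mean (delta R / R-like
#'   units, the default); `FALSE` returns raw counts.
#' @return `H x W` numeric magnitude matrix.
#' @export
response_magnitude <- function(map, fractional = TRUE) {
  m <- Mod(map$coeff)
  if (fractional) m / pmax(map$mean_image, .Machine$double.eps) else m
}

#' Phase map of a complex response
#'
#' @param map A [extract_response()] result.
#' @return `H x W` phase matrix in `[-pi, pi)`.
#' @export
response_phase <- function(map) {
  ((Arg(map$coeff) + pi) %% (2 * pi)) - pi
}

#' Convert azimuth/elevation phase maps to retinotopy in degrees
#'
#' Per pixel: phase -> time within the sweep cycle (subtracting
#' `delay_s`) -> swept bar position in degrees.
#'
#' @param azi_map,elev_map [extract_response()] results for the azimuth
#'   and elevation bar runs (same shape).
#' @param azi_spec,elev_spec The matching bar [stimulus_spec()]s.
#' @param delay_s Response delay subtracted from the phase-encoded time
#'   (hemodynamic delay plus any fixed acquisition offset).
#' @return An object of class `retinotopy_pair`: `azimuth_deg`,
#'   `elevation_deg` (`H x W`), `delay_s`.
#' @export
retinotopy_from_phases <- function(azi_map, elev_map, azi_spec, elev_spec,
                                   delay_s = 0) {
  if (!identical(dim(azi_map$coeff), dim(elev_map$coeff))) {
    stop("azimuth and elevation maps have different shapes")
  }
  stopifnot(azi_spec$kind == "bar_azimuth", elev_spec$kind == "bar_elevation")
  azi_t <- phase_to_stimulus_time(response_phase(azi_map), azi_spec, delay_s)
  ele_t <- phase_to_stimulus_time(response_phase(elev_map), elev_spec,
                                  delay_s)
  d <- dim(azi_map$coeff)
  structure(list(
    azimuth_deg = matrix(stimulus_position_at(azi_t, azi_spec), d[1], d[2]),
    elevation_deg = matrix(stimulus_position_at(ele_t, elev_spec),
                           d[1], d[2]),
    azimuth_range_deg = azi_spec$sweep_range_deg,
    elevation_range_deg = elev_spec$sweep_range_deg,
    delay_s = delay_s), class = "retinotopy_pair")
}

#' Map fidelity: spectral SNR at the stimulus frequency
#'
#' Per-pixel ratio of DFT power at the stimulus frequency to the mean
#' power in a flanking frequency band (stimulus-harmonic bins excluded),
#' averaged over all well-illuminated pixels (the darkest
#' `dark_quantile` of the mean image is dropped, standing in for
#' non-tissue pixels). A movie with no stimulus-locked signal scores ~1;
#' experiments scoring below the configured threshold are excluded by
#' [run_animal()], mirroring the exclusion of animals for which no
#' high-fidelity retinotopic map is obtainable.
#'
#' @param movie A [binned_movie()] or [raw_movie()].
#' @param f_stim_hz Stimulus frequency, Hz.
#' @param flank_bins DFT-bin offsets forming the flanking band (default
#'   2..8 on both sides of the stimulus bin).
#' @param dark_quantile Quantile of the mean image below which pixels are
#'   dropped (default 0.1).
#' @return Scalar SNR.
#' @export
map_fidelity <- function(movie, f_stim_hz, flank_bins = 2:8,
                         dark_quantile = 0.1) {
  d <- dim(movie$data)
  nt <- d[3]; rate <- movie$frame_rate_hz
  x <- matrix(as.numeric(movie$data), d[1] * d[2], nt)
  mean_px <- rowMeans(x)
  keep <- which(mean_px >= stats::quantile(mean_px, dark_quantile))
  xc <- x[keep, , drop = FALSE] - mean_px[keep]
  k0 <- round(f_stim_hz * nt / rate)  # stimulus DFT bin
  # flank band sits ABOVE the stimulus bin: slow drift leaks into the
  # bins below it; stimulus-harmonic bins are excluded
  flank <- k0 + flank_bins
  flank <- flank[flank < nt / 2 & flank %% k0 != 0]
  ks <- c(k0, flank)
  tk <- (seq_len(nt) - 1L) / rate
  fk <- ks * rate / nt
  pw <- (xc %*% cos(2 * pi * tk %o% fk))^2 +
        (xc %*% sin(2 * pi * tk %o% fk))^2
  p_stim <- pw[, 1]
  flank_mean <- rowMeans(pw[, -1, drop = FALSE])
  mean(p_stim / pmax(flank_mean, .Machine$double.eps))
}
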