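# Shared fixtures, all generated in code.

# standard stimulus set at test length (10 cycles, the default test-movie
# protocol; 50 cycles is the full acquisition)
test_specs <- function(n_cycles = 10L) {
  list(azimuth = stimulus_spec("bar_azimuth", n_cycles = n_cycles),
       elevation = stimulus_spec("bar_elevation", n_cycles = n_cycles),
       grating = stimulus_spec("grating_patch", n_cycles = n_cycles))
}

# simulate the three movies for one animal and run the analysis stages up
# to segmentation; returns everything recovery tests need
simulate_and_analyze <- function(noise = no_noise(), seed0 = 1L,
                                 sheet = build_default_sheet(),
                                 n_cycles = 10L) {
  sp <- test_specs(n_cycles)
  sa <- simulate_movie(sheet, sp$azimuth, noise = noise, seed = seed0)
  se <- simulate_movie(sheet, sp$elevation, noise = noise, seed = seed0 + 1L)
  sg <- simulate_movie(sheet, sp$grating, noise = noise, seed = seed0 + 2L)
  off <- (4 - 1) / (2 * 30)  # binning centroid offset
  f <- stimulus_frequency(sp$azimuth)
  ma <- extract_response(bin_movie(sa$movie), f, invert = TRUE,
                         t0_offset_s = off)
  me <- extract_response(bin_movie(se$movie), f, invert = TRUE,
                         t0_offset_s = off)
  mg <- extract_response(bin_movie(sg$movie), f, invert = TRUE,
                         t0_offset_s = off)
  retino <- retinotopy_from_phases(ma, me, sp$azimuth, sp$elevation,
                                   delay_s = sheet$delay_s)
  mag <- response_magnitude(mg)
  mask <- responsive_mask(mag)
  seg <- segment_areas(field_sign(retino, mask = mask), mask)
  list(truth = sa$truth, movies = list(azi = sa$movie, elev = se$movie,
                                       grating = sg$movie),
       retino = retino, mag = mag, mask = mask, seg = seg,
       labels_binned = bin_label_image(sa$truth$label_image),
       specs = sp)
}

# 2x2-block average of a matrix (for comparing truth maps to the binned
# analysis grid)
bin2_mean <- function(m) {
  (m[seq(1, nrow(m), 2), seq(1, ncol(m), 2)] +
     m[seq(2, nrow(m), 2), seq(1, ncol(m), 2)] +
     m[seq(1, nrow(m), 2), seq(2, ncol(m), 2)] +
     m[seq(2, nrow(m), 2), seq(2, ncol(m), 2)]) / 4
}

# independent single-bin DFT oracle: literal discrete sum, e^{+i 2 pi f t}
oracle_dft <- function(x, f, rate, t0 = 0) {
  tk <- (seq_along(x) - 1) / rate + t0
  xc <- x - mean(x)
  (2 / length(x)) * sum(xc * exp(2i * pi * f * tk))
}

# independent quadrature oracle for the waveform's first-harmonic
# amplitude: midpoint rule on (2/P) integral of w(u) cos(2 pi u / P)
oracle_first_harmonic <- function(duty, period = 8, n = 20000) {
  u <- (seq_len(n) - 0.5) / n * period - period / 2
  w <- retinomapper::response_waveform(u, period, duty)
  (2 / period) * sum(w * cos(2 * pi * u / period)) * (period / n)
}

# tiny valid raw movie with given dims filled from a seeded RNG
random_raw_movie <- function(h = 6, w = 4, tt = 8, seed = 1,
                             max_val = 4095) {
  set.seed(seed)
  raw_movie(array(sample.int(max_val + 1L, h * w * tt, replace = TRUE) - 1L,
                  c(h, w, tt)),
            frame_rate_hz = 30,
            meta = list(stimulus = stimulus_spec("bar_azimuth",
                                                 n_cycles = 1),
                        screen = screen_geometry()))
}
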