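make_binned <- function(x_by_px, rate = 7.5) {
  # x_by_px: list of pixel time courses, laid out on a 1 x n grid
  nt <- length(x_by_px[[1]])
  arr <- array(0, c(1, length(x_by_px), nt))
  for (i in seq_along(x_by_px)) arr[1, i, ] <- x_by_px[[i]]
  binned_movie(arr, frame_rate_hz = rate)
}

test_that("pure tone recovers fractional magnitude and phase exactly", {
  rate <- 7.5; f <- 1 / 8; nt <- 8 * 10 * rate  # 10 integer cycles
  tk <- (seq_len(nt) - 1) / rate
  m <- 30000
  mv <- make_binned(list(m * (1 + 0.01 * cos(2 * pi * f * tk)),
                         rep(m, nt)))
  crm <- extract_response(mv, f)
  expect_equal(response_magnitude(crm)[1, 1], 0.01, tolerance = 1e-9)
  expect_equal(response_phase(crm)[1, 1], 0, tolerance = 1e-9)
  # constant pixel: zero magnitude
  expect_equal(response_magnitude(crm)[1, 2], 0, tolerance = 1e-12)
  # delayed tone: phase increases with time-of-response
  t0 <- 1.25
  mv2 <- make_binned(list(m * (1 + 0.01 * cos(2 * pi * f * (tk - t0)))))
  crm2 <- extract_response(mv2, f)
  expect_equal(response_phase(crm2)[1, 1], 2 * pi * f * t0,
               tolerance = 1e-9)
})

test_that("coefficients match the brute-force DFT oracle", {
  rate <- 7.5
  for (seed in 1:100) {
    set.seed(seed)
    nt <- sample(c(120, 180, 240), 1)
    f <- sample(c(1 / 8, 1 / 4, 0.3), 1)
    x <- runif(nt, 0, 65535)
    mv <- make_binned(list(x), rate)
    got <- extract_response(mv, f)$coeff[1, 1]
    want <- oracle_dft(x, f, rate)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("oracle DFT satisfies Parseval on full spectra", {
  set.seed(42)
  n <- 64
  x <- rnorm(n)
  xc <- x - mean(x)
  # full DFT via the same literal sum the oracle uses (unnormalized)
  co <- vapply(0:(n - 1), function(k)
    sum(xc * exp(2i * pi * k * (0:(n - 1)) / n)), complex(1))
  expect_equal(sum(Mod(co)^2) / n, sum(xc^2), tolerance = 1e-8)
})

test_that("delay equivariance and magnitude invariance hold", {
  rate <- 7.5; f <- 1 / 8; nt <- 240
  mv <- simulate_movie(build_default_sheet(), test_specs(4)$azimuth,
                       noise = noise_model(), seed = 5)$movie
  b <- bin_movie(mv)
  crm <- extract_response(b, f)
  for (k in c(3L, 11L)) {
    nb <- dim(b$data)[3]
    rolled <- binned_movie(b$data[, , c((nb - k + 1):nb, 1:(nb - k))],
                           frame_rate_hz = b$frame_rate_hz)
    crm_k <- extract_response(rolled, f)
    rot <- (response_phase(crm_k) - response_phase(crm)) %% (2 * pi)
    expected <- (2 * pi * f * k / rate) %% (2 * pi)
    # compare on pixels with meaningful magnitude (phase of ~0 vectors is
    # numerically undefined)
    strong <- Mod(crm$coeff) > stats::quantile(Mod(crm$coeff), 0.5)
    expect_lt(max(abs(rot[strong] - expected)), 1e-6)
    expect_equal(response_magnitude(crm_k), response_magnitude(crm),
                 tolerance = 1e-10)
  }
})

test_that("extract_response enforces its preconditions", {
  mv <- make_binned(list(rnorm(100, 1000)), rate = 7.5)
  expect_error(extract_response(mv, 4), "Nyquist")
  expect_error(extract_response(mv, 1 / 60), "2 stimulus cycles")
})

test_that("retinotopy boundary examples hold and shapes are checked", {
  sp <- test_specs(10)
  co <- matrix(complex(modulus = 1, argument = 0), 2, 2)
  mk_map <- function(arg) {
    structure(list(coeff = matrix(complex(modulus = 1, argument = arg),
                                  2, 2),
                   f_stim_hz = 1 / 8, n_frames_used = 600,
                   mean_image = matrix(1, 2, 2), frame_rate_hz = 7.5),
              class = "complex_response_map")
  }
  rt0 <- retinotopy_from_phases(mk_map(0), mk_map(0), sp$azimuth,
                                sp$elevation, delay_s = 0)
  expect_equal(rt0$azimuth_deg[1, 1], -55)
  rt_pi <- retinotopy_from_phases(mk_map(pi), mk_map(pi), sp$azimuth,
                                  sp$elevation, delay_s = 0)
  expect_equal(rt_pi$azimuth_deg[1, 1], 0)
  bad <- mk_map(0)
  bad$coeff <- matrix(bad$coeff[1], 3, 3)
  expect_error(retinotopy_from_phases(mk_map(0), bad, sp$azimuth,
                                      sp$elevation), "shapes")
})

test_that("map fidelity calibrates near 1 on white noise and grows with
           signal", {
  sheet0 <- build_default_sheet(amplitudes = c(V1 = 0, LM = 0, LI = 0,
                                               AL = 0, RL = 0, AMPM = 0))
  spec <- test_specs(4)$azimuth
  white <- noise_model(white_sigma = 50, drift_amp = 0, physio_amp = 0)
  snrs <- vapply(1:20, function(i) {
    map_fidelity(bin_movie(simulate_movie(sheet0, spec, noise = white,
                                          seed = i)$movie), 1 / 8)
  }, numeric(1))
  expect_true(all(abs(snrs - 1) < 0.5))

  # doubling response amplitude strictly increases fidelity (same noise)
  amps <- c(V1 = 0.004, LM = 0.003, LI = 0.003, AL = 0.003, RL = 0.003,
            AMPM = 0.003)
  s1 <- map_fidelity(bin_movie(simulate_movie(
    build_default_sheet(amplitudes = amps), spec, noise = white,
    seed = 9)$movie), 1 / 8)
  s2 <- map_fidelity(bin_movie(simulate_movie(
    build_default_sheet(amplitudes = amps * 2), spec, noise = white,
    seed = 9)$movie), 1 / 8)
  expect_gt(s2, s1)
  expect_gt(s1, 3)
})
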