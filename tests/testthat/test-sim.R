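test_that("default sheet has six areas with V1 largest and alternating
           mirror flags at shared borders", {
  sheet <- build_default_sheet()
  expect_length(sheet$areas, 6)
  nms <- vapply(sheet$areas, `[[`, character(1), "name")
  expect_setequal(nms, c("V1", "LM", "LI", "AL", "RL", "AMPM"))
  lab <- sheet_label_image(sheet)
  sizes <- tabulate(lab, 6)
  expect_equal(which.max(sizes), match("V1", nms))
  expect_true(all(sizes > 0))

  # field sign from the true retinotopy alternates between V1 and LM
  fs <- field_sign(sheet_retinotopy(sheet), smooth_sigma_px = 1)
  v1_core <- lab == match("V1", nms)
  lm_core <- lab == match("LM", nms)
  expect_gt(mean(fs$sign[v1_core] == 1), 0.9)
  expect_gt(mean(fs$sign[lm_core] == -1), 0.9)
})

test_that("um_per_px scales polygon areas quadratically", {
  a1 <- tabulate(sheet_label_image(build_default_sheet()), 6)
  a2 <- tabulate(sheet_label_image(build_default_sheet(um_per_px = 60)), 6)
  expect_equal(a2 / a1, rep(0.25, 6), tolerance = 0.08) # pixel rounding
})

test_that("invalid sheets are rejected", {
  mk <- retinomapper:::.rect_area
  base <- build_default_sheet()
  bad <- base
  bad$areas[[2]] <- mk("LM", c(60, 96), c(8, 38), TRUE, 0.006) # into V1
  expect_error(retinomapper:::.validate_sheet(bad), "overlapping")
  bad2 <- base
  bad2$areas[[2]]$mirror <- FALSE  # LM touches V1: same sign forbidden
  expect_error(retinomapper:::.validate_sheet(bad2), "mirror")
  expect_error(build_default_sheet(amplitudes = c(V1 = 0.2, LM = 0, LI = 0,
                                                  AL = 0, RL = 0,
                                                  AMPM = 0)))
})

test_that("simulated movies honor the forward model", {
  sheet0 <- build_default_sheet(amplitudes = c(V1 = 0, LM = 0, LI = 0,
                                               AL = 0, RL = 0, AMPM = 0))
  spec <- test_specs(2)$azimuth
  sim0 <- simulate_movie(sheet0, spec, noise = no_noise(), seed = 1)
  expect_true(all(sim0$movie$data == sheet0$baseline_counts))

  sheet <- build_default_sheet()
  sim <- simulate_movie(sheet, spec, noise = no_noise(), seed = 1)
  expect_true(all(sim$movie$data >= 0 & sim$movie$data <= 4095))
  expect_true(is.integer(sim$movie$data))
  expect_identical(sim$truth$label_image, sheet_label_image(sheet))

  # seeding contract
  nz <- noise_model(white_sigma = 20)
  m1 <- simulate_movie(sheet, spec, noise = nz, seed = 42)$movie$data
  m2 <- simulate_movie(sheet, spec, noise = nz, seed = 42)$movie$data
  m3 <- simulate_movie(sheet, spec, noise = nz, seed = 43)$movie$data
  expect_identical(m1, m2)
  expect_false(identical(m1, m3))
})

test_that("single-pixel response magnitude matches the quadrature oracle", {
  # hand-built movie: one pixel modulated by the raised-cosine waveform
  rate <- 30; period <- 8; n_cyc <- 4; a <- 0.01; base <- 3000
  tk <- (seq_len(rate * period * n_cyc) - 1) / rate
  w <- response_waveform(tk - 2.5, period, duty = 0.5)
  px <- base - base * a * w
  arr <- array(base, c(2, 2, length(tk)))
  arr[1, 1, ] <- round(px)
  crm <- extract_response(raw_movie(array(as.integer(round(arr)),
                                          dim(arr))), 1 / period,
                          invert = TRUE)
  a1 <- oracle_first_harmonic(0.5, period)
  got <- response_magnitude(crm)[1, 1]
  # quantization to integer counts limits accuracy, not the analysis
  expect_equal(got, a * a1, tolerance = 0.02)
  expect_equal(waveform_first_harmonic(0.5), a1, tolerance = 1e-6)
})

test_that("noise-free phase recovers preferred time within one binned
           frame", {
  sheet <- build_default_sheet()
  spec <- test_specs(4)$azimuth
  sim <- simulate_movie(sheet, spec, noise = no_noise(), seed = 2)
  b <- bin_movie(sim$movie)
  crm <- extract_response(b, 1 / 8, invert = TRUE,
                          t0_offset_s = (4 - 1) / (2 * 30))
  tp_rec <- phase_to_stimulus_time(response_phase(crm), spec,
                                   delay_s = sheet$delay_s)
  tp_true <- bin2_mean(sim$truth$t_pref_image)
  inarea <- bin_label_image(sim$truth$label_image) > 0
  d <- abs(tp_rec - tp_true)
  d <- pmin(d, 8 - d)  # circular distance within the cycle
  expect_lt(max(d[inarea]), 1 / b$frame_rate_hz)
})

test_that("cohort generator reproduces cell means and truncates at zero", {
  des0 <- adult_design(n_per_cell = 3, animal_sd = 0)
  tab <- simulate_cohort_responses(des0, seed = 1)
  expect_equal(nrow(tab), 18)
  expect_true(all(tab$norm_V1 == 1))
  for (g in c("WT", "Het", "KO")) {
    expect_true(all(tab$norm_LM[tab$genotype == g] == 0.75))
  }
  # reproducibility
  expect_identical(simulate_cohort_responses(des0, seed = 9),
                   simulate_cohort_responses(des0, seed = 9))
  # truncation: absurd SD never yields negatives
  des_hi <- adult_design(n_per_cell = 5, animal_sd = 3)
  expect_true(all(simulate_cohort_responses(des_hi, seed = 2)$norm_AL >= 0))
  # unbalanced developmental cells
  dev <- development_design()
  expect_equal(dev$cells$n, c(7L, 5L, 6L, 6L, 7L, 7L))
  expect_equal(nrow(simulate_cohort_responses(dev, seed = 1)), 38)
})
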