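test_that("field sign of analytic planes follows the Jacobian", {
  h <- 40; w <- 40
  xplane <- matrix(rep(seq_len(w), each = h), h, w)
  yplane <- matrix(rep(seq_len(h), w), h, w)
  fs <- field_sign(list(azimuth_deg = xplane, elevation_deg = yplane),
                   smooth_sigma_px = 1)
  expect_true(all(fs$sign == 1))
  fs_neg <- field_sign(list(azimuth_deg = -xplane, elevation_deg = yplane),
                       smooth_sigma_px = 1)
  expect_true(all(fs_neg$sign == -1))
  # swapping the inputs flips every nonzero sign
  fs_swap <- field_sign(list(azimuth_deg = yplane, elevation_deg = xplane),
                        smooth_sigma_px = 1)
  expect_true(all(fs_swap$sign == -fs$sign))
  # adding a constant to either map changes nothing
  fs_off <- field_sign(list(azimuth_deg = xplane + 100,
                            elevation_deg = yplane - 3),
                       smooth_sigma_px = 1)
  expect_identical(fs_off$sign, fs$sign)
  # constant maps: all-zero sign
  suppressMessages(fs0 <- field_sign(list(azimuth_deg = matrix(5, h, w),
                                          elevation_deg = matrix(2, h, w)),
                                     smooth_sigma_px = 1))
  expect_true(all(fs0$sign == 0))
})

test_that("gaussian blur preserves constants and handles NA", {
  m <- matrix(7, 10, 12)
  expect_equal(gauss_blur(m, 1.5), m, tolerance = 1e-12)
  m[3, 4] <- NA
  sm <- gauss_blur(m, 1.5)
  expect_equal(sm[8, 8], 7, tolerance = 1e-12)
  expect_equal(sm[3, 4], 7, tolerance = 1e-12)  # filled from neighbors
})

test_that("segmentation on the true retinotopy recovers all areas", {
  sheet <- build_default_sheet()
  retino <- sheet_retinotopy(sheet)
  lab <- sheet_label_image(sheet)
  mask <- lab > 0
  seg <- segment_areas(field_sign(retino, mask = mask), mask,
                       min_size_px = 300)  # raw-resolution pixels
  expect_setequal(seg$names, c("V1", "LM", "LI", "AL", "RL", "AMPM"))
  dice <- segmentation_dice(seg, lab)
  expect_true(all(dice > 0.9))
  # determinism
  seg2 <- segment_areas(field_sign(retino, mask = mask), mask,
                        min_size_px = 300)
  expect_identical(seg$labels, seg2$labels)
})

test_that("mask restricted to V1 yields exactly one area named V1", {
  sheet <- build_default_sheet()
  lab <- sheet_label_image(sheet)
  mask <- lab == 1  # V1 polygon only
  seg <- segment_areas(field_sign(sheet_retinotopy(sheet), mask = mask),
                       mask, min_size_px = 300)
  expect_equal(seg$names, "V1")
  expect_true(all(seg$labels[!mask] == 0))
  # nothing reaching minimum size -> loud error
  expect_error(segment_areas(field_sign(sheet_retinotopy(sheet),
                                        mask = mask),
                             mask, min_size_px = 1e6), "minimum size")
})

test_that("label maps export and import losslessly, with AM/PM merge", {
  sheet <- build_default_sheet()
  lab <- sheet_label_image(sheet)
  mask <- lab > 0
  seg <- segment_areas(field_sign(sheet_retinotopy(sheet), mask = mask),
                       mask, min_size_px = 300)
  p <- file.path(withr::local_tempdir(), "labels.tif")
  export_labels(seg, p)
  back <- import_labels(p)
  expect_identical(back$labels, seg$labels)
  expect_equal(back$names, seg$names)

  # separate AM and PM labels merge into one AMPM label on import
  img <- matrix(0, 8, 8)
  img[1:4, 1:4] <- 1; img[1:4, 5:8] <- 2; img[5:8, 1:4] <- 3
  p2 <- file.path(withr::local_tempdir(), "ampm.tif")
  tiff_write(img, p2, "uint16")
  jsonlite::write_json(list(`1` = "V1", `2` = "AM", `3` = "PM"),
                       sub("\\.tif$", ".json", p2), auto_unbox = TRUE)
  merged <- import_labels(p2)
  expect_setequal(merged$names, c("V1", "AMPM"))
  am_lab <- match("AMPM", merged$names)
  expect_true(all(merged$labels[1:4, 5:8] == am_lab))
  expect_true(all(merged$labels[5:8, 1:4] == am_lab))

  # name table without V1 is unusable
  jsonlite::write_json(list(`1` = "LM", `2` = "AM", `3` = "PM"),
                       sub("\\.tif$", ".json", p2), auto_unbox = TRUE)
  expect_error(import_labels(p2), "V1")
  # duplicate names
  jsonlite::write_json(list(`1` = "V1", `2` = "LM", `3` = "LM"),
                       sub("\\.tif$", ".json", p2), auto_unbox = TRUE)
  expect_error(import_labels(p2), "duplicate")
})

test_that("dice coefficient behaves at the extremes", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  expect_equal(dice_coefficient(a & FALSE, a & FALSE), 1)
})
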