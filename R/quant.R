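# Region-amplitude quantification: a responsive-cortex mask built from the
# Gaussian-filtered magnitude map, per-area means taken on the ORIGINAL
# (unfiltered) magnitude map within (area AND mask), then normalization of
# every area to V1 within each animal.

#' Responsive-cortex mask from a magnitude map
#'
#' A duplicate of the magnitude map is Gaussian-filtered (5 x 5 kernel,
#' sigma 1 px by default) and thresholded; the filtered image is used ONLY
#' to build the mask. The threshold rule is either a fraction of the
#' filtered map's 99th percentile (scale-free, robust to outlier pixels;
#' the default, fraction 0.25) or an absolute value.
#'
#' @param mag Numeric magnitude matrix (fractional units).
#' @param kernel_px Odd Gaussian kernel support (default 5).
#' @param sigma_px Gaussian SD (default 1).
#' @param threshold Absolute threshold (used when
#'   `threshold_mode = "absolute"`).
#' @param threshold_mode `"fraction"` (default) or `"absolute"`.
#' @param fraction Fraction of the 99th-percentile filtered value
#'   (default 0.25).
#' @return Logical mask matrix with attribute `threshold` (the absolute
#'   value applied).
#' @export
responsive_mask <- function(mag, kernel_px = 5L, sigma_px = 1,
                            threshold = NULL,
                            threshold_mode = c("fraction", "absolute"),
                            fraction = 0.25) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(kernel_px %% 2L == 1L)
  filt <- gauss_blur(mag, sigma_px, size = kernel_px)
  thr <- if (threshold_mode == "absolute") {
    if (is.null(threshold)) stop("absolute mode needs a threshold value")
    threshold
  } else {
    fraction * stats::quantile(filt, 0.99, names = FALSE)
  }
  mask <- filt >= thr
  if (!any(mask)) {
    stop(sprintf("responsive mask is empty at threshold %.3g", thr))
  }
  attr(mask, "threshold") <- thr
  mask
}

#' Per-area mean magnitudes within the responsive mask
#'
#' For each labeled area, the mean of the ORIGINAL (unfiltered) magnitude
#' over pixels in the intersection of the area with the mask. Areas whose
#' intersection with the mask is empty are reported as `NA` with a
#' warning (excluded from statistics), never silently zero.
#'
#' @param mag Numeric magnitude matrix (unfiltered).
#' @param mask Logical responsive mask ([responsive_mask()]).
#' @param labels An `area_label_map`.
#' @param animal_id Identifier recorded in the output row.
#' @return A one-row `response_table` data frame: `animal_id`,
#'   `raw_<area>` and `n_px_<area>` per area, and `mask_threshold`.
#' @export
region_means <- function(mag, mask, labels, animal_id = "animal") {
  stopifnot(identical(dim(mag), dim(mask)),
            identical(dim(mag), dim(labels$labels)))
  row <- data.frame(animal_id = animal_id, stringsAsFactors = FALSE)
  for (i in seq_along(labels$names)) {
    nm <- labels$names[i]
    sel <- labels$labels == i & mask
    n <- sum(sel)
    if (n == 0) {
      warning("area ", nm, " has no responsive pixels; reported as NA")
      row[[paste0("raw_", nm)]] <- NA_real_
    } else {
      row[[paste0("raw_", nm)]] <- mean(mag[sel])
    }
    row[[paste0("n_px_", nm)]] <- n
  }
  row$mask_threshold <- attr(mask, "threshold") %||% NA_real_
  class(row) <- c("response_table", "data.frame")
  row
}

#' Normalize per-area amplitudes to V1
#'
#' Adds `norm_<area>` columns: each area's raw mean divided by the
#' animal's V1 raw mean (so `norm_V1` is exactly 1). This per-animal
#' normalization removes global gain differences (illumination, anesthetic
#' depth, hemodynamic reactivity) between animals.
#'
#' @param table A [region_means()] result (one or more rows).
#' @return The table with `norm_<area>` columns appended.
#' @export
normalize_to_v1 <- function(table) {
  if (!"raw_V1" %in% names(table)) stop("table has no raw_V1 column")
  v1 <- table$raw_V1
  if (any(is.na(v1)) || any(v1 <= 0)) {
    stop("V1 raw mean missing or non-positive: cannot normalize")
  }
  areas <- sub("^raw_", "", grep("^raw_", names(table), value = TRUE))
  for (a in areas) table[[paste0("norm_", a)]] <- table[[paste0("raw_", a)]] / v1
  table
}
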