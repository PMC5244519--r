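# Forward simulator: synthetic ISOI movies over a model cortical sheet with
# known retinotopy, area labels and response amplitudes, plus a fast
# response-level cohort generator for the statistics layer.
#
# The sheet is a flat field of raw camera pixels. Each visual area is an
# axis-aligned rectangle carrying an affine retinotopy: azimuth varies along
# x (mediolateral), elevation along y (posteroanterior). Mirror areas
# reverse the azimuth axis, so the visual field sign (sign of the
# retinotopic Jacobian) alternates across every shared border.

AREA_NAMES <- c("V1", "LM", "LI", "AL", "RL", "AMPM")

.rect_area <- function(name, x, y, mirror, amplitude) {
  list(name = name,
       rect = c(x_lo = x[1], x_hi = x[2], y_lo = y[1], y_hi = y[2]),
       polygon = cbind(x = c(x[1], x[2], x[2], x[1]),
                       y = c(y[1], y[1], y[2], y[2])),
       mirror = mirror, amplitude = amplitude)
}

#' Build the default model cortical sheet
#'
#' Lays out a large V1 plus five higher visual areas (LM, LI, AL, RL and a
#' merged AM/PM) on a raw-pixel field, qualitatively emulating the mouse
#' posterior cortex: LM/LI lateral, AL anterolateral, RL anterior, AM/PM
#' anteromedial to V1. Azimuth maps onto the mediolateral axis, elevation
#' onto the posteroanterior axis. LM, AL, RL and AM/PM share a border with
#' V1 with mirror-reversed azimuth; LI borders LM (mirror again, so its
#' sign matches V1). Areas with the same field sign never touch: they are
#' separated by unresponsive gaps, as the responsive-cortex mask — not the
#' field sign — separates them in the analysis.
#'
#' @param field_px Length-2 integer, raw field size `(H, W)` in pixels.
#'   Area rectangles scale with the field.
#' @param um_per_px Micrometers per raw pixel (geometry bookkeeping only).
#' @param amplitudes Named numeric, fractional reflectance modulation
#'   (delta R / R) per area; all must lie in `[0, 0.1)`.
#' @param delay_s Hemodynamic delay between stimulus time and response
#'   peak, seconds.
#' @param baseline_counts Camera baseline, counts (`<= 4095`).
#' @param azimuth_range_deg,elevation_range_deg Visual-field extent mapped
#'   across each area.
#' @return An object of class `cortical_sheet`.
#' @export
build_default_sheet <- function(field_px = c(128L, 128L),
                                um_per_px = 30,
                                amplitudes = c(V1 = 0.008, LM = 0.006,
                                               LI = 0.005, AL = 0.006,
                                               RL = 0.006, AMPM = 0.006),
                                delay_s = 1.5,
                                baseline_counts = 3000,
                                azimuth_range_deg = c(-55, 55),
                                elevation_range_deg = c(-37.5, 37.5)) {
  stopifnot(length(field_px) == 2L, all(field_px >= 64L),
            all(amplitudes >= 0), all(amplitudes < 0.1),
            baseline_counts > 0, baseline_counts <= 4095,
            setequal(names(amplitudes), AREA_NAMES))
  # layout is defined in physical units on a reference 128 px / 30 um-px
  # grid; finer pixels (smaller um_per_px) or larger fields scale the
  # polygons accordingly, anchored at the field center
  g <- 30 / um_per_px
  s <- field_px[2] / 128  # horizontal field scale
  sv <- field_px[1] / 128 # vertical field scale
  # pixel i covers [i - 0.5, i + 0.5]; scaling the cell EDGES keeps shared
  # borders shared and non-overlapping under rounding
  scale1 <- function(lo, hi, sc, center) {
    e_lo <- center + (lo - 0.5 - 64) * sc
    e_hi <- center + (hi + 0.5 - 64) * sc
    c(floor(e_lo) + 1, floor(e_hi))
  }
  rx <- function(lo, hi) scale1(lo, hi, s * g, field_px[2] / 2)
  ry <- function(lo, hi) scale1(lo, hi, sv * g, field_px[1] / 2)
  areas <- list(
    .rect_area("V1",   rx(16, 72),  ry(8, 72),   FALSE, amplitudes[["V1"]]),
    .rect_area("LM",   rx(73, 97),  ry(8, 38),   TRUE,  amplitudes[["LM"]]),
    .rect_area("LI",   rx(98, 122), ry(8, 38),   FALSE, amplitudes[["LI"]]),
    .rect_area("AL",   rx(73, 98),  ry(52, 72),  TRUE,  amplitudes[["AL"]]),
    .rect_area("RL",   rx(38, 62),  ry(73, 98),  TRUE,  amplitudes[["RL"]]),
    .rect_area("AMPM", rx(8, 26),   ry(73, 104), TRUE,  amplitudes[["AMPM"]]))
  sheet <- structure(list(field_px = as.integer(field_px),
                          um_per_px = um_per_px, areas = areas,
                          delay_s = delay_s,
                          baseline_counts = baseline_counts,
                          azimuth_range_deg = azimuth_range_deg,
                          elevation_range_deg = elevation_range_deg),
                     class = "cortical_sheet")
  .validate_sheet(sheet)
  sheet
}

.validate_sheet <- function(sheet) {
  lab <- matrix(0L, sheet$field_px[1], sheet$field_px[2])
  for (i in seq_along(sheet$areas)) {
    r <- sheet$areas[[i]]$rect
    if (r["x_hi"] > ncol(lab) || r["y_hi"] > nrow(lab) ||
        r["x_lo"] < 1 || r["y_lo"] < 1) {
      stop("area ", sheet$areas[[i]]$name, " extends outside the field")
    }
    block <- lab[r["y_lo"]:r["y_hi"], r["x_lo"]:r["x_hi"]]
    if (any(block != 0L)) {
      stop("overlapping area polygons: ", sheet$areas[[i]]$name, " and ",
           sheet$areas[[block[block != 0L][1]]]$name)
    }
    lab[r["y_lo"]:r["y_hi"], r["x_lo"]:r["x_hi"]] <- i
  }
  # adjacent areas must differ in mirror flag (field sign alternation)
  for (i in seq_along(sheet$areas)) {
    for (j in seq_along(sheet$areas)) {
      if (j <= i) next
      ri <- sheet$areas[[i]]$rect; rj <- sheet$areas[[j]]$rect
      gap_x <- max(ri["x_lo"], rj["x_lo"]) - min(ri["x_hi"], rj["x_hi"])
      gap_y <- max(ri["y_lo"], rj["y_lo"]) - min(ri["y_hi"], rj["y_hi"])
      touching <- max(gap_x, gap_y) <= 1 && min(gap_x, gap_y) <= 0
      if (touching && sheet$areas[[i]]$mirror == sheet$areas[[j]]$mirror) {
        stop("adjacent areas ", sheet$areas[[i]]$name, " and ",
             sheet$areas[[j]]$name, " must differ in mirror flag")
      }
    }
  }
  invisible(sheet)
}

#' Ground-truth label image of a sheet
#'
#' @param sheet A [build_default_sheet()] model.
#' @return Integer `H x W` matrix; 0 = background, index i = i-th area in
#'   `sheet$areas` (names in `attr(, "names_by_label")`).
#' @export
sheet_label_image <- function(sheet) {
  lab <- matrix(0L, sheet$field_px[1], sheet$field_px[2])
  for (i in seq_along(sheet$areas)) {
    r <- sheet$areas[[i]]$rect
    lab[r["y_lo"]:r["y_hi"], r["x_lo"]:r["x_hi"]] <- i
  }
  attr(lab, "names_by_label") <-
    vapply(sheet$areas, `[[`, character(1), "name")
  lab
}

#' Ground-truth retinotopy of a sheet
#'
#' @param sheet A cortical sheet model.
#' @return List of `H x W` matrices `azimuth_deg`, `elevation_deg`
#'   (NA outside areas).
#' @export
sheet_retinotopy <- function(sheet) {
  h <- sheet$field_px[1]; w <- sheet$field_px[2]
  azi <- matrix(NA_real_, h, w); ele <- matrix(NA_real_, h, w)
  ar <- sheet$azimuth_range_deg; er <- sheet$elevation_range_deg
  for (a in sheet$areas) {
    r <- a$rect
    xs <- r["x_lo"]:r["x_hi"]; ys <- r["y_lo"]:r["y_hi"]
    fx <- (xs - r["x_lo"]) / max(1, r["x_hi"] - r["x_lo"])
    fy <- (ys - r["y_lo"]) / max(1, r["y_hi"] - r["y_lo"])
    if (a$mirror) fx <- 1 - fx
    azi[ys, xs] <- matrix(ar[1] + fx * (ar[2] - ar[1]), length(ys),
                          length(xs), byrow = TRUE)
    ele[ys, xs] <- matrix(er[1] + fy * (er[2] - er[1]), length(ys),
                          length(xs))
  }
  list(azimuth_deg = azi, elevation_deg = ele)
}

#' Noise model for simulated movies
#'
#' White per-pixel-per-frame camera noise plus two global (spatially
#' uniform) nuisance components: a slow sinusoidal drift and a periodic
#' physiological artifact at a frequency that must not be harmonically
#' related to the stimulus frequency. Defaults approximate shot noise at a
#' 3000-count baseline (`sqrt(3000) ~ 55`) with modest drift and a
#' 0.9 Hz "heartbeat" line.
#'
#' @param white_sigma SD of white noise, counts.
#' @param drift_amp Amplitude of slow drift, counts.
#' @param drift_timescale_s Drift period, seconds.
#' @param physio_amp Amplitude of the physiological artifact, counts.
#' @param physio_freq_hz Artifact frequency, Hz.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(white_sigma = 50, drift_amp = 30,
                        drift_timescale_s = 120, physio_amp = 10,
                        physio_freq_hz = 0.9) {
  stopifnot(white_sigma >= 0, drift_amp >= 0, physio_amp >= 0,
            drift_timescale_s > 0, physio_freq_hz > 0)
  structure(list(white_sigma = white_sigma, drift_amp = drift_amp,
                 drift_timescale_s = drift_timescale_s,
                 physio_amp = physio_amp, physio_freq_hz = physio_freq_hz),
            class = "noise_model")
}

#' Silent noise model (all amplitudes zero)
#' @return A [noise_model()] with every amplitude 0.
#' @export
no_noise <- function() noise_model(0, 0, 120, 0, 0.9)

#' Raised-cosine response waveform
#'
#' Unit-peak, nonnegative bump centered at 0 with support `duty * period`:
#' `w(u) = cos^2(pi * u / (duty * period))` for `|u| < duty * period / 2`
#' (periodic in `period`), 0 elsewhere.
#'
#' @param u Time from the response peak, seconds (vectorized).
#' @param period_s Stimulus period, seconds.
#' @param duty Fraction of the cycle the response occupies (default 0.5).
#' @return Waveform values in `[0, 1]`.
#' @export
response_waveform <- function(u, period_s, duty = 0.5) {
  um <- ((u + period_s / 2) %% period_s) - period_s / 2
  ifelse(abs(um) < duty * period_s / 2,
         cos(pi * um / (duty * period_s))^2, 0)
}

#' First-harmonic amplitude of the response waveform
#'
#' The Fourier-series coefficient that links the simulator's programmed
#' fractional amplitude `a` to the fractional magnitude measured at the
#' stimulus frequency: measured = `a * waveform_first_harmonic(duty)`.
#'
#' @param duty Waveform duty cycle.
#' @return Dimensionless coefficient in `(0, 1]`.
#' @export
waveform_first_harmonic <- function(duty = 0.5) {
  # (2/P) * integral of w(u) cos(2 pi u / P) du, independent of P
  f <- function(v) cos(pi * v / duty)^2 * cos(2 * pi * v)  # v = u/P
  2 * stats::integrate(f, -duty / 2, duty / 2, rel.tol = 1e-12)$value
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a raw widefield movie over a cortical sheet
#'
#' Forward model, per raw pixel p with programmed response time `t_pref`:
#' `counts(t) = baseline - baseline * a_p * w(t - t_pref - delay) + noise`,
#' quantized to integers and clipped to `[0, 4095]`. The intrinsic signal
#' is a reflectance DECREASE on activation, hence the subtraction. For bar
#' stimuli `t_pref` is the time the bar crosses the pixel's preferred
#' azimuth/elevation; for the grating patch all responsive pixels share
#' `t_pref = 0` (response locked to the cycle).
#'
#' @param sheet A [build_default_sheet()] model.
#' @param spec A [stimulus_spec()].
#' @param geom A [screen_geometry()] (stored in the metadata sidecar).
#' @param noise A [noise_model()].
#' @param seed Integer RNG seed; equal seeds give bit-identical movies.
#' @param frame_rate_hz Acquisition rate (default 30).
#' @param duty Response waveform duty cycle.
#' @return List with `movie` (a [raw_movie()]) and `truth`
#'   (a `simulated_ground_truth` list: sheet, label_image,
#'   true_amplitude_by_area, true_phase_image, retinotopy, delay_s, seed).
#' @export
simulate_movie <- function(sheet, spec, geom = screen_geometry(),
                           noise = noise_model(), seed = 1L,
                           frame_rate_hz = 30, duty = 0.5) {
  h <- sheet$field_px[1]; w <- sheet$field_px[2]
  fpc <- frame_rate_hz * spec$period_s
  if (abs(fpc - round(fpc)) > 1e-9) {
    stop("frames per cycle must be an integer")
  }
  fpc <- as.integer(round(fpc))
  n_frames <- fpc * spec$n_cycles
  base <- sheet$baseline_counts
  lab <- sheet_label_image(sheet)
  amp <- c(0, vapply(sheet$areas, `[[`, numeric(1), "amplitude"))[lab + 1L]
  if (any(base * (1 - amp) < 0)) stop("amplitude drives counts negative")

  retino <- sheet_retinotopy(sheet)
  tpref <- matrix(0, h, w)
  if (spec$kind == "bar_azimuth") {
    r <- spec$sweep_range_deg
    tpref[] <- (retino$azimuth_deg - r[1]) / (r[2] - r[1]) * spec$period_s
  } else if (spec$kind == "bar_elevation") {
    r <- spec$sweep_range_deg
    tpref[] <- (retino$elevation_deg - r[1]) / (r[2] - r[1]) * spec$period_s
  }
  tpref[is.na(tpref)] <- 0

  # signal is cycle-periodic: build one cycle, tile n_cycles times
  t_cycle <- (seq_len(fpc) - 1L) / frame_rate_hz
  inarea <- which(lab > 0L)
  sig <- matrix(base, h * w, fpc)
  if (length(inarea)) {
    wv <- outer(tpref[inarea], t_cycle,
                function(tp, t) response_waveform(t - tp - sheet$delay_s,
                                                 spec$period_s, duty))
    sig[inarea, ] <- base - base * amp[inarea] * wv
  }

  quantize <- function(x) pmax.int(pmin.int(round(x), 4095), 0)
  counts <- .with_seed(seed, {
    t_all <- (seq_len(n_frames) - 1L) / frame_rate_hz
    global <- numeric(n_frames)  # spatially uniform nuisance components
    if (noise$drift_amp > 0) {
      global <- global + noise$drift_amp *
        sin(2 * pi * t_all / noise$drift_timescale_s +
              stats::runif(1, 0, 2 * pi))
    }
    if (noise$physio_amp > 0) {
      global <- global + noise$physio_amp *
        sin(2 * pi * noise$physio_freq_hz * t_all +
              stats::runif(1, 0, 2 * pi))
    }
    if (noise$white_sigma == 0 && all(global == 0)) {
      matrix(as.integer(quantize(sig)), h * w, n_frames)  # tile cycles
    } else {
      out <- matrix(0L, h * w, n_frames)
      for (cyc in seq_len(spec$n_cycles)) {  # cycle chunks: small temporaries
        cols <- (cyc - 1L) * fpc + seq_len(fpc)
        x <- sig + rep(global[cols], each = h * w)
        if (noise$white_sigma > 0) {
          x <- x + stats::rnorm(length(x), 0, noise$white_sigma)
        }
        out[, cols] <- as.integer(quantize(x))
      }
      out
    }
  })
  dim(counts) <- c(h, w, n_frames)
  movie <- raw_movie(counts,
                     frame_rate_hz = frame_rate_hz,
                     meta = list(stimulus = spec, screen = geom,
                                 simulated = TRUE, seed = seed))
  f <- stimulus_frequency(spec)
  truth <- structure(list(
    sheet = sheet,
    label_image = lab,
    true_amplitude_by_area = stats::setNames(
      vapply(sheet$areas, `[[`, numeric(1), "amplitude"),
      vapply(sheet$areas, `[[`, character(1), "name")),
    true_phase_image = (2 * pi * f * (tpref + sheet$delay_s) + pi) %%
      (2 * pi) - pi,
    retinotopy = retino,
    t_pref_image = tpref,
    delay_s = sheet$delay_s,
    duty = duty,
    seed = seed), class = "simulated_ground_truth")
  list(movie = movie, truth = truth)
}

#' Downsample a label image to the binned grid
#'
#' Majority vote over each 2x2 block (ties broken toward background, then
#' the smaller label), matching the analysis resolution after
#' [bin_movie()].
#'
#' @param labels Integer `H x W` label matrix.
#' @param factor Spatial bin factor (default 2).
#' @return Integer `(H/f) x (W/f)` label matrix.
#' @export
bin_label_image <- function(labels, factor = 2L) {
  h <- nrow(labels); w <- ncol(labels)
  stopifnot(h %% factor == 0L, w %% factor == 0L)
  hb <- h %/% factor; wb <- w %/% factor
  out <- matrix(0L, hb, wb)
  for (dy in seq_len(factor)) {
    for (dx in seq_len(factor)) {
      sub <- labels[seq(dy, h, factor), seq(dx, w, factor)]
      if (dy == 1L && dx == 1L) {
        votes <- array(0L, c(hb, wb, max(labels) + 1L))
      }
      for (l in 0:max(labels)) {
        votes[, , l + 1L] <- votes[, , l + 1L] + (sub == l)
      }
    }
  }
  out[] <- apply(votes, c(1, 2), which.max) - 1L
  attr(out, "names_by_label") <- attr(labels, "names_by_label")
  out
}

# --- cohort-level generator -------------------------------------------------

#' Factorial cohort design for response-level simulation
#'
#' Describes a genotype x sex x age cohort as a table of cells, each with a
#' sample size and per-area mean V1-normalized amplitude. Between-animal
#' variability is Gaussian with SD `animal_sd * mean` (relative),
#' truncated at 0.
#'
#' @param cells Data frame with columns `genotype` (WT/Het/KO), `sex`
#'   (M/F), `age_group` (P17/P30/P100), `n` (>= 2), and one `mean_<AREA>`
#'   column per area.
#' @param animal_sd Relative between-animal SD (fraction of the cell mean).
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(cells, animal_sd = 0.15) {
  stopifnot(is.data.frame(cells), all(cells$n >= 2),
            all(cells$genotype %in% c("WT", "Het", "KO")),
            all(cells$sex %in% c("M", "F")),
            all(cells$age_group %in% c("P17", "P30", "P100")))
  mean_cols <- grep("^mean_", names(cells), value = TRUE)
  if (!length(mean_cols)) stop("cells needs mean_<AREA> columns")
  if (any(as.matrix(cells[mean_cols]) <= 0)) stop("means must be > 0")
  structure(list(cells = cells, animal_sd = animal_sd,
                 areas = sub("^mean_", "", mean_cols)),
            class = "cohort_design")
}

.DEFAULT_AREA_MEANS <- c(V1 = 1, LM = 0.75, LI = 0.55, AL = 0.65,
                         RL = 0.70, AMPM = 0.60)

#' Adult genotype x sex cohort design
#'
#' Three genotypes by two sexes at P100, `n_per_cell` animals per cell
#' (default 7, i.e. 42 animals). Optional multiplicative scaling of the
#' dorsal areas (AL, RL, AMPM) in Het and KO cells programs a
#' genotype effect.
#'
#' @param n_per_cell Animals per genotype-by-sex cell.
#' @param ko_dorsal_scale,het_dorsal_scale Multipliers on dorsal-area means
#'   in KO / Het animals (1 = null design). Applied to males only when
#'   `males_only_effect` is TRUE (the sexually dimorphic scenario).
#' @param males_only_effect Restrict the programmed effect to males.
#' @param animal_sd Relative between-animal SD.
#' @return A [cohort_design()].
#' @export
adult_design <- function(n_per_cell = 7L, ko_dorsal_scale = 1,
                         het_dorsal_scale = 1, males_only_effect = TRUE,
                         animal_sd = 0.15) {
  grid <- expand.grid(genotype = c("WT", "Het", "KO"), sex = c("M", "F"),
                      stringsAsFactors = FALSE)
  grid$age_group <- "P100"
  grid$n <- n_per_cell
  for (a in names(.DEFAULT_AREA_MEANS)) {
    m <- rep(.DEFAULT_AREA_MEANS[[a]], nrow(grid))
    if (a %in% c("AL", "RL", "AMPM")) {
      hit <- if (males_only_effect) grid$sex == "M" else rep(TRUE, nrow(grid))
      m[hit & grid$genotype == "KO"] <- m[hit & grid$genotype == "KO"] *
        ko_dorsal_scale
      m[hit & grid$genotype == "Het"] <- m[hit & grid$genotype == "Het"] *
        het_dorsal_scale
    }
    grid[[paste0("mean_", a)]] <- m
  }
  cohort_design(grid, animal_sd = animal_sd)
}

#' Developmental WT/KO male cohort design
#'
#' Two genotypes by three ages with the unbalanced sample sizes of a
#' typical developmental series: P17 WT 7 / KO 5, P30 6 / 6, P100 7 / 7
#' (38 animals). Dorsal-area means grow with age; `ko_dorsal_scale`
#' attenuates the adult dorsal response in KO animals.
#'
#' @param ko_dorsal_scale Multiplier on KO dorsal means at P30 and P100.
#' @param animal_sd Relative between-animal SD.
#' @return A [cohort_design()].
#' @export
development_design <- function(ko_dorsal_scale = 1, animal_sd = 0.15) {
  grid <- expand.grid(genotype = c("WT", "KO"),
                      age_group = c("P17", "P30", "P100"),
                      stringsAsFactors = FALSE)
  grid$sex <- "M"
  grid$n <- c(7L, 5L, 6L, 6L, 7L, 7L)
  age_gain <- c(P17 = 0.6, P30 = 0.8, P100 = 1.0)
  for (a in names(.DEFAULT_AREA_MEANS)) {
    m <- .DEFAULT_AREA_MEANS[[a]] * age_gain[grid$age_group]
    if (a %in% c("AL", "RL", "AMPM")) {
      hit <- grid$genotype == "KO" & grid$age_group != "P17"
      m[hit] <- m[hit] * ko_dorsal_scale
    }
    grid[[paste0("mean_", a)]] <- as.numeric(m)
  }
  cohort_design(grid, animal_sd = animal_sd)
}

#' Simulate per-animal normalized responses for a cohort
#'
#' Each animal's per-area normalized amplitude is its cell mean plus
#' Gaussian between-animal noise with SD `animal_sd * mean`, truncated at
#' 0. Fully reproducible from `seed`.
#'
#' @param design A [cohort_design()].
#' @param seed Integer RNG seed.
#' @return A `cohort_table` data frame: `animal_id`, `genotype`, `sex`,
#'   `age_group`, and one `norm_<AREA>` column per area.
#' @export
simulate_cohort_responses <- function(design, seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  .with_seed(seed, {
    cells <- design$cells
    rep_idx <- rep(seq_len(nrow(cells)), cells$n)
    n_tot <- length(rep_idx)
    out <- data.frame(animal_id = sprintf("sim%03d", seq_len(n_tot)),
                      genotype = cells$genotype[rep_idx],
                      sex = cells$sex[rep_idx],
                      age_group = cells$age_group[rep_idx],
                      stringsAsFactors = FALSE)
    for (a in design$areas) {
      mu <- cells[[paste0("mean_", a)]][rep_idx]
      out[[paste0("norm_", a)]] <-
        pmax(0, stats::rnorm(n_tot, mu, design$animal_sd * mu))
    }
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
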