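# End-to-end orchestration: bin -> Fourier maps -> fidelity gate ->
# retinotopy -> segmentation (or imported labels) -> responsive mask ->
# per-area quantification -> cohort statistics. All tunable parameters
# live in a single run config (YAML-serializable); every stage reads only
# from it, and defaults are recorded in the run manifest so gap-filling
# choices stay auditable.

#' Default run configuration
#'
#' @param n_cycles Stimulus cycles per run (50 for the full protocol;
#'   simulations/tests typically use 10).
#' @param delay_s Assumed hemodynamic delay, seconds (default 0 for real
#'   data, where it is unknown; simulations pass their true delay).
#' @param seed Integer seed recorded and used for any stochastic stage.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(n_cycles = 10L, delay_s = 0, seed = 1L) {
  structure(list(
    screen = screen_geometry(),
    stimuli = list(
      azimuth = stimulus_spec("bar_azimuth", n_cycles = n_cycles),
      elevation = stimulus_spec("bar_elevation", n_cycles = n_cycles),
      grating = stimulus_spec("grating_patch", n_cycles = n_cycles)),
    binning = c(t = 4L, y = 2L, x = 2L),
    delay_s = delay_s,
    fidelity = list(threshold = 3),
    mask = list(kernel_px = 5L, sigma_px = 1, mode = "fraction",
                fraction = 0.25, threshold = NULL),
    segmentation = list(smooth_sigma_px = 2, min_size_px = 100),
    stats = list(alpha = 0.05),
    blind = FALSE,
    seed = as.integer(seed)), class = "run_config")
}

#' Write / read a run config as YAML
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in intersect(names(raw), names(cfg))) cfg[[nm]] <- raw[[nm]]
  g <- raw$screen
  if (!is.null(g)) {
    cfg$screen <- screen_geometry(g$width_px, g$height_px, g$width_mm,
                                  g$height_mm, g$distance_cm, g$tilt_deg)
  }
  if (!is.null(raw$stimuli)) {
    cfg$stimuli <- lapply(raw$stimuli, function(s) {
      stimulus_spec(kind = s$kind, period_s = s$period_s,
                    n_cycles = s$n_cycles,
                    sweep_range_deg = unlist(s$sweep_range_deg),
                    patch_diameter_deg = s$patch_diameter_deg %||% 50,
                    spatial_freq_cpd = s$spatial_freq_cpd %||% 0.04,
                    velocity_profile = lapply(s$velocity_profile %||%
                                                list(c(6, 0), c(2, 50)),
                                              as.numeric))
    })
  }
  class(cfg) <- "run_config"
  cfg
}

.hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

# time offset of the first binned sample relative to stimulus onset
.bin_time_offset <- function(raw_rate_hz, t_bin) (t_bin - 1) / (2 * raw_rate_hz)

#' Run the full single-animal analysis
#'
#' Fixed stage order: bin the three movies, extract the complex response
#' at the stimulus frequency for each, apply the map-fidelity gate (an
#' animal without a high-fidelity retinotopic map is excluded and
#' recorded), convert bar phases to retinotopy, compute the field sign and
#' segment areas (or use imported labels), build the responsive mask from
#' the grating magnitude map, and quantify V1-normalized per-area
#' amplitudes.
#'
#' @param azi_movie,elev_movie,grating_movie [raw_movie()] objects (or
#'   TIFF paths) for the azimuth bar, elevation bar and grating runs.
#' @param config A [default_config()].
#' @param animal_id Identifier for the output row.
#' @param labels Optional imported `area_label_map` (bypasses automatic
#'   segmentation, as in a manual-ROI workflow).
#' @return List of class `animal_result`: `excluded`, `snr`, `maps`,
#'   `retinotopy`, `field_sign`, `segmentation`, `mask`, `table`
#'   (one-row normalized [region_means()] table), `manifest`.
#' @export
run_animal <- function(azi_movie, elev_movie, grating_movie,
                       config = default_config(), animal_id = "animal",
                       labels = NULL) {
  load_m <- function(m) if (is.character(m)) read_movie(m) else m
  stage <- function(nm, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", nm, conditionMessage(e)), call. = FALSE)
    })
  }
  azi <- stage("load", load_m(azi_movie))
  ele <- stage("load", load_m(elev_movie))
  grat <- stage("load", load_m(grating_movie))

  azi_b <- stage("bin", bin_movie(azi))
  ele_b <- stage("bin", bin_movie(ele))
  grat_b <- stage("bin", bin_movie(grat))

  f_stim <- stimulus_frequency(config$stimuli$grating)
  offset <- .bin_time_offset(azi$frame_rate_hz, config$binning[["t"]])

  maps <- stage("map", list(
    azimuth = extract_response(azi_b, stimulus_frequency(
      config$stimuli$azimuth), invert = TRUE, t0_offset_s = offset),
    elevation = extract_response(ele_b, stimulus_frequency(
      config$stimuli$elevation), invert = TRUE, t0_offset_s = offset),
    grating = extract_response(grat_b, f_stim, invert = TRUE,
                               t0_offset_s = offset)))

  snr <- stage("fidelity", map_fidelity(azi_b, stimulus_frequency(
    config$stimuli$azimuth)))
  manifest <- list(
    animal_id = animal_id,
    config_hash = .hash_object(unclass(config)),
    fidelity_snr = snr,
    warnings = character(),
    timestamp = format(Sys.time(), tz = "UTC"))
  if (snr < config$fidelity$threshold) {
    manifest$warnings <- sprintf(
      "excluded: map fidelity SNR %.2f below threshold %.2f", snr,
      config$fidelity$threshold)
    return(structure(list(excluded = TRUE, snr = snr, maps = maps,
                          table = NULL, manifest = manifest),
                     class = "animal_result"))
  }

  retino <- stage("retinotopy", retinotopy_from_phases(
    maps$azimuth, maps$elevation, config$stimuli$azimuth,
    config$stimuli$elevation, delay_s = config$delay_s))
  mag <- response_magnitude(maps$grating)
  mask <- stage("mask", responsive_mask(
    mag, kernel_px = config$mask$kernel_px, sigma_px = config$mask$sigma_px,
    threshold = config$mask$threshold, threshold_mode = config$mask$mode,
    fraction = config$mask$fraction))
  fs <- stage("field_sign", field_sign(
    retino, smooth_sigma_px = config$segmentation$smooth_sigma_px,
    mask = mask))
  seg <- if (is.null(labels)) {
    stage("segment", segment_areas(fs, mask,
                                   min_size_px = config$segmentation$min_size_px))
  } else labels
  tab <- stage("quantify", normalize_to_v1(
    region_means(mag, mask, seg, animal_id = animal_id)))

  manifest$stage_hashes <- c(
    binned = .hash_object(list(azi_b$data, ele_b$data, grat_b$data)),
    maps = .hash_object(lapply(maps, `[[`, "coeff")),
    labels = .hash_object(seg$labels),
    table = .hash_object(tab))
  structure(list(excluded = FALSE, snr = snr, maps = maps,
                 retinotopy = retino, field_sign = fs, segmentation = seg,
                 mask = mask, table = tab, manifest = manifest),
            class = "animal_result")
}

#' Aggregate animal results and run the configured cohort statistics
#'
#' Binds the per-animal normalized tables to their factors, then for each
#' area runs a one-way genotype ANOVA (single age group) or a two-way
#' genotype x age ANOVA, with Bonferroni post hoc tests across genotypes
#' when the genotype effect is significant.
#'
#' @param animal_results List of [run_animal()] results (excluded animals
#'   are dropped and listed in the report).
#' @param factors Data frame with `animal_id`, `genotype`, `sex`,
#'   `age_group` (withheld from all earlier stages: the analysis up to
#'   this point is blind to them).
#' @param config A [default_config()].
#' @return List of class `cohort_result`: `table` (cohort table),
#'   `anova` (per-area `anova_result`), `excluded` (ids), `report`
#'   (character summary).
#' @export
run_cohort <- function(animal_results, factors, config = default_config()) {
  if (!length(animal_results)) stop("empty cohort")
  excl <- vapply(animal_results, `[[`, logical(1), "excluded")
  kept <- animal_results[!excl]
  excluded_ids <- vapply(animal_results[excl], function(a)
    a$manifest$animal_id, character(1))
  if (!length(kept)) stop("all animals excluded by the fidelity gate")
  tab <- do.call(rbind, lapply(kept, `[[`, "table"))
  tab <- merge(tab, factors, by = "animal_id", sort = FALSE)
  areas <- sub("^norm_", "", grep("^norm_", names(tab), value = TRUE))
  one_age <- length(unique(tab$age_group)) == 1L
  cells <- if (one_age) table(tab$genotype) else table(tab$genotype,
                                                       tab$age_group)
  if (any(cells < 2)) stop("fewer than 2 animals in a compared cell")
  alpha <- config$stats$alpha
  anovas <- list()
  report <- character()
  for (a in areas) {
    # V1 is tested on raw amplitudes (its normalized value is 1 by
    # construction); HVAs are tested on V1-normalized amplitudes
    y <- if (a == "V1" && "raw_V1" %in% names(tab)) tab$raw_V1
         else tab[[paste0("norm_", a)]]
    res <- if (one_age) {
      one_way_anova(y, tab$genotype, effect_name = "genotype")
    } else {
      two_way_anova(y, tab$genotype, tab$age_group,
                    a_name = "genotype", b_name = "age")
    }
    gp <- res$effects$p[res$effects$name == "genotype"]
    if (length(gp) && gp < alpha && length(unique(tab$genotype)) > 1) {
      res$posthoc <- bonferroni_posthoc(y, tab$genotype)
    }
    anovas[[a]] <- res
    for (i in seq_len(nrow(res$effects))) {
      e <- res$effects[i, ]
      report <- c(report, sprintf(
        "%s %s: F(%d,%d) = %.3g, p = %.3g%s", a, e$name, e$df1, e$df2,
        e$F, e$p, if (e$p < alpha) " *" else ""))
    }
  }
  if (length(excluded_ids)) {
    report <- c(report, paste("excluded by fidelity gate:",
                              paste(excluded_ids, collapse = ", ")))
  }
  structure(list(table = tab, anova = anovas, excluded = excluded_ids,
                 report = report), class = "cohort_result")
}

#' Write a cohort table as CSV
#' @param table A cohort/response table (data frame).
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table CSV
#' @param path CSV path.
#' @return A `cohort_table` data frame.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
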