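#' @name synthetic_community
#' @title Synthetic rodent-community isotope data generator
#'
#' @description
#' Generates specimen-level isotope datasets with the statistical structure
#' the analysis pipeline assumes, so that every stage can be tested against
#' known truth without any external data: a sinusoidal seasonal drinking
#' water delta18O cycle, tissue formation windows (permanently growing
#' incisors integrate the last 4-7 weeks of life, molars 8-12 weeks, bone
#' roughly the whole post-weaning life), a late-summer-biased mortality
#' profile (owl-pellet taphocoenosis), a Gaussian carbonate-phosphate
#' offset, per-species diets with optional C4 contamination, and analytical
#' measurement noise.
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

month_days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

default_species_table <- function() {
  # apatite-scale d13C means/SDs of the seven-species incisor community;
  # mixture parameters default off (pure single-Gaussian diets)
  data.frame(
    species = c("Arvicola terrestris", "Myodes glareolus",
                "Microtus agrestis", "Microtus arvalis",
                "Apodemus sylvaticus", "Mus musculus", "Rattus norvegicus"),
    family = c("arvicolid", "arvicolid", "arvicolid", "arvicolid",
               "murid", "murid", "murid"),
    d13C_mean = c(-17.7, -16.2, -19.7, -18.8, -15.9, -12.1, -9.6),
    d13C_sd = c(0.6, 0.7, 0.6, 1.4, 1.7, 5.3, 3.4),
    c4_prob = 0, c4_shift = 0,
    tissues = c("incisor;M1;M2;M3;bone", rep("incisor;bone", 6)),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic community generator
#'
#' All parameters of [generate_community()], with defaults describing a
#' temperate NW-European locality: annual mean precipitation delta18O of
#' -7.3 per mil with a 2 per-mil seasonal amplitude peaking in mid-July;
#' tissue windows of 28-49 days (incisors) and 56-84 days (molars); bone
#' integrating from weaning (day 21) to death; monthly mortality weights
#' rising from 1 in late winter to 4 in August-September; a 10.9 +/- 0.8
#' per-mil carbonate-phosphate offset; analytical SDs of 0.1 (d18O_CO3),
#' 0.2 (d18O_PO4) and 0.04 (d13C) per mil.
#'
#' @param annual_mean_lw annual mean water delta18O, per mil.
#' @param seasonal_amplitude seasonal half-amplitude, per mil (>= 0).
#' @param phase_peak_day day-of-year of the water delta18O maximum.
#' @param calibration registry name of the body-water-to-phosphate forward
#'   map.
#' @param co3_po4_offset,co3_po4_offset_sd carbonate-phosphate offset mean
#'   and SD, per mil.
#' @param tissue_windows named list `tissue -> c(days_min, days_max)` for
#'   the tooth tissues; bone always integrates weaning-to-death.
#' @param weaning_day age in days at which bone recording starts.
#' @param mortality_weights 12 non-negative monthly weights (Jan..Dec), not
#'   all zero.
#' @param lifespan_days `c(mean, sd, min)` of a truncated-normal lifespan in
#'   days.
#' @param species_table data frame `species`, `family`, `d13C_mean`,
#'   `d13C_sd`, `c4_prob`, `c4_shift`, `tissues` (semicolon-separated).
#' @param suckling_enrichment per-mil delta18O added to juvenile tissue
#'   (default 0).
#' @param individual_sd per-mil biological noise SD, one draw per
#'   individual shared across its tissues.
#' @param measurement_sd named per-analyte analytical SDs.
#' @param diet_seasonal_amplitude optional per-mil sinusoidal modulation of
#'   diet d13C over the tissue formation midpoint (default 0 = off).
#' @param n_per_species individuals per species.
#' @param seed integer RNG seed.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(annual_mean_lw = -7.3,
                              seasonal_amplitude = 2.0,
                              phase_peak_day = 196,
                              calibration = "longinelli_2003",
                              co3_po4_offset = 10.9,
                              co3_po4_offset_sd = 0.8,
                              tissue_windows = list(incisor = c(28, 49),
                                                    M1 = c(56, 84),
                                                    M2 = c(56, 84),
                                                    M3 = c(56, 84)),
                              weaning_day = 21,
                              mortality_weights = c(1.2, 1, 1.2, 1.5, 2, 2.5,
                                                    3, 4, 4, 3, 2, 1.5),
                              lifespan_days = c(mean = 300, sd = 80,
                                                min = 90),
                              species_table = default_species_table(),
                              suckling_enrichment = 0,
                              individual_sd = 0.5,
                              measurement_sd = c(d18O_co3 = 0.1,
                                                 d18O_po4 = 0.2,
                                                 d13C = 0.04),
                              diet_seasonal_amplitude = 0,
                              n_per_species = 10,
                              seed = 1L) {
  stopifnot(seasonal_amplitude >= 0,
            length(mortality_weights) == 12L,
            all(mortality_weights >= 0), any(mortality_weights > 0),
            all(measurement_sd >= 0),
            individual_sd >= 0, co3_po4_offset_sd >= 0,
            n_per_species >= 1)
  for (w in tissue_windows) {
    stopifnot(length(w) == 2L, all(w > 0), w[1] <= w[2])
  }
  need <- c("species", "family", "d13C_mean", "d13C_sd", "c4_prob",
            "c4_shift", "tissues")
  if (!all(need %in% names(species_table))) {
    rodiso_stop("rodiso_config_error",
                paste0("species_table must have columns ",
                       paste(need, collapse = ", ")))
  }
  resolve_calibration(calibration)  # fail early on unknown name
  structure(list(annual_mean_lw = annual_mean_lw,
                 seasonal_amplitude = seasonal_amplitude,
                 phase_peak_day = phase_peak_day,
                 calibration = calibration,
                 co3_po4_offset = co3_po4_offset,
                 co3_po4_offset_sd = co3_po4_offset_sd,
                 tissue_windows = tissue_windows,
                 weaning_day = weaning_day,
                 mortality_weights = mortality_weights,
                 lifespan_days = lifespan_days,
                 species_table = species_table,
                 suckling_enrichment = suckling_enrichment,
                 individual_sd = individual_sd,
                 measurement_sd = measurement_sd,
                 diet_seasonal_amplitude = diet_seasonal_amplitude,
                 n_per_species = n_per_species,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Seasonal drinking-water delta18O series
#'
#' Returns the idealized daily water curve
#' `d18O_LW(t) = mean + amplitude * cos(2*pi*(t - peak)/365)` as a
#' vectorized function of day `t` (periodic, so negative or multi-year days
#' are fine).  The mean over any full 365-day cycle of integer days equals
#' the configured annual mean exactly.
#'
#' @param config a [simulation_config()].
#' @return function of numeric `t` returning per-mil water values.
#' @export
water_series <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- config$annual_mean_lw
  a <- config$seasonal_amplitude
  p <- config$phase_peak_day
  function(t) m + a * cos(2 * pi * (t - p) / 365)
}

window_mean_water <- function(config, start_day, end_day) {
  w <- water_series(config)
  mean(w(seq(floor(start_day), floor(end_day))))
}

#' Isotope values recorded by one tissue of one individual
#'
#' Averages the seasonal water curve over the tissue's formation window
#' ending at death (teeth: the last `window_days` days; bone: weaning to
#' death), maps the average through the configured forward calibration to
#' phosphate delta18O, and adds the supplied individual shift and
#' carbonate-phosphate offset draw.  Deterministic given its arguments; all
#' random draws live in [generate_community()].
#'
#' @param config a [simulation_config()].
#' @param death_day day (absolute; day-of-year works since the water curve
#'   is periodic) of death.
#' @param tissue `"incisor"`, `"M1"`, `"M2"`, `"M3"` or `"bone"`.
#' @param window_days tooth formation window length in days; default the
#'   midpoint of the configured range.  Ignored for bone.
#' @param birth_day day of birth; required for bone, used for truncation
#'   otherwise.  Default `death_day - lifespan mean`.
#' @param offset_draw carbonate-phosphate offset applied to this record
#'   (default: the configured mean, no noise).
#' @param indiv_shift per-mil biological shift of this individual.
#' @return list `d18O_po4`, `d18O_co3`, `window` (`c(start, end)`),
#'   `truncated` (logical: window clipped to the post-weaning lifespan).
#' @export
record_tissue <- function(config, death_day, tissue, window_days = NULL,
                          birth_day = NULL, offset_draw = NULL,
                          indiv_shift = 0) {
  stopifnot(inherits(config, "simulation_config"),
            tissue %in% rodiso_tissues)
  birth_day <- birth_day %||% (death_day - config$lifespan_days[["mean"]])
  if (death_day <= birth_day) {
    rodiso_stop("rodiso_invalid_input", "death_day must exceed birth_day")
  }
  earliest <- birth_day + config$weaning_day
  if (earliest >= death_day) earliest <- birth_day  # died before weaning age
  if (tissue == "bone") {
    start <- earliest
  } else {
    win <- config$tissue_windows[[tissue]]
    if (is.null(win)) {
      rodiso_stop("rodiso_config_error",
                  paste0("no tissue window configured for ", tissue))
    }
    window_days <- window_days %||% mean(win)
    start <- death_day - window_days + 1
  }
  truncated <- start < earliest
  if (truncated) start <- earliest
  avg_lw <- window_mean_water(config, start, death_day)
  po4 <- from_local_water(config$calibration, avg_lw) + indiv_shift
  off <- offset_draw %||% config$co3_po4_offset
  list(d18O_po4 = po4, d18O_co3 = po4 + off,
       window = c(start, death_day), truncated = truncated)
}

draw_death_day <- function(config) {
  m <- sample.int(12L, 1L, prob = config$mortality_weights)
  start <- c(0, cumsum(month_days))[m]
  start + sample.int(month_days[m], 1L)
}

#' Generate a synthetic rodent-community dataset
#'
#' Fully reproducible from `config$seed`.  Per individual: a truncated
#' normal lifespan, a death day drawn from the monthly mortality weights, a
#' shared biological delta18O shift, a diet delta13C draw (Gaussian, with
#' optional C4-contamination mixture), then per tissue a formation window
#' drawn uniformly within the configured range, the deterministic
#' [record_tissue()] value, a Gaussian carbonate-phosphate offset draw and
#' per-analyte measurement noise.
#'
#' @param config a [simulation_config()].
#' @return a `specimen_records` data frame with attribute `truth`: a list
#'   with the generating `config`, per-record `true` data frame
#'   (`specimen_id`, `death_day`, `birth_day`, `lifespan`, `indiv_shift`,
#'   `d13C_indiv`).
#' @export
generate_community <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ls_par <- config$lifespan_days
  ms <- config$measurement_sd
  rows <- list()
  truth <- list()
  for (si in seq_len(nrow(config$species_table))) {
    sp <- config$species_table[si, ]
    tissues <- strsplit(sp$tissues, ";", fixed = TRUE)[[1]]
    for (i in seq_len(config$n_per_species)) {
      id <- sprintf("sp%02d_%03d", si, i)
      lifespan <- max(ls_par[["min"]],
                      stats::rnorm(1, ls_par[["mean"]], ls_par[["sd"]]))
      death_day <- draw_death_day(config)
      birth_day <- death_day - lifespan
      indiv_shift <- stats::rnorm(1, 0, config$individual_sd)
      d13C_indiv <- stats::rnorm(1, sp$d13C_mean, sp$d13C_sd) +
        (stats::runif(1) < sp$c4_prob) * sp$c4_shift
      age_class <- if (lifespan < 120) "juvenile" else "adult"
      suck <- if (age_class == "juvenile") config$suckling_enrichment else 0
      for (tis in tissues) {
        wdays <- if (tis == "bone") NULL else {
          win <- config$tissue_windows[[tis]]
          stats::runif(1, win[1], win[2])
        }
        off_draw <- stats::rnorm(1, config$co3_po4_offset,
                                 config$co3_po4_offset_sd)
        rt <- record_tissue(config, death_day, tis, window_days = wdays,
                            birth_day = birth_day, offset_draw = off_draw,
                            indiv_shift = indiv_shift + suck)
        d13C_mod <- if (config$diet_seasonal_amplitude > 0) {
          mid <- mean(rt$window)
          config$diet_seasonal_amplitude *
            cos(2 * pi * (mid - config$phase_peak_day) / 365)
        } else 0
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = id, species = sp$species, family = sp$family,
          tissue = tis, side = NA_character_,
          d18O_co3 = rt$d18O_co3 + stats::rnorm(1, 0, ms[["d18O_co3"]]),
          d18O_po4 = rt$d18O_po4 + stats::rnorm(1, 0, ms[["d18O_po4"]]),
          d13C = d13C_indiv + d13C_mod + stats::rnorm(1, 0, ms[["d13C"]]),
          age_class = age_class, stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(
        specimen_id = id, species = sp$species, death_day = death_day,
        birth_day = birth_day, lifespan = lifespan,
        indiv_shift = indiv_shift, d13C_indiv = d13C_indiv,
        stringsAsFactors = FALSE)
    }
  }
  out <- specimen_records(do.call(rbind, rows))
  attr(out, "truth") <- list(config = config,
                             individuals = do.call(rbind, truth))
  out
}

#' Parameter-recovery experiment on synthetic data
#'
#' Generates a community, runs the estimation pipeline on it, and reports
#' estimated-minus-true discrepancies: the carbonate-phosphate offset, the
#' incisor-vs-bone delta18O_CO3 pattern (sign and proportion positive: under
#' seasonality plus summer-biased mortality most individuals record
#' 18O-enriched summer water in their incisors), the annual-mean water
#' recovered from bone through the matching (bone-appropriate) calibration,
#' and the per-species diet means.
#'
#' @param config a [simulation_config()].
#' @return list of class `recovery_report`: `offset` (true, estimated, sd,
#'   error), `incisor_bone` (mean offset, proportion positive, n),
#'   `water` (true annual mean, estimated from bone, error), `diet`
#'   (data frame with true apatite-scale means and estimated means).
#' @export
recovery_experiment <- function(config = simulation_config()) {
  data <- generate_community(config)
  est <- estimate_offset(data)
  ib <- paired_tissue_offsets(data, "incisor", "bone", "d18O_co3")
  water <- suppressWarnings(
    reconstruct_water(data, config$calibration,
                      offset = config$co3_po4_offset, tissue = "bone"))
  ds <- diet_summary(data, diet_model(), by = "species")
  truth_diet <- apatite_to_diet(config$species_table$d13C_mean, diet_model())
  diet_cmp <- merge(
    data.frame(species = config$species_table$species,
               true_diet_mean = truth_diet, stringsAsFactors = FALSE),
    ds[, c("species", "n", "diet_mean")], by = "species")
  structure(list(
    offset = list(true = config$co3_po4_offset,
                  estimated = est$mean_offset, sd = est$sd_offset,
                  n = est$n_pairs,
                  error = est$mean_offset - config$co3_po4_offset),
    incisor_bone = list(mean_offset = mean(ib$pairs$offset),
                        proportion_positive = ib$proportion_positive,
                        n = nrow(ib$pairs)),
    water = list(true = config$annual_mean_lw,
                 estimated = water$d18O_lw,
                 error = water$d18O_lw - config$annual_mean_lw),
    diet = diet_cmp), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n",
      "  offset: true ", x$offset$true, ", est ",
      round_report(x$offset$estimated, 2), " (n = ", x$offset$n, ")\n",
      "  incisor - bone: mean ", round_report(x$incisor_bone$mean_offset, 2),
      ", ", round_report(100 * x$incisor_bone$proportion_positive, 0),
      "% positive\n",
      "  water: true ", x$water$true, ", est ",
      round_report(x$water$estimated, 2), "\n", sep = "")
  invisible(x)
}
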