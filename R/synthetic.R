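# Synthetic-data generators for the six input streams of the pipeline:
# weather, emergence counts, biomass samples, stage-attainment intervals,
# fecundity (calibration + per-plant panicle inventories) and pot responses.
# Defaults bundle published parameter estimates as generating truth so tests
# and examples run at field-realistic magnitudes with no external data.

# Generating truth per season. Emergence (b, g50) per species; biomass
# (c, time50, d without/with crop) per species with the season's curve
# family; stage-attainment means (degree C day, BBCH 93 = seed shedding);
# fecundity group means and suppression ratios; DENS50 per competition cell.
scenario_truth <- function(year) {
  if (year == "2017_18") {
    list(
      family = "weibull",
      sowing = as.Date("2017-10-10"),
      emergence = data.frame(
        species = c("V_myuros", "L_multiflorum", "A_myosuroides", "A_spica_venti"),
        b = c(-5.0, -5.7, -5.0, -4.8),
        g50 = c(197, 179, 221, 265)),
      biomass = data.frame(
        species = c("V_myuros", "L_multiflorum", "A_myosuroides"),
        c = c(11.4, 6.0, 8.7),
        time50 = c(1317, 1251, 1230),
        d_minus = c(14.8, 14.9, 16.4),
        d_plus = c(1.5, 6.2, 4.7)),
      stages = data.frame(
        species = rep(c("V_myuros", "L_multiflorum", "A_myosuroides", "A_spica_venti"),
                      each = 3L),
        bbch_stage = rep(c(21, 51, 93), times = 4L),
        mean_tt_c = c(420, 1120, 1567,   400, 1060, 1646,
                      380, 1000, 1387,   480, 1260, 1690),
        sd_tt_c = 60),
      fecundity = data.frame(
        species = c("V_myuros", "L_multiflorum", "A_myosuroides"),
        mean_minus = c(14478, 2364, 4896),
        ratio = c(0.04, 0.20, 0.19),
        slope = c(20, 15, 18)),
      competition = data.frame(
        species = rep(c("V_myuros", "A_spica_venti"), each = 4L),
        crop_stage = rep("2_leaf", 8L),
        harvest = rep(c("BBCH_26_29", "BBCH_39_47", "BBCH_81_90", "seeds"), 2L),
        a = rep(c(2, 10, 20, 2000), 2L),
        dens50 = c(104, 28, 30, 39,   35, 92, 82, 35))
    )
  } else {
    list(
      family = "loglogistic",
      sowing = as.Date("2018-09-13"),
      emergence = data.frame(
        species = c("V_myuros", "L_multiflorum", "A_myosuroides", "A_spica_venti"),
        b = c(-4.9, -9.5, -5.0, -5.2),
        g50 = c(237, 199, 250, 288)),
      biomass = data.frame(
        species = c("V_myuros", "L_multiflorum", "A_myosuroides"),
        c = c(-10.1, -11.7, -9.8),
        time50 = c(1548, 1380, 1319),
        d_minus = c(29.3, 15.2, 22.0),
        d_plus = c(5.4, 10.3, 7.1)),
      stages = data.frame(
        species = rep(c("V_myuros", "L_multiflorum", "A_myosuroides", "A_spica_venti"),
                      each = 3L),
        bbch_stage = rep(c(21, 51, 93), times = 4L),
        mean_tt_c = c(560, 1540, 2165,   540, 1480, 2213,
                      500, 1380, 1870,   660, 1720, 2249),
        sd_tt_c = 60),
      fecundity = data.frame(
        species = c("V_myuros", "L_multiflorum", "A_myosuroides"),
        mean_minus = c(16680, 4264, 12120),
        ratio = c(0.11, 0.22, 0.24),
        slope = c(20, 15, 18)),
      competition = data.frame(
        species = rep(c("V_myuros", "A_spica_venti"), each = 4L),
        crop_stage = rep("2_leaf", 8L),
        harvest = rep(c("BBCH_26_29", "BBCH_39_47", "BBCH_81_90", "seeds"), 2L),
        a = rep(c(2, 10, 20, 2000), 2L),
        dens50 = c(30, 10, 14, 18,   17, 29, 51, 43))
    )
  }
}

#' Scenario configuration for the synthetic-data generators
#'
#' Bundles generating truth and design sizes for all six input streams.
#' Defaults mirror the two field seasons: season-specific emergence and
#' growth parameters, a Weibull biomass family for 2017/18 and log-logistic
#' for 2018/19, inspection schedules of 10 (2017/18) or 6 (2018/19)
#' emergence counts, 6 biomass samplings, around 19 seedlings per 0.25 m^2
#' quadrat, 15 marked plants per species for phenology and fecundity, and
#' the six-density target-neighbourhood pot design with 4 replicates.
#' Any element can be overridden via `...`.
#'
#' @param seed Integer RNG seed recorded in the config; each generator
#'   derives its own stream from it. `NULL` leaves the RNG state untouched.
#' @param year `"2017_18"` or `"2018_19"`.
#' @param ... Named overrides of config elements (e.g. `n_per_quadrat`,
#'   `n_units`, `noise_cv`, `inspection_tt`, `species`).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(seed = NULL, year = c("2017_18", "2018_19"), ...) {
  year <- match.arg(year)
  truth <- scenario_truth(year)
  cfg <- list(
    seed = seed,
    year = year,
    family = truth$family,
    sowing = truth$sowing,
    truth = truth,
    species = truth$emergence$species,
    # emergence design
    inspection_tt = if (year == "2017_18") {
      c(40, 70, 100, 130, 170, 240, 310, 380, 450, 520)
    } else {
      c(60, 120, 180, 260, 360, 480)
    },
    n_units = if (year == "2017_18") 9L else 6L,  # plots x quadrats
    n_per_quadrat = 19L,                          # ~75 plants/m2 on 0.25 m2
    # biomass design
    biomass_tt = c(600, 900, 1200, 1500, 1800, 2100),
    n_plots = 3L,
    noise_cv = 0.10,                              # sd as fraction of d
    # phenology design
    n_plants = 15L,                               # 5 marked plants x 3 blocks
    stage_grid_step = 90,                         # ~ biweekly scoring, degree C d
    # fecundity design
    n_calib = 30L,
    length_meanlog = log(12), length_sdlog = 0.3,
    # competition design
    densities = c(0, 48, 96, 192, 288, 576),
    n_reps = 4L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Synthetic scenario: season %s (%s biomass family), seed %s\n",
              x$year, x$family, x$seed %||% "<unset>"))
  cat(sprintf("  species: %s\n", paste(x$species, collapse = ", ")))
  cat(sprintf("  %d emergence units x %d seeds, %d biomass plots, %d plants, %d pot reps\n",
              x$n_units, x$n_per_quadrat, x$n_plots, x$n_plants, x$n_reps))
  invisible(x)
}

# Derive a per-stream seed from the config seed; offsets keep streams
# distinct while staying within 32-bit integer range.
stream_seed <- function(config, offset) {
  if (!is.null(config$seed)) {
    set.seed((as.integer(config$seed) + offset) %% .Machine$integer.max)
  }
  invisible(NULL)
}

#' Generate a daily weather series
#'
#' Sinusoidal annual mean temperature with Gaussian daily noise, returned
#' for both an air and a (damped, lagged) soil sensor, covering sowing
#' through the following August.
#'
#' @param config A [scenario_config()].
#' @return Weather data frame (`date`, `tmin_c`, `tmax_c`, `source`) with
#'   contiguous dates per source.
#' @export
gen_weather <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  stream_seed(config, 0L)
  start <- config$sowing - 9L
  end <- as.Date(paste0(as.integer(format(config$sowing, "%Y")) + 1L, "-08-31"))
  dates <- seq(start, end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  mean_air <- 8.5 + 8 * cos(2 * pi * (doy - 196) / 365.25)
  noise <- stats::rnorm(length(dates), 0, 2)
  half_range <- 4 + abs(stats::rnorm(length(dates), 0, 1.5))
  air <- data.frame(date = dates,
                    tmin_c = mean_air + noise - half_range,
                    tmax_c = mean_air + noise + half_range,
                    source = "air")
  mean_soil <- 1 + 0.9 * (8.5 + 6 * cos(2 * pi * (doy - 206) / 365.25))
  noise_s <- stats::rnorm(length(dates), 0, 1)
  hr_s <- 2 + abs(stats::rnorm(length(dates), 0, 0.75))
  soil <- data.frame(date = dates,
                     tmin_c = mean_soil + noise_s - hr_s,
                     tmax_c = mean_soil + noise_s + hr_s,
                     source = "soil")
  rbind(air, soil)
}

# Inverse-CDF draw of log-logistic emergence times.
rloglogistic <- function(n, b, g50) {
  u <- stats::runif(n)
  g50 * ((1 - u) / u)^(1 / b)
}

#' Generate grouped emergence counts
#'
#' Per quadrat, `n_per_quadrat` seeds receive i.i.d. log-logistic emergence
#' times with the species' `(b, g50)`; cumulative counts are tallied at the
#' inspection schedule. Times beyond the last inspection remain unobserved
#' (the final count may fall short of the number sown).
#'
#' @param config A [scenario_config()].
#' @return Data frame `unit_id, species, crop, year, cum_tt_c, cum_count,
#'   n_sown`.
#' @export
gen_emergence <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  stream_seed(config, 1L)
  tt <- config$inspection_tt
  out <- list()
  for (i in seq_len(nrow(config$truth$emergence))) {
    sp <- config$truth$emergence$species[i]
    b <- config$truth$emergence$b[i]
    g50 <- config$truth$emergence$g50[i]
    for (u in seq_len(config$n_units)) {
      times <- rloglogistic(config$n_per_quadrat, b, g50)
      counts <- vapply(tt, function(x) sum(times <= x), integer(1))
      out[[length(out) + 1L]] <- data.frame(
        unit_id = sprintf("%s_u%02d", sp, u),
        species = sp,
        crop = (u %% 2L),
        year = config$year,
        cum_tt_c = tt,
        cum_count = counts,
        n_sown = config$n_per_quadrat)
    }
  }
  do.call(rbind, out)
}

#' Generate per-plant biomass samples
#'
#' Season-family growth curve value plus Gaussian noise (sd =
#' `noise_cv * d`), truncated at zero, at the 6 sampling thermal times for
#' each plot. Crop treatments differ only in the upper limit `d`
#' (the configured suppression ratio).
#'
#' @param config A [scenario_config()].
#' @return Data frame `plot_id, species, crop, year, cum_tt_c,
#'   dm_per_plant_g`.
#' @export
gen_biomass <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  stream_seed(config, 2L)
  fn <- growth_mean_fun(config$family)
  out <- list()
  for (i in seq_len(nrow(config$truth$biomass))) {
    row <- config$truth$biomass[i, ]
    # Printed timing values are TIME50; Weibull needs the scale e.
    timing <- if (config$family == "weibull") {
      row$time50 * log(2)^(1 / abs(row$c))
    } else {
      row$time50
    }
    for (crop in c(0L, 1L)) {
      d <- if (crop == 0L) row$d_minus else row$d_plus
      mu <- fn(config$biomass_tt, row$c, d, timing)
      for (p in seq_len(config$n_plots)) {
        y <- pmax(0, mu + stats::rnorm(length(mu), 0, config$noise_cv * d))
        out[[length(out) + 1L]] <- data.frame(
          plot_id = sprintf("%s_c%d_p%d", row$species, crop, p),
          species = row$species, crop = crop, year = config$year,
          cum_tt_c = config$biomass_tt, dm_per_plant_g = y)
      }
    }
  }
  do.call(rbind, out)
}

#' Generate interval-censored stage-attainment records
#'
#' Latent attainment times are Normal(stage mean, SD) truncated positive;
#' the reported interval is the pair of consecutive scoring times (a grid
#' with step `stage_grid_step`) that brackets the latent time. The latent
#' times are attached as attribute `"latent"` for round-trip checks.
#'
#' @param config A [scenario_config()].
#' @return Data frame `plant_id, species, crop, year, bbch_stage, tt_lo_c,
#'   tt_hi_c` with attribute `latent`.
#' @export
gen_stage_intervals <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  stream_seed(config, 3L)
  step <- config$stage_grid_step
  out <- list()
  latents <- numeric(0)
  for (i in seq_len(nrow(config$truth$stages))) {
    row <- config$truth$stages[i, ]
    lat <- stats::rnorm(config$n_plants, row$mean_tt_c, row$sd_tt_c)
    while (any(lat <= 0)) lat[lat <= 0] <- stats::rnorm(sum(lat <= 0), row$mean_tt_c, row$sd_tt_c)
    lo <- floor(lat / step) * step
    out[[length(out) + 1L]] <- data.frame(
      plant_id = sprintf("%s_s%g_pl%02d", row$species, row$bbch_stage,
                         seq_len(config$n_plants)),
      species = row$species,
      crop = rep_len(c(0L, 1L), config$n_plants),
      year = config$year,
      bbch_stage = row$bbch_stage,
      tt_lo_c = lo, tt_hi_c = lo + step)
    latents <- c(latents, lat)
  }
  res <- do.call(rbind, out)
  attr(res, "latent") <- latents
  res
}

#' Generate fecundity calibration records and plant panicle inventories
#'
#' Calibration: panicle lengths are log-normal; seed counts are
#' Poisson(slope x length), giving a through-origin linear mean relation.
#' Plants: panicle counts per plant are Poisson with a mean chosen so that
#' expected seeds per plant equals the configured group mean; crop presence
#' multiplies the panicle-count mean by the configured suppression ratio.
#'
#' @param config A [scenario_config()].
#' @return List with `calibration` (`species, length_cm, seed_count`) and
#'   `plants` (`plant_id, species, crop, year, panicle_lengths` with lengths
#'   semicolon-joined, as in the plant CSV schema).
#' @export
gen_fecundity <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  stream_seed(config, 4L)
  mean_len <- exp(config$length_meanlog + config$length_sdlog^2 / 2)
  calib <- list()
  plants <- list()
  for (i in seq_len(nrow(config$truth$fecundity))) {
    row <- config$truth$fecundity[i, ]
    len <- stats::rlnorm(config$n_calib, config$length_meanlog, config$length_sdlog)
    calib[[length(calib) + 1L]] <- data.frame(
      species = row$species, length_cm = len,
      seed_count = stats::rpois(config$n_calib, row$slope * len))
    for (crop in c(0L, 1L)) {
      lambda <- row$mean_minus * (if (crop == 1L) row$ratio else 1) /
        (row$slope * mean_len)
      n_pan <- stats::rpois(config$n_plants, lambda)
      pl <- vapply(n_pan, function(k) {
        if (k == 0L) return("")
        paste(sprintf("%.2f", stats::rlnorm(k, config$length_meanlog,
                                            config$length_sdlog)),
              collapse = ";")
      }, character(1))
      plants[[length(plants) + 1L]] <- data.frame(
        plant_id = sprintf("%s_c%d_pl%02d", row$species, crop,
                           seq_len(config$n_plants)),
        species = row$species, crop = crop, year = config$year,
        panicle_lengths = pl)
    }
  }
  list(calibration = do.call(rbind, calib), plants = do.call(rbind, plants))
}

#' Parse semicolon-joined panicle lengths from the plant CSV schema
#'
#' @param x Character vector like `"12.30;9.81;15.02"` (empty string for a
#'   plant with no panicles).
#' @return List of numeric vectors.
#' @export
parse_lengths <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    as.numeric(v)
  })
}

#' Generate target-neighbourhood pot observations
#'
#' Hyperbolic mean response plus Gaussian noise (sd = `noise_cv * a`,
#' truncated at zero) at the six wheat densities, for each configured
#' species x crop-stage x harvest cell and replicate.
#'
#' @param config A [scenario_config()].
#' @return Data frame `species, crop_stage, density_m2, harvest, response,
#'   response_type, rep`.
#' @export
gen_competition <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  stream_seed(config, 5L)
  out <- list()
  for (i in seq_len(nrow(config$truth$competition))) {
    row <- config$truth$competition[i, ]
    mu <- hyperbolic_curve(config$densities, row$a, row$dens50)
    for (r in seq_len(config$n_reps)) {
      out[[length(out) + 1L]] <- data.frame(
        species = row$species, crop_stage = row$crop_stage,
        density_m2 = config$densities, harvest = row$harvest,
        response = pmax(0, mu + stats::rnorm(length(mu), 0, config$noise_cv * row$a)),
        response_type = if (row$harvest == "seeds") "seeds" else "dm_g",
        rep = r)
    }
  }
  do.call(rbind, out)
}

#' Write a full synthetic scenario to CSV files
#'
#' Generates all six input streams and writes them under `dir` as
#' `weather.csv`, `emergence.csv`, `biomass.csv`, `stages.csv`,
#' `calibration.csv`, `plants.csv`, `pots.csv`, plus `manifest.json`
#' recording the generating truth, seed and design sizes for test
#' harnesses. Regenerating with the same config and seed is byte-identical.
#'
#' @param config A [scenario_config()] (with a non-`NULL` seed for
#'   reproducibility).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_scenario <- function(config, dir) {
  stopifnot(inherits(config, "scenario_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fec <- gen_fecundity(config)
  streams <- list(
    weather = gen_weather(config),
    emergence = gen_emergence(config),
    biomass = gen_biomass(config),
    stages = gen_stage_intervals(config),
    calibration = fec$calibration,
    plants = fec$plants,
    pots = gen_competition(config)
  )
  paths <- character(0)
  for (nm in names(streams)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    df <- streams[[nm]]
    attr(df, "latent") <- NULL
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[nm] <- p
  }
  manifest <- list(
    year = config$year, seed = config$seed, family = config$family,
    sowing = format(config$sowing),
    truth = lapply(config$truth[c("emergence", "biomass", "stages",
                                  "fecundity", "competition")], as.list),
    design = config[c("inspection_tt", "n_units", "n_per_quadrat",
                      "biomass_tt", "n_plots", "noise_cv", "n_plants",
                      "stage_grid_step", "n_calib", "densities", "n_reps")]
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["manifest"] <- mp
  invisible(paths)
}
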