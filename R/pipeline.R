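# Orchestration: validate input CSVs and run the full analysis from files to
# report tables mirroring the published table layouts.

read_stream <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

stream_schemas <- list(
  weather = c("date", "tmin_c", "tmax_c", "source"),
  emergence = c("unit_id", "species", "crop", "year", "cum_tt_c", "cum_count"),
  biomass = c("plot_id", "species", "crop", "year", "cum_tt_c", "dm_per_plant_g"),
  stages = c("plant_id", "species", "crop", "year", "bbch_stage", "tt_lo_c", "tt_hi_c"),
  calibration = c("species", "length_cm", "seed_count"),
  plants = c("plant_id", "species", "crop", "year", "panicle_lengths"),
  pots = c("species", "crop_stage", "density_m2", "harvest", "response",
           "response_type", "rep")
)

issue_row <- function(file, row, issue) {
  data.frame(file = file, row = row, issue = issue, stringsAsFactors = FALSE)
}

#' Validate pipeline input files
#'
#' Checks each supplied CSV against its stream schema and row-level
#' invariants (monotone cumulative counts, ordered intervals, nonnegative
#' responses, valid weather records), plus cross-file species-label
#' consistency. Column order is irrelevant (header-based matching). Never
#' raises: returns a machine-readable issue table, empty when everything is
#' valid.
#'
#' @param paths Named list/vector of file paths; recognised names are
#'   `weather`, `emergence`, `biomass`, `stages`, `calibration`, `plants`,
#'   `pots`. Missing entries are skipped.
#' @return Data frame with columns `file`, `row`, `issue` (zero rows when
#'   clean).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- issue_row(...)
  species_seen <- list()

  for (nm in intersect(names(stream_schemas), names(paths))) {
    path <- paths[[nm]]
    if (is.null(path) || is.na(path)) next
    if (!file.exists(path)) {
      add(nm, NA_integer_, sprintf("file not found: %s", path))
      next
    }
    df <- try(read_stream(path), silent = TRUE)
    if (inherits(df, "try-error")) {
      add(nm, NA_integer_, "file could not be parsed as CSV")
      next
    }
    missing <- setdiff(stream_schemas[[nm]], names(df))
    if (length(missing) > 0L) {
      add(nm, NA_integer_, sprintf("missing column(s): %s",
                                   paste(missing, collapse = ", ")))
      next
    }
    if ("species" %in% names(df)) {
      species_seen[[nm]] <- unique(as.character(df$species))
    }
    switch(nm,
      weather = {
        bad <- which(df$tmin_c > df$tmax_c)
        for (r in bad) add(nm, r, "tmin_c > tmax_c")
        for (src in unique(df$source)) {
          sub <- df[df$source == src, , drop = FALSE]
          dts <- sort(as.Date(sub$date))
          if (anyDuplicated(dts)) add(nm, NA_integer_,
                                      sprintf("duplicate dates in source '%s'", src))
          if (length(dts) > 1L && any(diff(dts) > 1L)) {
            add(nm, NA_integer_, sprintf("date gap in source '%s'", src))
          }
        }
      },
      emergence = {
        for (u in unique(df$unit_id)) {
          ix <- which(df$unit_id == u)
          sub <- df[ix, , drop = FALSE]
          ord <- order(sub$cum_tt_c)
          if (any(diff(sub$cum_tt_c[ord]) <= 0)) {
            add(nm, ix[1L], sprintf("unit '%s': inspection times not strictly increasing", u))
          }
          drops <- which(diff(sub$cum_count[ord]) < 0)
          for (k in drops) {
            add(nm, ix[ord][k + 1L],
                sprintf("unit '%s': cumulative count decreases", u))
          }
        }
      },
      biomass = {
        bad <- which(df$cum_tt_c <= 0 | df$dm_per_plant_g < 0)
        for (r in bad) add(nm, r, "nonpositive thermal time or negative biomass")
      },
      stages = {
        bad <- which(df$tt_lo_c > df$tt_hi_c | df$tt_lo_c < 0)
        for (r in bad) add(nm, r, "invalid stage interval")
      },
      calibration = {
        bad <- which(df$length_cm <= 0 | df$seed_count < 0)
        for (r in bad) add(nm, r, "invalid calibration record")
      },
      plants = NULL,
      pots = {
        bad <- which(df$density_m2 < 0 | df$response < 0)
        for (r in bad) add(nm, r, "negative density or response")
      }
    )
  }

  if (length(species_seen) > 1L) {
    pool <- sort(unique(unlist(species_seen)))
    core <- intersect(names(species_seen), c("emergence", "biomass", "stages"))
    for (nm in core) {
      extra <- setdiff(species_seen[[nm]], Reduce(union, species_seen[setdiff(core, nm)]))
      if (length(core) > 1L && length(extra) > 0L && length(extra) == length(pool)) {
        add(nm, NA_integer_, "species labels inconsistent with other files")
      }
    }
  }

  if (length(issues) == 0L) {
    data.frame(file = character(0), row = integer(0), issue = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, issues)
  }
}

#' Run the full analysis pipeline from CSV inputs to report tables
#'
#' Orchestrates every stage for which inputs are present: emergence fits
#' and GERM10/50/90 per species; growth fits with TIME50, lack-of-fit and
#' crop-suppression d-ratios; pairwise interval-censored phenology
#' comparisons with bootstrap means; fecundity calibration, per-plant seed
#' estimates and suppression ratio tests; hyperbolic competition fits with
#' pairwise DENS50 comparisons. Stages whose inputs are absent are skipped
#' with a log entry; report CSVs and a JSON run manifest are written to
#' `out_dir` when given.
#'
#' @param config Named list or path to a YAML file with elements: `inputs`
#'   (named paths as in [validate_inputs()]), `year` label, `family`
#'   (biomass curve family, default by year suffix), `n_perm` (default
#'   1000), `n_boot` (default 10000), `base_temp` (default 1), `seed`
#'   (integer; mandatory for the stochastic stages), `out_dir` (optional).
#' @return Invisibly, a list of report data frames (`emergence`, `growth`,
#'   `phenology_means`, `phenology_pairwise`, `fecundity`, `competition`,
#'   `competition_pairwise`) plus `log` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  inputs <- config$inputs %||% list()
  n_perm <- config$n_perm %||% 1000L
  n_boot <- config$n_boot %||% 10000L
  seed <- config$seed
  if (is.null(seed)) pk_stop("config$seed is required", "config")

  have <- names(inputs)[vapply(inputs, function(p)
    is.character(p) && file.exists(p), logical(1))]
  if (length(have) == 0L) {
    pk_stop("no readable input files in config$inputs", "validation")
  }
  issues <- validate_inputs(inputs[have])
  if (nrow(issues) > 0L) {
    pk_stop(sprintf("input validation failed with %d issue(s); first: [%s row %s] %s",
                    nrow(issues), issues$file[1L],
                    format(issues$row[1L]), issues$issue[1L]),
            "validation")
  }

  log_lines <- character(0)
  note <- function(msg) log_lines <<- c(log_lines, msg)
  reports <- list()

  if ("emergence" %in% have) {
    df <- read_stream(inputs$emergence)
    rows <- list()
    for (sp in unique(df$species)) {
      fit <- try(fit_emergence(df[df$species == sp, , drop = FALSE]), silent = TRUE)
      if (inherits(fit, "try-error")) {
        note(sprintf("emergence: fit failed for %s", sp))
        next
      }
      qs <- lapply(c(0.10, 0.50, 0.90), function(p) emergence_quantile(fit, p))
      se_b <- if (!is.null(fit$vcov)) sqrt(fit$vcov[1, 1]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, b = fit$b,
        b_lo = fit$b - stats::qnorm(0.975) * se_b,
        b_hi = fit$b + stats::qnorm(0.975) * se_b,
        germ10 = qs[[1]]$estimate, germ10_lo = qs[[1]]$lo, germ10_hi = qs[[1]]$hi,
        germ50 = qs[[2]]$estimate, germ50_lo = qs[[2]]$lo, germ50_hi = qs[[2]]$hi,
        germ90 = qs[[3]]$estimate, germ90_lo = qs[[3]]$lo, germ90_hi = qs[[3]]$hi)
    }
    reports$emergence <- do.call(rbind, rows)
  } else note("emergence: no input, skipped")

  if ("biomass" %in% have) {
    df <- read_stream(inputs$biomass)
    family <- config$family %||%
      (if (grepl("2017", config$year %||% "")) "weibull" else "loglogistic")
    rows <- list()
    for (sp in unique(df$species)) {
      fits <- list()
      for (crop in c(0L, 1L)) {
        sub <- df[df$species == sp & df$crop == crop, , drop = FALSE]
        if (nrow(sub) == 0L) next
        fit <- try(fit_growth(sub, family = family), silent = TRUE)
        if (inherits(fit, "try-error")) {
          note(sprintf("growth: fit failed for %s crop=%d", sp, crop))
          next
        }
        lof <- try(lack_of_fit(fit, sub), silent = TRUE)
        fits[[as.character(crop)]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, crop = crop, family = family,
          c = fit$c, c_se = fit$se[["c"]],
          time50 = time50(fit), timing = fit$timing,
          timing_se = fit$se[["timing"]],
          d = fit$d, d_se = fit$se[["d"]],
          lof_p = if (inherits(lof, "try-error")) NA_real_ else lof$p_value,
          ratio = NA_real_, ratio_se = NA_real_, ratio_p = NA_real_)
      }
      if (all(c("0", "1") %in% names(fits))) {
        sr <- suppression_ratio(fits[["0"]], fits[["1"]])
        k <- length(rows)
        rows[[k]]$ratio <- sr$ratio
        rows[[k]]$ratio_se <- sr$se
        rows[[k]]$ratio_p <- sr$p_value
      }
    }
    reports$growth <- do.call(rbind, rows)
  } else note("growth: no input, skipped")

  if ("stages" %in% have) {
    df <- read_stream(inputs$stages)
    set.seed(seed)
    cmp <- compare_stages(df, n_iter = n_perm, n_boot = n_boot)
    reports$phenology_means <- cmp$means
    reports$phenology_pairwise <- cmp$pairwise
  } else note("phenology: no input, skipped")

  if (all(c("calibration", "plants") %in% have)) {
    calib_df <- read_stream(inputs$calibration)
    plants_df <- read_stream(inputs$plants)
    set.seed(seed + 1L)
    rows <- list()
    for (sp in unique(plants_df$species)) {
      cal <- try(calibrate(calib_df[calib_df$species == sp, , drop = FALSE]),
                 silent = TRUE)
      if (inherits(cal, "try-error")) {
        note(sprintf("fecundity: calibration failed for %s", sp))
        next
      }
      sub <- plants_df[plants_df$species == sp, , drop = FALSE]
      seeds <- suppressWarnings(vapply(parse_lengths(sub$panicle_lengths),
                                       function(l) estimate_plant(cal, l),
                                       numeric(1)))
      minus <- seeds[sub$crop == 0L]
      plus <- seeds[sub$crop == 1L]
      if (length(minus) == 0L || length(plus) == 0L || mean(minus) == 0) {
        note(sprintf("fecundity: missing treatment group for %s", sp))
        next
      }
      rt <- fecundity_ratio_test(minus, plus, n_perm = n_perm, n_boot = n_boot)
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, r_squared = cal$r_squared,
        mean_minus = mean(minus), mean_plus = mean(plus),
        ratio = rt$ratio, ratio_lo = rt$lo, ratio_hi = rt$hi,
        p_value = rt$p_value)
    }
    reports$fecundity <- do.call(rbind, rows)
  } else note("fecundity: calibration and/or plants input missing, skipped")

  if ("pots" %in% have) {
    df <- read_stream(inputs$pots)
    cells <- unique(df[, c("species", "crop_stage", "harvest")])
    fits <- list()
    rows <- list()
    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      sub <- df[df$species == cell$species & df$crop_stage == cell$crop_stage &
                  df$harvest == cell$harvest, , drop = FALSE]
      fit <- try(fit_hyperbolic(sub), silent = TRUE)
      if (inherits(fit, "try-error")) {
        note(sprintf("competition: fit failed for %s/%s/%s",
                     cell$species, cell$crop_stage, cell$harvest))
        next
      }
      key <- paste(cell$species, cell$crop_stage, cell$harvest, sep = "|")
      fits[[key]] <- fit
      rows[[length(rows) + 1L]] <- data.frame(
        species = cell$species, crop_stage = cell$crop_stage,
        harvest = cell$harvest, a = fit$a, a_se = fit$se_a,
        dens50 = fit$dens50, dens50_se = fit$se_dens50,
        converged = fit$converged)
    }
    reports$competition <- do.call(rbind, rows)
    prs <- list()
    for (hv in unique(cells$harvest)) {
      for (cs in unique(cells$crop_stage)) {
        keys <- names(fits)[vapply(names(fits), function(k) {
          parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
          parts[2L] == cs && parts[3L] == hv && isTRUE(fits[[k]]$converged)
        }, logical(1))]
        if (length(keys) < 2L) next
        cmb <- utils::combn(keys, 2L)
        for (k in seq_len(ncol(cmb))) {
          w <- compare_dens50(fits[[cmb[1L, k]]], fits[[cmb[2L, k]]])
          prs[[length(prs) + 1L]] <- data.frame(
            crop_stage = cs, harvest = hv,
            speciesA = strsplit(cmb[1L, k], "|", fixed = TRUE)[[1L]][1L],
            speciesB = strsplit(cmb[2L, k], "|", fixed = TRUE)[[1L]][1L],
            diff = w$difference, p_value = w$p_value)
        }
      }
    }
    reports$competition_pairwise <- if (length(prs) > 0L) do.call(rbind, prs) else NULL
  } else note("competition: no input, skipped")

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenokit")),
    seed = seed, n_perm = n_perm, n_boot = n_boot,
    year = config$year %||% NA, inputs = inputs[have],
    skipped = log_lines,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports)) {
      if (is.null(reports[[nm]])) next
      utils::write.csv(reports[[nm]],
                       file.path(config$out_dir, paste0("report_", nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(c(reports, list(log = log_lines, manifest = manifest)))
}
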