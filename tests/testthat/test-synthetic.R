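test_that("generators are deterministic given config and seed", {
  cfg <- tiny_scenario(77)
  for (gen in list(gen_weather, gen_emergence, gen_biomass,
                   gen_stage_intervals, gen_competition)) {
    a <- gen(cfg)
    b <- gen(cfg)
    attr(a, "latent") <- attr(b, "latent") <- NULL
    expect_identical(a, b)
  }
  f1 <- gen_fecundity(cfg)
  f2 <- gen_fecundity(cfg)
  expect_identical(f1, f2)
})

test_that("written scenario files are byte-identical across runs", {
  cfg <- tiny_scenario(78)
  d1 <- file.path(tempdir(), "scenA")
  d2 <- file.path(tempdir(), "scenB")
  p1 <- write_scenario(cfg, d1)
  p2 <- write_scenario(cfg, d2)
  for (nm in setdiff(names(p1), "manifest")) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generated weather passes thermal-time validation and has seasons", {
  cfg <- tiny_scenario(79)
  w <- gen_weather(cfg)
  expect_true(all(w$tmin_c <= w$tmax_c))
  air <- w[w$source == "air", ]
  s <- accumulate_thermal_time(air, origin = cfg$sowing)
  expect_true(all(diff(s$cum_tt_c) >= 0))
  # summer means exceed winter means
  mo <- as.integer(format(as.Date(air$date), "%m"))
  mean_t <- (air$tmin_c + air$tmax_c) / 2
  expect_gt(mean(mean_t[mo %in% 6:8]), mean(mean_t[mo %in% c(12, 1, 2)]))
  # soil series also accumulates cleanly
  expect_silent(accumulate_thermal_time(w[w$source == "soil", ],
                                        origin = cfg$sowing))
})

test_that("emergence generator matches its CDF and round-trips through the fitter", {
  cfg <- scenario_config(seed = 80)
  # law of large numbers at g50: half of the seeds have emerged
  set.seed(80)
  times <- phenokit:::rloglogistic(1e4, b = -5, g50 = 200)
  expect_equal(mean(times <= 200), 0.5, tolerance = 3 * 0.005)

  e <- gen_emergence(cfg)
  truth <- cfg$truth$emergence
  sp <- "V_myuros"
  fit <- fit_emergence(e[e$species == sp, ])
  tr <- truth[truth$species == sp, ]
  expect_lt(abs(fit$b - tr$b) / sqrt(fit$vcov[1, 1]), 3)
  expect_lt(abs(log(fit$g50) - log(tr$g50)) / sqrt(fit$vcov[2, 2]), 3)

  # zero seeds give all-zero counts
  cfg0 <- scenario_config(seed = 80, n_per_quadrat = 0L)
  e0 <- gen_emergence(cfg0)
  expect_true(all(e0$cum_count == 0))
})

test_that("biomass generator round-trips the suppression ratio", {
  cfg <- scenario_config(seed = 81, n_plots = 4L)
  b <- gen_biomass(cfg)
  tr <- cfg$truth$biomass[cfg$truth$biomass$species == "L_multiflorum", ]
  fm <- fit_growth(b[b$species == "L_multiflorum" & b$crop == 0, ], cfg$family)
  fp <- fit_growth(b[b$species == "L_multiflorum" & b$crop == 1, ], cfg$family)
  r <- suppression_ratio(fm, fp)
  expect_equal(r$ratio, tr$d_plus / tr$d_minus, tolerance = 0.35)
  # zero-noise data refit exactly
  cfg0 <- scenario_config(seed = 81, noise_cv = 0)
  b0 <- gen_biomass(cfg0)
  f0 <- fit_growth(b0[b0$species == "V_myuros" & b0$crop == 0, ], cfg0$family)
  tr0 <- cfg0$truth$biomass[cfg0$truth$biomass$species == "V_myuros", ]
  expect_equal(f0$d, tr0$d_minus, tolerance = 1e-4)
  expect_equal(time50(f0), tr0$time50, tolerance = 0.1)
  expect_true(all(gen_biomass(cfg)$dm_per_plant_g >= 0))
})

test_that("stage intervals bracket their latent times and track the grid width", {
  cfg <- tiny_scenario(82)
  st <- gen_stage_intervals(cfg)
  lat <- attr(st, "latent")
  expect_true(all(st$tt_lo_c < lat & lat <= st$tt_hi_c))
  expect_true(all(st$tt_hi_c - st$tt_lo_c == cfg$stage_grid_step))

  cfg_wide <- tiny_scenario(82)
  cfg_wide$stage_grid_step <- 180
  st_w <- gen_stage_intervals(cfg_wide)
  expect_gt(mean(st_w$tt_hi_c - st_w$tt_lo_c), mean(st$tt_hi_c - st$tt_lo_c))

  # equal-mean species under the null: rejection rate near the nominal level
  set.seed(83)
  rej <- replicate(200, {
    lo <- floor(rnorm(16, 1400, 60) / 90) * 90
    iv <- data.frame(tt_lo_c = lo, tt_hi_c = lo + 90)
    lab <- sample(16) <= 8
    mc_permutation_test(iv[lab, ], iv[!lab, ], n_iter = 200)$p_value <= 0.05
  })
  expect_lte(mean(rej), 0.10)
})

test_that("fecundity generator round-trips calibration and suppression", {
  cfg <- scenario_config(seed = 84)
  fec <- gen_fecundity(cfg)
  tr <- cfg$truth$fecundity
  sp <- "A_myosuroides"
  cal <- calibrate(fec$calibration[fec$calibration$species == sp, ])
  expect_lt(abs(cal$slope - tr$slope[tr$species == sp]) / cal$se_slope, 3)

  plants <- fec$plants[fec$plants$species == sp, ]
  seeds <- suppressWarnings(vapply(parse_lengths(plants$panicle_lengths),
                                   function(l) estimate_plant(cal, l), numeric(1)))
  set.seed(84)
  rt <- fecundity_ratio_test(seeds[plants$crop == 0], seeds[plants$crop == 1],
                             n_perm = 200, n_boot = 1000)
  truth_ratio <- tr$ratio[tr$species == sp]
  expect_true(rt$lo <= truth_ratio * 1.5 && truth_ratio * 0.5 <= rt$hi)
  expect_equal(rt$ratio, truth_ratio, tolerance = 0.5)

  # a plant with no panicles yields a zero estimate
  expect_equal(suppressWarnings(estimate_plant(cal, numeric(0))), 0)
})

test_that("competition generator round-trips and honours its mean structure", {
  cfg <- scenario_config(seed = 85, n_reps = 4L)
  pots <- gen_competition(cfg)
  tr <- cfg$truth$competition
  cell <- pots[pots$species == "V_myuros" & pots$harvest == "BBCH_26_29", ]
  fit <- fit_hyperbolic(cell)
  tr_cell <- tr[tr$species == "V_myuros" & tr$harvest == "BBCH_26_29", ]
  expect_equal(fit$dens50, tr_cell$dens50, tolerance = 0.5)
  # mean response at zero density approximates a
  expect_equal(mean(cell$response[cell$density_m2 == 0]), tr_cell$a,
               tolerance = 0.25)
})

test_that("every generated stream passes input validation", {
  cfg <- tiny_scenario(86)
  dir <- file.path(tempdir(), "scen_valid")
  paths <- write_scenario(cfg, dir)
  issues <- validate_inputs(as.list(paths[setdiff(names(paths), "manifest")]))
  expect_equal(nrow(issues), 0L)
  unlink(dir, recursive = TRUE)
})
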