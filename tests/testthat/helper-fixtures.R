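# Shared fixtures, built in code.

# Grouped counts lying exactly on a log-logistic CDF (expected multinomial
# counts, no rounding): the ML fit should recover the generating parameters.
exact_emergence_counts <- function(b, g50, times, n = 1e6, units = 1L) {
  do.call(rbind, lapply(seq_len(units), function(u) {
    data.frame(unit_id = paste0("u", u),
               cum_tt_c = times,
               cum_count = n * emergence_cdf(times, b, g50))
  }))
}

# Multinomial draws of grouped emergence counts from the log-logistic model,
# conditioning on all seeds emerging by the end of the schedule (no censored
# mass), matching the default fit contract.
simulate_emergence_counts <- function(b, g50, times, n_seeds, n_units) {
  do.call(rbind, lapply(seq_len(n_units), function(u) {
    usmp <- stats::runif(n_seeds)
    t_i <- g50 * ((1 - usmp) / usmp)^(1 / b)
    t_i <- t_i[t_i <= max(times)]
    data.frame(unit_id = paste0("u", u),
               cum_tt_c = times,
               cum_count = vapply(times, function(x) sum(t_i <= x), integer(1)))
  }))
}

# Biomass samples from a growth curve with Gaussian noise.
simulate_biomass <- function(family, c, d, timing, times, n_plots, sd) {
  fn <- if (family == "weibull") weibull_curve else loglogistic_curve
  mu <- fn(times, c, d, timing)
  do.call(rbind, lapply(seq_len(n_plots), function(p) {
    data.frame(cum_tt_c = times,
               dm_per_plant_g = pmax(0, mu + stats::rnorm(length(mu), 0, sd)))
  }))
}

# Exhaustive two-sample permutation p-value for point data: the proportion of
# all label assignments whose |mean difference| is at least the observed one
# (the observed assignment is among them, so p >= 1/choose(n, nA)).
exhaustive_perm_p <- function(a, b) {
  x <- c(a, b)
  nA <- length(a)
  s_obs <- abs(mean(a) - mean(b))
  combos <- utils::combn(length(x), nA)
  stats <- apply(combos, 2L, function(ix) abs(mean(x[ix]) - mean(x[-ix])))
  mean(stats >= s_obs - 1e-12)
}

tiny_scenario <- function(seed, year = "2017_18") {
  scenario_config(
    seed = seed, year = year,
    n_units = 4L, n_per_quadrat = 25L, n_plots = 3L, n_plants = 8L,
    n_reps = 3L, n_calib = 20L
  )
}
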