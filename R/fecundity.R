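# Seed-production estimation from panicle (or head) length, and crop-
# suppression inference on per-plant fecundity.

#' Calibrate seeds-per-panicle against panicle length
#'
#' Ordinary least-squares line of counted seeds on panicle (or head) length,
#' the calibration used to estimate per-plant seed production without
#' exhaustive counting. Calibration records from plants grown with and
#' without the crop are typically pooled when the crop effect on the
#' relation is nonsignificant.
#'
#' @param records Data frame with columns `length_cm` and `seed_count`
#'   (optionally `species`, carried through).
#' @return Object of class `seed_calibration`: `slope` (seeds/cm),
#'   `intercept` (seeds), `r_squared`, `n`, `species`.
#' @export
calibrate <- function(records) {
  check_columns(records, c("length_cm", "seed_count"), "calibration records")
  if (nrow(records) < 3L) {
    pk_stop("need at least 3 calibration records", "insufficient_data")
  }
  if (any(records$length_cm <= 0)) pk_stop("panicle lengths must be > 0", "domain")
  if (any(records$seed_count < 0)) pk_stop("seed counts must be >= 0", "domain")
  if (length(unique(records$length_cm)) < 2L) {
    pk_stop("all panicle lengths equal: calibration line is rank-deficient",
            "rank_deficiency")
  }
  fit <- stats::lm(seed_count ~ length_cm, data = records)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = sm$r.squared,
         se_slope = sm$coefficients[2L, 2L],
         n = nrow(records),
         species = if ("species" %in% names(records))
           unique(as.character(records$species))[1L] else NA_character_),
    class = "seed_calibration"
  )
}

#' @export
print.seed_calibration <- function(x, ...) {
  cat(sprintf("Seed calibration%s: seeds = %.2f + %.2f x length_cm (R^2 = %.2f, n = %d)\n",
              if (is.na(x$species)) "" else paste0(" [", x$species, "]"),
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Estimate a plant's seed production from its panicle lengths
#'
#' Applies the calibration line to every panicle on the plant, clamps
#' negative per-panicle predictions at zero, sums, and rounds to the nearest
#' whole seed at the plant level.
#'
#' @param calibration A `seed_calibration`.
#' @param lengths Numeric vector of panicle/head lengths (cm) on one plant.
#' @return Estimated seeds per plant (integer-valued numeric).
#' @export
estimate_plant <- function(calibration, lengths) {
  stopifnot(inherits(calibration, "seed_calibration"))
  if (length(lengths) == 0L) {
    pk_warn("plant has no panicles; seed estimate is 0", "empty_plant")
    return(0)
  }
  if (any(lengths <= 0)) pk_stop("panicle lengths must be > 0", "domain")
  round(sum(pmax(0, calibration$slope * lengths + calibration$intercept)))
}

#' Mean seed production per plant
#'
#' @param plants Numeric vector of per-plant seed estimates (e.g. from
#'   [estimate_plant()]), or a data frame with column `seeds_per_plant`.
#' @return Arithmetic mean seeds per plant.
#' @export
mean_seed_production <- function(plants) {
  if (is.data.frame(plants)) {
    check_columns(plants, "seeds_per_plant", "plant fecundity data")
    plants <- plants$seeds_per_plant
  }
  if (length(plants) == 0L) pk_stop("no plants supplied", "domain")
  mean(plants)
}

#' Permutation test and bootstrap CI for the fecundity suppression ratio
#'
#' Quantifies crop suppression of seed production as the ratio of group
#' mean seeds per plant, `mean(plus) / mean(minus)`. Significance of the
#' group difference comes from a label-permutation test on the absolute
#' difference of means (add-one p estimator); the CI of the ratio is a
#' percentile bootstrap resampling plants independently within each group.
#'
#' Set the RNG seed before calling for reproducibility.
#'
#' @param minus Per-plant seed estimates for plants grown without the crop.
#' @param plus Per-plant seed estimates for plants grown with the crop.
#' @param n_perm Permutation iterations (default 1000).
#' @param n_boot Bootstrap resamples (default 10000).
#' @param coverage CI coverage (default 0.95).
#' @return A `ratio_estimate` with `ratio`, `lo`, `hi` (percentile
#'   bootstrap), `p_value` (permutation), `n_perm`, `n_boot`.
#' @export
fecundity_ratio_test <- function(minus, plus, n_perm = 1000, n_boot = 10000,
                                 coverage = 0.95) {
  if (is.data.frame(minus)) minus <- minus$seeds_per_plant
  if (is.data.frame(plus)) plus <- plus$seeds_per_plant
  if (length(minus) == 0L || length(plus) == 0L) {
    pk_stop("both groups must be nonempty", "domain")
  }
  m_minus <- mean(minus)
  if (m_minus == 0) pk_stop("mean of the -crop group is 0: ratio undefined",
                            "invalid_denominator")
  ratio <- mean(plus) / m_minus

  # Permutation test on |difference of means|.
  x <- c(minus, plus)
  nM <- length(minus)
  n <- length(x)
  s_obs <- abs(mean(minus) - mean(plus))
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample.int(n)
    s_star <- abs(mean(x[perm[seq_len(nM)]]) - mean(x[perm[-seq_len(nM)]]))
    if (s_star >= s_obs) exceed <- exceed + 1L
  }
  p <- (1 + exceed) / (1 + n_perm)

  # Percentile bootstrap of the ratio, resampling within groups.
  im <- matrix(sample.int(nM, nM * n_boot, replace = TRUE), nrow = nM)
  ip <- matrix(sample.int(length(plus), length(plus) * n_boot, replace = TRUE),
               nrow = length(plus))
  bm <- colMeans(matrix(minus[im], nrow = nM))
  bp <- colMeans(matrix(plus[ip], nrow = length(plus)))
  ok <- bm > 0
  ratios <- bp[ok] / bm[ok]
  alpha <- (1 - coverage) / 2
  qs <- unname(stats::quantile(ratios, c(alpha, 1 - alpha)))

  ratio_estimate(ratio = ratio, se = stats::sd(ratios),
                 lo = qs[1L], hi = qs[2L], p_value = p,
                 what = "seed production (+crop / -crop)",
                 extra = list(n_perm = n_perm, n_boot = n_boot,
                              mean_minus = m_minus, mean_plus = mean(plus)))
}
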