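# Target-neighbourhood competition: hyperbolic response of a target weed to
# neighbouring winter-wheat density, summarised by DENS50.

#' Hyperbolic crop-competition response curve
#'
#' Evaluates \deqn{Y(x) = a / (1 + x/DENS50),} the two-parameter rectangular
#' hyperbola describing how a target plant's response (dry matter or seed
#' production) declines with increasing neighbour density `x`. `a` is the
#' response of a plant growing alone (`x = 0`); `DENS50` is the neighbour
#' density that halves the response.
#'
#' @param x Neighbour (winter wheat) density (plants/m^2), `>= 0`.
#'   Vectorised.
#' @param a Response at zero density, `> 0`.
#' @param dens50 Density halving the response (plants/m^2), `> 0`.
#' @return Predicted response, in the units of `a`.
#' @export
hyperbolic_curve <- function(x, a, dens50) {
  if (any(!is.na(x) & x < 0)) pk_stop("density x must be >= 0", "domain")
  if (dens50 <= 0) pk_stop("dens50 must be > 0", "domain")
  a / (1 + x / dens50)
}

#' Construct a hyperbolic fit object
#'
#' Carrier for [fit_hyperbolic()] results, also usable directly with
#' published `(a, DENS50)` estimates and standard errors for post-hoc
#' comparisons via [compare_dens50()].
#'
#' @param a Response at zero density.
#' @param dens50 DENS50 (plants/m^2).
#' @param se_a,se_dens50 Optional standard errors.
#' @param vcov,rss,df,converged,n Optional fit diagnostics.
#' @return Object of class `hyperbolic_fit`.
#' @export
hyperbolic_fit <- function(a, dens50, se_a = NA_real_, se_dens50 = NA_real_,
                           vcov = NULL, rss = NA_real_, df = NA_real_,
                           converged = TRUE, n = NA_integer_) {
  if (a <= 0) pk_stop("a must be > 0", "domain")
  if (dens50 <= 0) pk_stop("dens50 must be > 0", "domain")
  structure(
    list(a = a, dens50 = dens50, se_a = se_a, se_dens50 = se_dens50,
         vcov = vcov, rss = rss, df = df, converged = converged, n = n),
    class = "hyperbolic_fit"
  )
}

#' @export
print.hyperbolic_fit <- function(x, ...) {
  cat(sprintf("Hyperbolic competition fit%s\n",
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  a = %.2f (%.2f), DENS50 = %.1f (%.1f) plants/m^2\n",
              x$a, x$se_a, x$dens50, x$se_dens50))
  invisible(x)
}

#' Fit the hyperbolic competition model
#'
#' Least-squares fit of [hyperbolic_curve()] to target-plant responses over
#' a gradient of neighbour densities (Levenberg--Marquardt). `DENS50` is
#' optimised on the log scale to enforce positivity; its standard error is
#' delta-transformed back. Starting values: `a` from the mean response at
#' the lowest density, `DENS50` from the density whose mean response is
#' nearest `a/2`.
#'
#' A flat response profile leaves `DENS50` unidentified; such fits are
#' returned with `converged = FALSE`.
#'
#' @param data Data frame with columns `density_m2` and `response`.
#' @return A `hyperbolic_fit` with estimates, standard errors and the
#'   `(a, log dens50)` covariance.
#' @examples
#' sim <- gen_competition(scenario_config(seed = 1))
#' cell <- sim[sim$species == sim$species[1] & sim$harvest == sim$harvest[1] &
#'             sim$crop_stage == sim$crop_stage[1], ]
#' fit_hyperbolic(cell)
#' @export
fit_hyperbolic <- function(data) {
  check_columns(data, c("density_m2", "response"), "pot data")
  x <- data$density_m2
  y <- data$response
  if (any(x < 0)) pk_stop("densities must be >= 0", "domain")
  if (any(y < 0)) pk_stop("responses must be >= 0", "domain")
  if (length(unique(x)) < 2L) {
    pk_stop("single density level: DENS50 unidentifiable", "unidentifiable")
  }
  if (length(y) < 4L) pk_stop("need at least 4 observations", "insufficient_data")

  means <- tapply(y, x, mean)
  xs <- as.numeric(names(means))
  a0 <- max(means[which.min(xs)], 1e-6)
  pos <- xs > 0
  d0 <- if (any(pos)) xs[pos][which.min(abs(means[pos] - a0 / 2))] else stats::median(xs)
  if (d0 <= 0) d0 <- stats::median(xs[xs > 0])

  env <- list2env(list(x = x, y = y))
  fit <- try(minpack.lm::nlsLM(
    y ~ a / (1 + x / exp(ld)),
    start = list(a = a0, ld = log(d0)),
    data = env,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    pk_stop(sprintf("hyperbolic fit failed to converge: %s",
                    attr(fit, "condition")$message),
            "nonconvergence")
  }

  est <- stats::coef(fit)
  vc <- try(stats::vcov(fit), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- matrix(NA_real_, 2, 2)
  dimnames(vc) <- list(c("a", "log_dens50"), c("a", "log_dens50"))
  dens50 <- exp(est[["ld"]])
  se_ld <- sqrt(max(vc[2L, 2L], 0))

  # Flat response: dens50 runs away and/or its log-scale SE explodes.
  converged <- is.finite(dens50) && dens50 < 100 * max(x[x > 0]) &&
    is.finite(se_ld) && se_ld < 10

  hyperbolic_fit(
    a = est[["a"]], dens50 = dens50,
    se_a = sqrt(max(vc[1L, 1L], 0)),
    se_dens50 = dens50 * se_ld,
    vcov = vc,
    rss = sum(stats::residuals(fit)^2),
    df = length(y) - 2L,
    converged = converged, n = length(y)
  )
}

#' Wald comparison of DENS50 between two hyperbolic fits
#'
#' Post-hoc two-sided Wald t-test of the DENS50 difference between two
#' fitted competition curves (species, crop growth stages or harvests),
#' using the normal reference distribution.
#'
#' @param fitA,fitB Converged `hyperbolic_fit` objects with standard errors.
#' @return A `wald_test` (see [compare_fit_parameter()]).
#' @export
compare_dens50 <- function(fitA, fitB) {
  for (f in list(fitA, fitB)) {
    if (!inherits(f, "hyperbolic_fit") || !isTRUE(f$converged)) {
      pk_stop("both inputs must be converged hyperbolic fits", "nonconvergence")
    }
    if (is.na(f$se_dens50)) {
      pk_stop("fits must carry DENS50 standard errors", "nonconvergence")
    }
  }
  wald_test(fitA$dens50, fitB$dens50, fitA$se_dens50, fitB$se_dens50,
            label = "DENS50")
}
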