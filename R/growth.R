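#' Weibull biomass-accumulation curve
#'
#' Evaluates the three-parameter Weibull (Gompertz-type) growth curve in its
#' increasing orientation,
#' \deqn{Y(t) = d \exp\{-\exp[-|c|(\log t - \log e)]\},}
#' rising from 0 towards the upper limit `d` (total plant biomass). Published
#' tables report the rate as a positive magnitude while the curve increases;
#' the absolute value of `c` is therefore used inside the exponent and
#' reported, so either sign may be supplied.
#'
#' At `t = e` the curve passes through `d/e ~= 0.368 d`; the thermal time to
#' half the final biomass is recovered by [time50()].
#'
#' @param t Thermal time (degree C day), `> 0`. Vectorised.
#' @param c Rate of biomass production (magnitude used).
#' @param d Upper biomass limit (g per plant), `> 0`.
#' @param e Scale parameter (degree C day), `> 0`.
#' @return Biomass (g per plant) in `[0, d)`.
#' @export
weibull_curve <- function(t, c, d, e) {
  if (any(!is.na(t) & t <= 0)) pk_stop("thermal time t must be > 0", "domain")
  if (e <= 0) pk_stop("scale e must be > 0", "domain")
  d * exp(-exp(-abs(c) * (log(t) - log(e))))
}

#' Log-logistic biomass-accumulation curve
#'
#' Evaluates \deqn{Y(t) = d / (1 + \exp[c(\log t - \log TIME50)]),} the
#' three-parameter log-logistic growth curve. With the sign convention of
#' published tables (`c < 0`) the curve increases with thermal time and
#' reaches `d/2` exactly at `t = t50` (TIME50).
#'
#' @param t Thermal time (degree C day), `> 0`. Vectorised.
#' @param c Rate parameter; negative for an increasing curve.
#' @param d Upper biomass limit (g per plant), `> 0`.
#' @param t50 Thermal time to half the final biomass (degree C day), `> 0`.
#' @return Biomass (g per plant) in `(0, d)`.
#' @export
loglogistic_curve <- function(t, c, d, t50) {
  if (any(!is.na(t) & t <= 0)) pk_stop("thermal time t must be > 0", "domain")
  if (t50 <= 0) pk_stop("t50 must be > 0", "domain")
  d / (1 + exp(c * (log(t) - log(t50))))
}

#' Construct a growth fit object
#'
#' Creates a `growth_fit` from parameter values, either as the return
#' carrier of [fit_growth()] or directly from published estimates (e.g. to
#' compute suppression ratios from reported `d` values and their standard
#' errors).
#'
#' @param family `"weibull"` or `"loglogistic"`.
#' @param c Rate parameter (Weibull: magnitude; log-logistic: negative for
#'   increasing curves).
#' @param d Upper biomass limit (g per plant).
#' @param timing Timing parameter (degree C day): scale `e` for the Weibull
#'   family, `TIME50` for the log-logistic.
#' @param se Optional named numeric vector of standard errors with any of
#'   names `c`, `d`, `timing`.
#' @param vcov,rss,df,converged,n Optional diagnostics from a fit.
#' @return Object of class `growth_fit`.
#' @export
growth_fit <- function(family = c("weibull", "loglogistic"), c, d, timing,
                       se = NULL, vcov = NULL, rss = NA_real_, df = NA_real_,
                       converged = TRUE, n = NA_integer_) {
  family <- match.arg(family)
  if (d <= 0) pk_stop("upper limit d must be > 0", "domain")
  if (timing <= 0) pk_stop("timing parameter must be > 0", "domain")
  se_full <- c(c = NA_real_, d = NA_real_, timing = NA_real_)
  if (!is.null(se)) se_full[names(se)] <- se
  structure(
    list(family = family, c = c, d = d, timing = timing, se = se_full,
         vcov = vcov, rss = rss, df = df, converged = converged, n = n),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  lab <- if (x$family == "weibull") "e" else "TIME50"
  cat(sprintf("%s growth fit%s\n",
              if (x$family == "weibull") "Weibull" else "Log-logistic",
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  c = %.3f (%.3f), d = %.3f (%.3f) g, %s = %.1f (%.1f) C d\n",
              x$c, x$se["c"], x$d, x$se["d"], lab, x$timing, x$se["timing"]))
  cat(sprintf("  TIME50 = %.1f C d", time50(x)))
  if (!is.na(x$rss)) cat(sprintf(", RSS = %.4g on %g df", x$rss, x$df))
  cat("\n")
  invisible(x)
}

growth_mean_fun <- function(family) {
  if (family == "weibull") {
    function(t, c, d, timing) weibull_curve(t, c, d, timing)
  } else {
    function(t, c, d, timing) loglogistic_curve(t, c, d, timing)
  }
}

#' Fit a biomass-accumulation curve by nonlinear least squares
#'
#' Fits [weibull_curve()] or [loglogistic_curve()] to per-plant dry-matter
#' samples against thermal time by homoscedastic least squares on the
#' original response scale (Levenberg--Marquardt via
#' [minpack.lm::nls.lm()], best of a small grid of starting values).
#' Starting values: `d` from the maximum observed biomass, the timing
#' parameter from the sampling time whose mean response is closest to half
#' of that, rate magnitudes 2--25.
#'
#' @param data Data frame with columns `cum_tt_c` (thermal time, degree C
#'   day) and `dm_per_plant_g` (dry matter per plant, g).
#' @param family `"weibull"` (suited to seasons with asymmetric growth) or
#'   `"loglogistic"`.
#' @param log_response Fit on `log(y + 1)` scale instead of the original
#'   scale. Default `FALSE`.
#' @return A `growth_fit` with estimates, asymptotic standard errors,
#'   covariance, residual sum of squares and residual degrees of freedom.
#' @examples
#' sim <- gen_biomass(scenario_config(seed = 1))
#' sub <- sim[sim$species == sim$species[1] & sim$crop == 0, ]
#' fit_growth(sub, family = "weibull")
#' @export
fit_growth <- function(data, family = c("weibull", "loglogistic"),
                       log_response = FALSE) {
  family <- match.arg(family)
  check_columns(data, c("cum_tt_c", "dm_per_plant_g"), "biomass data")
  t <- data$cum_tt_c
  y <- data$dm_per_plant_g
  if (any(t <= 0)) pk_stop("thermal times must be > 0", "domain")
  if (any(y < 0)) pk_stop("biomass must be >= 0", "domain")

  n_times <- length(unique(t))
  if (n_times < 4L || all(y == 0)) {
    pk_stop("insufficient data: need >= 4 distinct sampling times and nonzero biomass",
            "insufficient_data")
  }

  means <- tapply(y, t, mean)
  tt <- as.numeric(names(means))
  d0 <- max(max(y), 1e-6) * 1.05
  timing0 <- tt[which.min(abs(means - d0 / 2))]
  csign <- if (family == "weibull") 1 else -1

  yfit <- if (log_response) log(y + 1) else y
  fn <- growth_mean_fun(family)
  pred <- function(p) {
    mu <- fn(t, p[1L], p[2L], exp(p[3L]))
    if (log_response) log(mu + 1) else mu
  }
  resid_fun <- function(p) yfit - pred(p)

  # Small start grid over the rate magnitude and timing: steep (step-like)
  # profiles make single-start Levenberg-Marquardt fragile.
  fit <- NULL
  for (c0 in csign * c(5, 2, 10, 25)) {
    for (t0 in unique(c(timing0, stats::median(tt)))) {
      cand <- try(suppressWarnings(minpack.lm::nls.lm(
        par = c(c0, d0, log(t0)), fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12)
      )), silent = TRUE)
      # info 1-4: converged; 5: iteration cap hit, which for step-like data
      # means a runaway-steep rate whose deviance has plateaued -- usable.
      if (inherits(cand, "try-error") || !(cand$info %in% 1:5) ||
          !is.finite(cand$deviance)) next
      if (is.null(fit) || cand$deviance < fit$deviance - 1e-10) fit <- cand
    }
  }
  if (is.null(fit)) {
    pk_stop("growth fit failed to converge from any starting value",
            "nonconvergence")
  }

  est <- fit$par
  names(est) <- c("cc", "dd", "ltiming")
  rss <- fit$deviance
  dfres <- length(y) - 3L
  # Asymptotic covariance from the Gauss-Newton approximation at the
  # optimum; a singular information matrix (e.g. near-step rate estimates)
  # yields NA standard errors rather than a failed fit.
  vc <- try(rss / dfres * solve(fit$hessian), silent = TRUE)
  if (inherits(vc, "try-error") || any(!is.finite(vc)) || any(diag(vc) < 0)) {
    vc <- matrix(NA_real_, 3, 3)
  }
  # Delta transform ltiming -> timing.
  timing <- exp(est[["ltiming"]])
  J <- diag(c(1, 1, timing))
  vc_nat <- J %*% vc %*% t(J)
  dimnames(vc_nat) <- list(c("c", "d", "timing"), c("c", "d", "timing"))
  ses <- unname(sqrt(pmax(diag(vc_nat), 0)))

  c_est <- est[["cc"]]
  if (family == "weibull") c_est <- abs(c_est)  # report magnitude, table style

  growth_fit(
    family = family, c = c_est, d = est[["dd"]], timing = timing,
    se = c(c = ses[1L], d = ses[2L], timing = ses[3L]),
    vcov = vc_nat,
    rss = rss,
    df = dfres,
    converged = TRUE, n = length(y)
  )
}

#' Thermal time to half the final biomass
#'
#' For a log-logistic fit TIME50 is the timing parameter itself; for a
#' Weibull fit it is obtained by solving the curve for `d/2` analytically,
#' \deqn{TIME50 = e\,(\log 2)^{-1/|c|}.}
#'
#' @param fit A converged `growth_fit`.
#' @return TIME50 (degree C day).
#' @export
time50 <- function(fit) {
  stopifnot(inherits(fit, "growth_fit"))
  if (!isTRUE(fit$converged)) pk_stop("fit did not converge", "nonconvergence")
  if (fit$family == "loglogistic") {
    fit$timing
  } else {
    fit$timing * log(2)^(-1 / abs(fit$c))
  }
}

#' Lack-of-fit F-test for a growth curve
#'
#' Compares the fitted three-parameter curve against the saturated
#' one-mean-per-sampling-time model. The pure-error sum of squares comes from
#' replicate measurements at shared sampling times; `p > 0.05` indicates the
#' parametric curve describes the data adequately.
#'
#' @param fit A `growth_fit` from [fit_growth()] (original-scale fit).
#' @param data The data frame the fit was computed from.
#' @return List with `F`, `p_value`, `df_lof`, `df_pe`.
#' @export
lack_of_fit <- function(fit, data) {
  stopifnot(inherits(fit, "growth_fit"))
  check_columns(data, c("cum_tt_c", "dm_per_plant_g"), "biomass data")
  t <- data$cum_tt_c
  y <- data$dm_per_plant_g
  groups <- split(y, t)
  reps <- vapply(groups, length, integer(1))
  if (all(reps < 2L)) {
    pk_stop("lack-of-fit test unavailable: no replicated sampling times",
            "test_unavailable")
  }
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- length(y) - length(groups)
  df_lof <- length(groups) - 3L
  if (df_lof <= 0L || df_pe <= 0L) {
    pk_stop("lack-of-fit test unavailable: not enough distinct times or replication",
            "test_unavailable")
  }
  ss_lof <- max(fit$rss - ss_pe, 0)
  Fstat <- (ss_lof / df_lof) / (ss_pe / df_pe)
  list(F = Fstat, p_value = stats::pf(Fstat, df_lof, df_pe, lower.tail = FALSE),
       df_lof = df_lof, df_pe = df_pe)
}

#' Crop-suppression ratio of total biomass
#'
#' Ratio of the fitted upper biomass limits `d` with and without crop
#' competition, `ratio = d_plus / d_minus`. A lower ratio means the species'
#' biomass production is more sensitive to the crop. The standard error is
#' the first-order delta-method combination of the two independent `d`
#' standard errors, and the two-sided Wald test is against a ratio of 1.
#'
#' @param fit_minus Fit for plants grown without the crop (denominator).
#' @param fit_plus Fit for plants grown with the crop (numerator).
#' @return Object of class `ratio_estimate` with `ratio`, `se`, `lo`, `hi`
#'   (normal-theory 95% CI) and `p_value`.
#' @examples
#' minus <- growth_fit("weibull", c = 6.0, d = 14.9, timing = 1251,
#'                     se = c(d = 1.2))
#' plus <- growth_fit("weibull", c = 4.5, d = 6.2, timing = 1235,
#'                    se = c(d = 2.2))
#' suppression_ratio(minus, plus)
#' @export
suppression_ratio <- function(fit_minus, fit_plus) {
  stopifnot(inherits(fit_minus, "growth_fit"), inherits(fit_plus, "growth_fit"))
  if (fit_minus$d <= 0) pk_stop("denominator d must be > 0", "invalid_denominator")
  ratio <- fit_plus$d / fit_minus$d
  se <- ratio * sqrt((fit_plus$se["d"] / fit_plus$d)^2 +
                     (fit_minus$se["d"] / fit_minus$d)^2)
  se <- unname(se)
  z <- if (is.na(se) || se == 0) {
    if (ratio == 1) 0 else Inf
  } else {
    (ratio - 1) / se
  }
  ratio_estimate(ratio = ratio, se = se,
                 lo = ratio - stats::qnorm(0.975) * se,
                 hi = ratio + stats::qnorm(0.975) * se,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 what = "total biomass d (+crop / -crop)")
}

# Shared carrier for suppression ratios (biomass d, seed production).
ratio_estimate <- function(ratio, se = NA_real_, lo = NA_real_, hi = NA_real_,
                           p_value = NA_real_, what = "ratio", extra = list()) {
  if (!is.na(ratio) && ratio < 0) pk_stop("ratio must be >= 0", "domain")
  structure(c(list(ratio = ratio, se = se, lo = lo, hi = hi,
                   p_value = p_value, what = what), extra),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("Suppression ratio [%s]: %.3f", x$what, x$ratio))
  if (!is.na(x$lo)) cat(sprintf(" (95%% CI %.3f-%.3f)", x$lo, x$hi))
  if (!is.na(x$se)) cat(sprintf(", SE %.3f", x$se))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}
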