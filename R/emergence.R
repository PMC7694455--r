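#' Log-logistic cumulative emergence curve
#'
#' Evaluates the two-parameter log-logistic cumulative distribution
#' \deqn{E(t) = 1 / (1 + \exp[b(\log t - \log GERM50)])}
#' where `g50` (GERM50) is the thermal time at which half of the final
#' emergence is reached and `b` is the emergence-rate parameter. With the
#' sign convention used in published tables, `b < 0` gives a curve that
#' increases with thermal time.
#'
#' @param t Thermal time (degree C day), `> 0`. Vectorised.
#' @param b Slope (emergence rate); negative for an increasing curve.
#' @param g50 Thermal time to 50% emergence (degree C day), `> 0`.
#' @return Proportion emerged in `(0, 1)`.
#' @export
emergence_cdf <- function(t, b, g50) {
  if (any(!is.na(t) & t <= 0)) pk_stop("thermal time t must be > 0", "domain")
  if (g50 <= 0) pk_stop("g50 must be > 0", "domain")
  1 / (1 + exp(b * (log(t) - log(g50))))
}

#' Construct an emergence fit object from known parameters
#'
#' Builds an `emergence_fit` either from [fit_emergence()] internals or
#' directly from published parameter estimates so that quantile and
#' comparison machinery can be applied to reported fits. The covariance is
#' on the `(b, log g50)` scale.
#'
#' @param b Slope parameter (negative for increasing curves).
#' @param g50 GERM50 (degree C day), `> 0`.
#' @param vcov Optional 2x2 covariance matrix of `(b, log g50)`.
#' @param logLik,converged,n_units Optional fit diagnostics.
#' @return An object of class `emergence_fit`.
#' @export
emergence_fit <- function(b, g50, vcov = NULL, logLik = NA_real_,
                          converged = TRUE, n_units = NA_integer_) {
  if (g50 <= 0) pk_stop("g50 must be > 0", "domain")
  if (!is.null(vcov)) {
    vcov <- as.matrix(vcov)
    stopifnot(identical(dim(vcov), c(2L, 2L)))
    if (max(abs(vcov - t(vcov))) > 1e-8 * max(1, max(abs(vcov)))) {
      pk_stop("covariance must be symmetric", "domain")
    }
  }
  structure(
    list(b = b, g50 = g50, vcov = vcov, logLik = logLik,
         converged = converged, n_units = n_units),
    class = "emergence_fit"
  )
}

#' @export
print.emergence_fit <- function(x, ...) {
  cat("Log-logistic emergence fit (grouped time-to-event ML)\n")
  cat(sprintf("  b = %.3f, GERM50 = %.1f C d%s\n", x$b, x$g50,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$vcov)) {
    cat(sprintf("  SE(b) = %.3f, SE(log g50) = %.4f\n",
                sqrt(x$vcov[1, 1]), sqrt(x$vcov[2, 2])))
  }
  if (!is.na(x$logLik)) cat(sprintf("  logLik = %.3f\n", x$logLik))
  invisible(x)
}

# Grouped event-time negative log-likelihood on (b, log g50).
# Each unit contributes multinomial interval counts d_j with probabilities
# E(t_j) - E(t_{j-1}) (E(0) = 0) and, when n_sown is known, a right-censored
# term (n_sown - n_final) * log(1 - E(t_k)).
emergence_negll <- function(par, units) {
  b <- par[1L]
  g50 <- exp(par[2L])
  total <- 0
  for (u in units) {
    E <- emergence_cdf(u$t, b, g50)
    p <- diff(c(0, E))
    if (any(p <= 0)) return(1e10)
    total <- total - sum(u$d * log(p))
    if (u$censored > 0) {
      surv <- 1 - E[length(E)]
      if (surv <= 0) return(1e10)
      total <- total - u$censored * log(surv)
    }
  }
  total
}

# Split an emergence data frame into per-unit interval-count structures.
emergence_units <- function(data, use_n_sown) {
  split_ids <- split(seq_len(nrow(data)), data$unit_id)
  lapply(split_ids, function(ix) {
    d <- data[ix, , drop = FALSE]
    d <- d[order(d$cum_tt_c), , drop = FALSE]
    if (any(diff(d$cum_tt_c) <= 0)) {
      pk_stop("inspection thermal times must be strictly increasing within a unit",
              "invalid_record")
    }
    if (any(diff(d$cum_count) < 0)) {
      pk_stop("cumulative counts must be nondecreasing within a unit",
              "invalid_record")
    }
    n_final <- d$cum_count[nrow(d)]
    censored <- 0
    if (use_n_sown) {
      ns <- unique(d$n_sown)
      if (length(ns) != 1L || is.na(ns)) {
        pk_stop("n_sown must be a single known value per unit", "invalid_record")
      }
      if (ns < n_final) pk_stop("n_sown below final emerged count", "invalid_record")
      censored <- ns - n_final
    }
    list(t = d$cum_tt_c, d = diff(c(0, d$cum_count)), censored = censored,
         n_final = n_final)
  })
}

#' Fit the log-logistic emergence model to grouped inspection counts
#'
#' Maximum-likelihood fit of [emergence_cdf()] to cumulative seedling counts
#' observed at a schedule of inspection thermal times (the time-to-event
#' approach for grouped emergence data). Counts between consecutive
#' inspections are treated as multinomial interval counts; seeds never seen
#' to emerge contribute a right-censored term only when the number sown is
#' supplied (`use_n_sown = TRUE`). The default conditions on the final
#' observed count as the emerging population, which reproduces curves
#' normalised to 0--100% cumulative emergence.
#'
#' Optimisation is on `(b, log g50)` with starting values from a
#' logit-linear regression of pooled empirical cumulative proportions on
#' `log(t)`, BFGS first and a Nelder--Mead fallback; the covariance is the
#' inverse observed information at the optimum.
#'
#' @param data Data frame with columns `unit_id`, `cum_tt_c`, `cum_count`
#'   and, when `use_n_sown = TRUE`, `n_sown`. Units (quadrats) are pooled
#'   into a single fit; subset beforehand to control grouping.
#' @param use_n_sown Include the right-censored never-emerged mass using the
#'   `n_sown` column. Default `FALSE`.
#' @return An `emergence_fit` with elements `b`, `g50`, `vcov` (on
#'   `(b, log g50)`), `logLik`, `converged`, `n_units`.
#' @examples
#' sim <- gen_emergence(scenario_config(seed = 1))
#' fit <- fit_emergence(sim[sim$species == sim$species[1], ])
#' emergence_quantile(fit, 0.5)
#' @export
fit_emergence <- function(data, use_n_sown = FALSE) {
  check_columns(data, c("unit_id", "cum_tt_c", "cum_count"), "emergence data")
  if (use_n_sown) check_columns(data, "n_sown", "emergence data")
  if (any(data$cum_tt_c <= 0)) pk_stop("thermal times must be > 0", "domain")

  units <- emergence_units(data, use_n_sown)

  # Identifiability: need at least two informative intervals overall, i.e.
  # emergence spread over more than one inspection interval somewhere.
  informative <- sum(vapply(units, function(u) sum(u$d > 0), integer(1)))
  interior <- any(vapply(units, function(u) {
    denom <- u$n_final + u$censored
    denom > 0 && any(cumsum(u$d) > 0 & cumsum(u$d) < denom)
  }, logical(1)))
  if (informative < 2L || !interior) {
    pk_stop("degenerate grouping: emergence data contain fewer than two informative intervals",
            "unidentifiable")
  }

  # Starting values from pooled empirical proportions:
  # logit(E) = -b log t + b log g50.
  tt <- sort(unique(data$cum_tt_c))
  tot <- sum(vapply(units, function(u) u$n_final + u$censored, numeric(1)))
  cum <- vapply(tt, function(x) {
    sum(vapply(units, function(u) {
      k <- findInterval(x, u$t)
      if (k == 0L) 0 else cumsum(u$d)[k]
    }, numeric(1)))
  }, numeric(1))
  F_emp <- cum / tot
  keep <- F_emp > 0 & F_emp < 1
  if (sum(keep) >= 2L) {
    co <- stats::coef(stats::lm(stats::qlogis(F_emp[keep]) ~ log(tt[keep])))
    b0 <- -co[[2L]]
    lg0 <- if (abs(co[[2L]]) > 1e-12) -co[[1L]] / co[[2L]] else log(stats::median(tt))
  } else {
    b0 <- -5
    lg0 <- log(stats::weighted.mean(tt, vapply(seq_along(tt), function(i) {
      sum(vapply(units, function(u) u$d[match(tt[i], u$t)] %||% 0,
                 numeric(1)), na.rm = TRUE)
    }, numeric(1)) + 1e-9))
  }
  if (!is.finite(b0) || b0 >= 0) b0 <- -5
  if (!is.finite(lg0)) lg0 <- log(stats::median(tt))

  opt <- try(stats::optim(c(b0, lg0), emergence_negll, units = units,
                          method = "BFGS",
                          control = list(reltol = 1e-10, maxit = 500)),
             silent = TRUE)
  if (inherits(opt, "try-error") || opt$convergence != 0) {
    opt <- stats::optim(c(b0, lg0), emergence_negll, units = units,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-10, maxit = 2000))
  }
  if (opt$convergence != 0) {
    pk_stop(sprintf("emergence fit did not converge (optim code %d, message: %s)",
                    opt$convergence, opt$message %||% "none"),
            "nonconvergence")
  }

  par <- opt$par
  if (par[1L] > 0) {
    pk_warn("fitted slope b is positive (decreasing curve); data imply the opposite sign convention",
            "sign_flip")
  }
  H <- stats::optimHess(par, emergence_negll, units = units)
  vc <- try(solve(H), silent = TRUE)
  if (inherits(vc, "try-error")) vc <- matrix(NA_real_, 2, 2)
  vc <- (vc + t(vc)) / 2
  dimnames(vc) <- list(c("b", "log_g50"), c("b", "log_g50"))

  emergence_fit(b = par[1L], g50 = exp(par[2L]), vcov = vc,
                logLik = -opt$value, converged = TRUE,
                n_units = length(units))
}

#' Emergence quantile (GERM10/50/90) with delta-method confidence interval
#'
#' Inverts the log-logistic emergence curve: the thermal time at which a
#' proportion `p` of final emergence is reached is
#' \deqn{t_p = GERM50 \cdot ((1-p)/p)^{1/b}.}
#' The confidence interval is computed by the delta method on `log t_p`
#' using the `(b, log g50)` covariance and back-transformed, which keeps the
#' interval positive.
#'
#' @param fit An `emergence_fit`.
#' @param p Proportion in `(0, 1)`; e.g. 0.1, 0.5, 0.9 for GERM10/50/90.
#' @param level Confidence level, default 0.95.
#' @return A list of class `quantile_estimate` with `p`, `estimate`, `se`,
#'   `lo`, `hi` (degree C day; `se`/`lo`/`hi` are `NA` without a covariance).
#' @export
emergence_quantile <- function(fit, p, level = 0.95) {
  stopifnot(inherits(fit, "emergence_fit"), length(p) == 1L)
  if (p <= 0 || p >= 1) pk_stop("p must lie strictly in (0, 1)", "domain")
  if (!isTRUE(fit$converged)) pk_stop("fit did not converge", "nonconvergence")
  if (fit$b == 0) pk_stop("slope b = 0: quantiles undefined", "degenerate_slope")

  logr <- log((1 - p) / p)
  logt <- log(fit$g50) + logr / fit$b
  est <- exp(logt)

  se <- lo <- hi <- NA_real_
  if (!is.null(fit$vcov) && all(is.finite(fit$vcov))) {
    grad <- c(-logr / fit$b^2, 1)          # d logt / d(b, log g50)
    v <- drop(t(grad) %*% fit$vcov %*% grad)
    if (v >= 0) {
      se <- sqrt(v)
      z <- stats::qnorm(1 - (1 - level) / 2)
      lo <- exp(logt - z * se)
      hi <- exp(logt + z * se)
    }
  }
  structure(list(p = p, estimate = est, se_log = se, lo = lo, hi = hi,
                 level = level),
            class = "quantile_estimate")
}

#' @export
print.quantile_estimate <- function(x, ...) {
  cat(sprintf("GERM%g = %.1f C d", 100 * x$p, x$estimate))
  if (!is.na(x$lo)) cat(sprintf("  (%g%% CI %.1f-%.1f)", 100 * x$level, x$lo, x$hi))
  cat("\n")
  invisible(x)
}

#' Wald comparison of a parameter between two emergence fits
#'
#' Two-sided Wald t-test of the difference in `b`, `GERM50`, or an emergence
#' quantile between two fits, using the normal reference distribution:
#' statistic \eqn{(\theta_A - \theta_B)/\sqrt{se_A^2 + se_B^2}}. Standard
#' errors on the original parameter scale come from the delta method on the
#' `(b, log g50)` covariance.
#'
#' @param fitA,fitB Converged `emergence_fit` objects with covariances.
#' @param which One of `"b"`, `"g50"`, `"quantile"`.
#' @param p Quantile proportion, required when `which = "quantile"`.
#' @return List of class `wald_test`: `estimateA`, `estimateB`, `difference`,
#'   `se`, `statistic`, `p_value`.
#' @export
compare_fit_parameter <- function(fitA, fitB, which = c("b", "g50", "quantile"),
                                  p = NULL) {
  which <- match.arg(which)
  for (f in list(fitA, fitB)) {
    if (!inherits(f, "emergence_fit") || !isTRUE(f$converged)) {
      pk_stop("both inputs must be converged emergence fits", "nonconvergence")
    }
    if (is.null(f$vcov) || !all(is.finite(f$vcov))) {
      pk_stop("fits must carry a finite covariance", "nonconvergence")
    }
  }
  extract <- function(fit) {
    switch(which,
      b = c(fit$b, sqrt(fit$vcov[1, 1])),
      g50 = c(fit$g50, fit$g50 * sqrt(fit$vcov[2, 2])),
      quantile = {
        if (is.null(p)) pk_stop("p required for which = 'quantile'", "domain")
        q <- emergence_quantile(fit, p)
        c(q$estimate, q$estimate * q$se_log)
      }
    )
  }
  a <- extract(fitA)
  b <- extract(fitB)
  wald_test(a[1L], b[1L], a[2L], b[2L],
            label = if (which == "quantile") sprintf("GERM%g", 100 * p) else which)
}

# Shared Wald machinery (also used by the competition module).
wald_test <- function(estA, estB, seA, seB, label = "parameter") {
  se <- sqrt(seA^2 + seB^2)
  stat <- if (se == 0) {
    if (estA == estB) 0 else Inf * sign(estA - estB)
  } else {
    (estA - estB) / se
  }
  structure(
    list(label = label, estimateA = estA, estimateB = estB,
         difference = estA - estB, se = se, statistic = stat,
         p_value = 2 * stats::pnorm(-abs(stat))),
    class = "wald_test"
  )
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Wald comparison of %s: %.4g vs %.4g (diff %.4g, SE %.4g)\n",
              x$label, x$estimateA, x$estimateB, x$difference, x$se))
  cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}
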