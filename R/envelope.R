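#' Condition-specific rate set
#'
#' Specific rates of one metabolic state (aerobic or microaerobic stage of a
#' two-stage fermentation): growth rate `mu` (1/h) and mass-specific glucose
#' (`gamma`, <= 0), acetoin (`alpha`) and 2,3-butanediol (`beta`, >= 0)
#' exchange rates (g/gDW/h), with `delta = alpha + beta` the total diol
#' secretion rate.
#'
#' @param condition `"aerobic"` or `"microaerobic"`.
#' @param mu,gamma,alpha,beta rates as above.
#' @param se optional named numeric of standard errors (`mu`, `gamma`,
#'   `alpha`, `beta`).
#' @return an object of class `condition_rates`.
#' @export
condition_rates <- function(condition = c("aerobic", "microaerobic"),
                            mu, gamma, alpha, beta, se = NULL) {
  condition <- match.arg(condition)
  if (mu < 0) stop_domain("growth rate mu must be >= 0")
  if (gamma > 1e-12) stop_domain("glucose rate gamma must be <= 0 (uptake)")
  if (beta < -1e-12) stop_domain("butanediol rate beta must be >= 0")
  structure(list(condition = condition, mu = mu, gamma = gamma,
                 alpha = alpha, beta = beta, delta = alpha + beta,
                 se = se),
            class = "condition_rates")
}

#' @export
print.condition_rates <- function(x, ...) {
  cat(sprintf("<condition_rates> %s: mu=%.4g 1/h, gamma=%.4g, alpha=%.4g, beta=%.4g, delta=%.4g g/gDW/h\n",
              x$condition, x$mu, x$gamma, x$alpha, x$beta, x$delta))
  invisible(x)
}

#' Fit condition-specific rates from a fed-batch time series
#'
#' The growth rate is the least-squares slope of `ln X` versus time. Each
#' mass-specific rate `q` is the least-squares slope of the (consumption-
#' corrected) species concentration versus the cumulative biomass integral
#' `I(t) = integral of X dt`. By default `I(t)` is evaluated analytically
#' from the fitted exponential biomass curve, `(Xhat(t) - Xhat(t0))/mu`,
#' which makes the fit an exact inverse of piecewise-exponential kinetics;
#' `integral = "trapezoid"` selects the model-free trapezoidal rule instead.
#'
#' Glucose feed pulses are handled by reconstructing cumulative consumption:
#' any concentration increase between consecutive samples is attributed to a
#' feed addition, so only decrements count as consumption. Within a
#' microaerobic window the acetoin rate is fitted only over the sub-window
#' where acetoin is present (declining towards depletion); if fewer than
#' `min_points` such samples exist, `alpha` is set to 0 and the butanediol
#' slope is fitted over the full window.
#'
#' @param series data frame with columns `time_h`, `biomass_gDW_L`,
#'   `glucose_g_L`, `acetoin_g_L`, `btd_g_L`, `condition` (the schema
#'   produced by [generate_timeseries()]).
#' @param condition which condition label to fit (`"aerobic"` or
#'   `"microaerobic"`).
#' @param window optional numeric length-2 time window (h) further
#'   restricting the rows used.
#' @param integral `"exponential"` (default) or `"trapezoid"`.
#' @param min_points minimum number of samples required (default 3).
#' @return a [condition_rates()] with standard errors.
#' @export
fit_condition_rates <- function(series, condition = c("aerobic", "microaerobic"),
                                window = NULL,
                                integral = c("exponential", "trapezoid"),
                                min_points = 3L) {
  condition <- match.arg(condition)
  integral <- match.arg(integral)
  need <- c("time_h", "biomass_gDW_L", "glucose_g_L", "acetoin_g_L",
            "btd_g_L", "condition")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop_data(sprintf("series is missing column(s): %s",
                                      paste(miss, collapse = ", ")))
  d <- series[series$condition == condition, , drop = FALSE]
  if (!is.null(window)) {
    d <- d[d$time_h >= window[1] & d$time_h <= window[2], , drop = FALSE]
  }
  d <- d[order(d$time_h), , drop = FALSE]
  if (nrow(d) < min_points) {
    stop_insufficient_data(sprintf(
      "need at least %d samples in the '%s' window, got %d",
      min_points, condition, nrow(d)))
  }
  if (any(d$biomass_gDW_L <= 0)) stop_data("biomass must be strictly positive")

  t <- d$time_h; X <- d$biomass_gDW_L
  fit_mu <- lm(log(X) ~ t)
  mu <- unname(coef(fit_mu)[2])
  se_mu <- suppressWarnings(summary(fit_mu))$coefficients[2, 2]

  Ix <- if (integral == "exponential") {
    Xhat <- exp(predict(fit_mu))
    if (abs(mu) > 1e-10) (Xhat - Xhat[1]) / mu else cumtrapz_vec(t, Xhat)
  } else {
    cumtrapz_vec(t, X)
  }

  slope <- function(y) {
    f <- lm(y ~ Ix)
    c(est = unname(coef(f)[2]), se = suppressWarnings(summary(f))$coefficients[2, 2])
  }

  ## glucose: feed-pulse aware cumulative consumption (decrements only)
  dG <- diff(d$glucose_g_L)
  cons <- c(0, cumsum(pmax(-dG, 0)))
  g_fit <- slope(-cons)

  ## acetoin / butanediol, with depletion sub-window in microaerobic stage
  A <- d$acetoin_g_L; B <- d$btd_g_L
  if (condition == "microaerobic" && any(A <= 1e-9)) {
    pre <- which(A > 1e-9)
    pre <- pre[pre < which(A <= 1e-9)[1] + 1L]  # keep only pre-depletion run
    if (length(pre) >= min_points) {
      fA <- lm(A[pre] ~ Ix[pre]); fB <- lm(B[pre] ~ Ix[pre])
      a_fit <- c(est = unname(coef(fA)[2]), se = suppressWarnings(summary(fA))$coefficients[2, 2])
      b_fit <- c(est = unname(coef(fB)[2]), se = suppressWarnings(summary(fB))$coefficients[2, 2])
    } else {
      a_fit <- c(est = 0, se = NA_real_)
      b_fit <- slope(B)
    }
  } else {
    a_fit <- slope(A)
    b_fit <- slope(B)
  }

  condition_rates(condition,
                  mu = max(mu, 0),
                  gamma = min(g_fit[["est"]], 0),
                  alpha = a_fit[["est"]],
                  beta = max(b_fit[["est"]], 0),
                  se = c(mu = se_mu, gamma = g_fit[["se"]],
                         alpha = a_fit[["se"]], beta = b_fit[["se"]]))
}

cumtrapz_vec <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

#' Affine production envelope between two metabolic states
#'
#' Interpolates the fitted aerobic and microaerobic rate sets linearly in
#' the growth rate: `gamma(mu)`, `delta(mu)` and the minimal acetoin
#' exchange `min_alpha(mu)` are affine on the domain
#' `[mu_micro, mu_aero]`. The microaerobic anchor of `min_alpha` is the
#' acetoin *uptake* rate observed while accumulated acetoin is being
#' reconsumed.
#'
#' @param aero,micro [condition_rates()] for the aerobic and microaerobic
#'   anchors; `aero$mu` must exceed `micro$mu`.
#' @return object of class `production_envelope` with the two anchors and
#'   the affine coefficients.
#' @export
build_envelope <- function(aero, micro) {
  stopifnot(inherits(aero, "condition_rates"), inherits(micro, "condition_rates"))
  if (!(aero$mu > micro$mu)) {
    stop_domain("aerobic anchor growth rate must exceed the microaerobic one")
  }
  affine <- function(y0, y1) {
    sl <- (y1 - y0) / (aero$mu - micro$mu)
    c(intercept = y0 - sl * micro$mu, slope = sl)
  }
  structure(list(
    aerobic = aero, microaerobic = micro,
    mu_min = micro$mu, mu_max = aero$mu,
    gamma_co = affine(micro$gamma, aero$gamma),
    delta_co = affine(micro$delta, aero$delta),
    min_alpha_co = affine(micro$alpha, aero$alpha)),
    class = "production_envelope")
}

#' @export
print.production_envelope <- function(x, ...) {
  cat(sprintf("<production_envelope> mu in [%.4g, %.4g] 1/h\n", x$mu_min, x$mu_max))
  print(x$aerobic); print(x$microaerobic)
  invisible(x)
}

#' Evaluate the production envelope at a growth rate
#'
#' @param pe a [build_envelope()] object.
#' @param mu growth rate(s) within the envelope domain; values outside
#'   `[mu_micro, mu_aero]` (beyond 1e-9 slack) raise a `dcfba_domain_error`
#'   rather than being clamped.
#' @return data frame with columns `mu`, `gamma`, `delta`, `min_alpha`,
#'   `beta_max` (`= delta - min_alpha`).
#' @export
rates_at <- function(pe, mu) {
  stopifnot(inherits(pe, "production_envelope"))
  if (any(mu < pe$mu_min - 1e-9 | mu > pe$mu_max + 1e-9)) {
    stop_domain(sprintf(
      "mu outside the envelope domain [%.4g, %.4g]; extrapolation is refused",
      pe$mu_min, pe$mu_max))
  }
  ev <- function(co) unname(co["intercept"] + co["slope"] * mu)
  data.frame(mu = mu,
             gamma = ev(pe$gamma_co),
             delta = ev(pe$delta_co),
             min_alpha = ev(pe$min_alpha_co),
             beta_max = ev(pe$delta_co) - ev(pe$min_alpha_co))
}

#' Verify envelope feasibility against the metabolic model
#'
#' Samples `n_samples` equidistant growth rates over the envelope domain
#' and, at each, asks the strain model for the minimal oxygen uptake with
#' the envelope rates fixed (`alpha = min_alpha(mu)`,
#' `beta = delta(mu) - min_alpha(mu)`). Infeasible points are reported, not
#' raised.
#'
#' @param pe a [build_envelope()] object.
#' @param net the production-strain network.
#' @param n_samples number of equidistant growth rates (default 11).
#' @param ... passed to [min_oxygen_uptake()].
#' @return data frame of class `envelope_verification` with columns `mu`,
#'   `xi` (mmol/gDW/h, `NA` where infeasible) and `feasible`.
#' @export
verify_envelope <- function(pe, net, n_samples = 11L, ...) {
  mu <- if (n_samples == 1L) pe$mu_min else
    seq(pe$mu_min, pe$mu_max, length.out = n_samples)
  r <- rates_at(pe, mu)
  xi <- vapply(seq_along(mu), function(i) {
    tryCatch(min_oxygen_uptake(net, mu[i], r$gamma[i], r$delta[i],
                               r$min_alpha[i], ...),
             dcfba_infeasible_error = function(e) NA_real_)
  }, numeric(1))
  structure(data.frame(mu = mu, xi = xi, feasible = !is.na(xi)),
            class = c("envelope_verification", "data.frame"))
}

#' Serialize / restore a production envelope as JSON
#'
#' @param pe a [build_envelope()] object.
#' @param path file path.
#' @return `write_envelope` returns `path` invisibly; `read_envelope`
#'   returns the restored `production_envelope`.
#' @export
write_envelope <- function(pe, path) {
  anchors <- lapply(pe[c("aerobic", "microaerobic")], function(a) {
    a[c("condition", "mu", "gamma", "alpha", "beta", "delta", "se")]
  })
  jsonlite::write_json(
    list(anchors = anchors,
         coefficients = pe[c("gamma_co", "delta_co", "min_alpha_co")],
         mu_domain = c(pe$mu_min, pe$mu_max)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_envelope
#' @export
read_envelope <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- function(a) condition_rates(a$condition, a$mu, a$gamma, a$alpha, a$beta,
                                    se = if (length(a$se)) unlist(a$se) else NULL)
  build_envelope(mk(x$anchors$aerobic), mk(x$anchors$microaerobic))
}
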