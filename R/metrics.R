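#' Process performance metrics
#'
#' Computes the standard fermentation performance metrics at process end
#' under the fixed-volume (1 L) convention: final titer `B(T)`, average
#' productivity `P = B(T)/T`, product-to-substrate yield
#' `Y = B(T)/Gcon(T)` and biomass-specific yield `Y_BX = B(T)/X`. Biomass
#' is often not sampled at the final time point, so a separate `X_time`
#' annotation records when the supplied `X` was measured.
#'
#' @param B final 2,3-butanediol concentration (g/L).
#' @param A final acetoin concentration (g/L).
#' @param Gcon cumulative consumed glucose (g/L); must be positive for the
#'   yield to be defined.
#' @param X biomass concentration (g/L) at `X_time`.
#' @param t_total process length `T` (h), must be positive.
#' @param X_time time of the biomass measurement (default `t_total`).
#' @param t_s1,t_s2 optional stage lengths (h); when given they must sum to
#'   `t_total`.
#' @return an object of class `process_metrics` with fields `titer`,
#'   `productivity`, `yield`, `yield_biomass`, `acetoin_final`,
#'   `glucose_consumed`, `t_total`, `t_s1`, `t_s2`, `X_time`.
#' @examples
#' m <- compute_metrics(B = 44.5, A = 0, Gcon = 170, X = 10, t_total = 23.8)
#' m$productivity  # 1.87 g/L/h
#' @export
compute_metrics <- function(B, A, Gcon, X, t_total, X_time = t_total,
                            t_s1 = NA_real_, t_s2 = NA_real_) {
  if (t_total <= 0) stop_domain("process length must be positive")
  if (!is.na(t_s1) && !is.na(t_s2) &&
      abs(t_s1 + t_s2 - t_total) > 1e-9 * max(1, t_total)) {
    stop_domain("stage lengths must sum to the process length")
  }
  zero_prod <- B <= 0
  structure(list(
    titer = max(B, 0),
    productivity = if (zero_prod) 0 else B / t_total,
    yield = if (zero_prod) 0 else if (Gcon > 0) B / Gcon else NA_real_,
    yield_biomass = if (zero_prod) 0 else if (X > 0) B / X else NA_real_,
    acetoin_final = A, glucose_consumed = Gcon,
    t_total = t_total, t_s1 = t_s1, t_s2 = t_s2, X_time = X_time),
    class = "process_metrics")
}

#' @export
print.process_metrics <- function(x, ...) {
  cat(sprintf(
    "<process_metrics> titer=%.4g g/L, P=%.4g g/L/h, Y=%.3g g/g over T=%.4g h\n",
    x$titer, x$productivity, x$yield, x$t_total))
  invisible(x)
}

#' Lag-phase correction
#'
#' Estimates the lag-phase length from the exponential growth of the
#' aerobic first stage and removes it from the experimental process
#' length: assuming `X_S1 = X_0 * exp(mu_S1 * (t_LS1 - t_L))`, the lag is
#' `t_L = t_LS1 - ln(X_S1/X_0)/mu_S1` and the lag-free process length is
#' `T = T_L - t_L`. Negative lag estimates (biomass grew faster than the
#' fitted rate implies) are clamped to 0 with a warning.
#'
#' @param t_ls1 uncorrected (lag-inclusive) length of stage 1 (h).
#' @param X_s1 biomass at the end of stage 1 (g/L).
#' @param X_0 biomass at inoculation (g/L); requires `X_s1 > X_0 > 0`.
#' @param mu_s1 fitted exponential growth rate of stage 1 (1/h), > 0.
#' @param T_L experimental (lag-inclusive) process length (h).
#' @return list with `t_lag` (h), `t_total` (lag-free length `T`, h) and
#'   `t_s1` (lag-free stage-1 length, h).
#' @export
lag_correct <- function(t_ls1, X_s1, X_0, mu_s1, T_L) {
  if (!(X_s1 > X_0 && X_0 > 0)) {
    stop_domain("need biomass X_s1 > X_0 > 0 for the lag estimate")
  }
  if (mu_s1 <= 0) stop_domain("stage-1 growth rate must be positive")
  if (!(t_ls1 >= 0 && T_L >= t_ls1)) {
    stop_domain("need 0 <= t_ls1 <= T_L")
  }
  t_lag <- t_ls1 - log(X_s1 / X_0) / mu_s1
  if (t_lag < 0) {
    warning("negative lag estimate clamped to 0")
    t_lag <- 0
  }
  if (t_lag > t_ls1) t_lag <- t_ls1
  list(t_lag = t_lag, t_total = T_L - t_lag, t_s1 = t_ls1 - t_lag)
}
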