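#' Continuous two-reactor chemostat design
#'
#' Steady-state design of two chemostats in series (equal volumes, shared
#' feed flux `phi`): the feed (glucose only, concentration `G_feed`)
#' enters reactor 1, whose outflow feeds reactor 2. Per reactor the
#' species balances at steady state are
#' `0 = phi * (c_in - c) + q * X` for `c` in (A, B, X, G) with the
#' envelope-coupled specific rates `q = (alpha_i, beta_i, mu_i, gamma_i)`.
#' A non-washout steady state of reactor 1 requires `mu_1 = phi`; reactor
#' 2 requires `mu_2 < phi`.
#'
#' @param phi feed flux per reactor volume (1/h).
#' @param G_feed glucose concentration in the feed (g/L).
#' @param rates data frame with 2 rows (reactor 1, 2) and columns `mu`,
#'   `alpha`, `beta`, `gamma`.
#' @param states data frame with 2 rows and columns `A`, `B`, `X`, `G`
#'   (g/L, steady-state concentrations).
#' @return object of class `chemostat_design` including
#'   [chemostat_metrics()] output in `$metrics`.
#' @export
chemostat_design <- function(phi, G_feed, rates, states) {
  stopifnot(nrow(rates) == 2, nrow(states) == 2)
  if (phi < 0 || G_feed < 0) stop_domain("phi and G_feed must be non-negative")
  if (any(states < -1e-9)) stop_domain("steady-state concentrations must be >= 0")
  d <- structure(list(phi = phi, G_feed = G_feed,
                      rates = rates, states = states),
                 class = "chemostat_design")
  d$metrics <- chemostat_metrics(d)
  d
}

#' @export
print.chemostat_design <- function(x, ...) {
  cat(sprintf(
    "<chemostat_design> phi=%.4g 1/h, G_feed=%.4g g/L; mu1=%.4g, mu2=%.4g 1/h\n  titer B2=%.4g g/L, productivity phi*B2=%.4g g/L/h (per total volume %.4g)\n",
    x$phi, x$G_feed, x$rates$mu[1], x$rates$mu[2],
    x$metrics$titer, x$metrics$productivity, x$metrics$productivity_total_volume))
  invisible(x)
}

#' Steady-state residual of a two-reactor design
#'
#' Evaluates the eight species balances (A, B, X, G in both reactors) at
#' the design's concentrations and rates; an exact steady state gives a
#' zero vector. The feed carries glucose only, so the reactor-1 inflow
#' terms are `phi * (0 - A1)`, `phi * (0 - B1)`, `phi * (0 - X1)` and
#' `phi * (G_feed - G1)`.
#'
#' @param design a [chemostat_design()].
#' @return named numeric length-8 residual vector (g/L/h).
#' @export
steady_state_residual <- function(design) {
  stopifnot(inherits(design, "chemostat_design"))
  phi <- design$phi; s <- design$states; r <- design$rates
  feed <- c(A = 0, B = 0, X = 0, G = design$G_feed)
  res <- numeric(0)
  for (i in 1:2) {
    inflow <- if (i == 1) feed else
      c(A = s$A[1], B = s$B[1], X = s$X[1], G = s$G[1])
    q <- c(A = r$alpha[i], B = r$beta[i], X = r$mu[i], G = r$gamma[i])
    ri <- phi * (inflow - unlist(s[i, c("A", "B", "X", "G")])) +
      q * s$X[i]
    names(ri) <- paste0(c("A", "B", "X", "G"), i)
    res <- c(res, ri)
  }
  res
}

## closed-form steady state under complete glucose consumption (G2 = 0):
## decision variables are mu1 (= phi), mu2, alpha1, alpha2 and X1
chemostat_closed_form <- function(pe, mu1, mu2, alpha1, alpha2, X1) {
  r1 <- rates_at(pe, mu1); r2 <- rates_at(pe, mu2)
  phi <- mu1
  beta1 <- r1$delta - alpha1; beta2 <- r2$delta - alpha2
  if (phi <= mu2) return(NULL)                       # reactor-2 washout
  X2 <- phi * X1 / (phi - mu2)
  G1 <- -r2$gamma * X2 / phi                         # so that G2 = 0
  G_feed <- G1 - r1$gamma * X1 / phi
  A1 <- alpha1 * X1 / phi
  B1 <- beta1 * X1 / phi
  A2 <- A1 + alpha2 * X2 / phi
  B2 <- B1 + beta2 * X2 / phi
  list(phi = phi, G_feed = G_feed,
       rates = data.frame(mu = c(mu1, mu2), alpha = c(alpha1, alpha2),
                          beta = c(beta1, beta2),
                          gamma = c(r1$gamma, r2$gamma)),
       states = data.frame(A = c(A1, A2), B = c(B1, B2),
                           X = c(X1, X2), G = c(G1, 0)),
       min_alpha = c(r1$min_alpha, r2$min_alpha))
}

#' Optimize the continuous two-reactor process
#'
#' Maximizes titer (`B2`) or volumetric productivity (`phi * B2`) over the
#' feed flux, feed glucose concentration and the per-reactor
#' envelope-coupled operating points, subject to the steady-state
#' balances, complete glucose consumption in reactor 2 (`G2 = 0`),
#' `G1 >= 0`, non-negative acetoin concentrations, biomass caps
#' `X_i <= X_max`, `G_feed <= G_feed_max`, growth rates inside the
#' envelope domain and optionally a minimal titer `B2 >= titer_floor`.
#' The objective weights follow `psi1 * F1 + psi2 * F2` with `psi1 = 1`,
#' `psi2 = 0.01`, `F2` (complementary slackness of the embedded FBA)
#' identically 0 in the envelope-reduced formulation.
#'
#' The steady state is closed-form in the decision variables
#' (`mu1 = phi`, `mu2`, `alpha1`, `alpha2`, `X1`), so the optimizer works
#' in that reduced space with an augmented-Lagrangian method and seeded
#' multistart.
#'
#' @param pe a [build_envelope()] envelope.
#' @param objective `"productivity"` (default) or `"titer"`.
#' @param X_max biomass cap per reactor (g/L), default 25.
#' @param titer_floor optional minimal `B2` (g/L), `NULL` to disable.
#' @param G_feed_max cap on the feed glucose concentration (g/L), default
#'   600 (near the solubility limit).
#' @param n_starts seeded multistart count.
#' @param seed RNG seed for the restarts.
#' @return a [chemostat_design()] with solver status in `$status`.
#' @export
optimize_chemostat <- function(pe, objective = c("productivity", "titer"),
                               X_max = 25, titer_floor = NULL,
                               G_feed_max = 600, n_starts = 5L, seed = 1L) {
  stopifnot(inherits(pe, "production_envelope"))
  objective <- match.arg(objective)
  mu_lo <- pe$mu_min; mu_hi <- pe$mu_max
  a_lo <- min(pe$aerobic$alpha, pe$microaerobic$alpha)
  a_hi <- max(pe$aerobic$alpha, pe$microaerobic$alpha)
  ## z = (mu1, mu2, alpha1, alpha2, X1)
  lower <- c(mu_lo + 1e-4, mu_lo, a_lo, a_lo, 1e-3)
  upper <- c(mu_hi, mu_hi, a_hi, a_hi, X_max)

  value_of <- function(cf) {
    if (objective == "titer") cf$states$B[2] else cf$phi * cf$states$B[2]
  }
  fobj <- function(z) {
    cf <- chemostat_closed_form(pe, z[1], z[2], z[3], z[4], z[5])
    if (is.null(cf)) return(-1e6)
    value_of(cf)
  }
  cineq <- function(z) {
    cf <- chemostat_closed_form(pe, z[1], z[2], z[3], z[4], z[5])
    if (is.null(cf)) return(rep(10, 8 + !is.null(titer_floor)))
    g <- c((z[2] - z[1] + 1e-4) / 0.1,                  # mu2 < mu1 = phi
           (cf$states$X[2] - X_max) / X_max,
           (cf$G_feed - G_feed_max) / G_feed_max,
           -cf$G_feed / G_feed_max,
           -cf$states$A[1],                             # A1 >= 0
           -cf$states$A[2],                             # A2 >= 0
           (cf$min_alpha[1] - z[3]) / 0.3,
           (cf$min_alpha[2] - z[4]) / 0.3)
    if (!is.null(titer_floor)) {
      g <- c(g, (titer_floor - cf$states$B[2]) / max(titer_floor, 1))
    }
    g
  }

  min_alpha_at <- function(mu) rates_at(pe, mu)$min_alpha
  ## project a point back onto the constraint set (the steady state is
  ## linear in X1, so the caps reduce to a rescaling of X1)
  repair <- function(z) {
    z <- pmin(pmax(z, lower), upper)
    z[2] <- min(z[2], z[1] - 1e-4)
    z[2] <- max(z[2], lower[2])
    z[3] <- max(z[3], min_alpha_at(z[1]), 0)       # A1 >= 0 needs alpha1 >= 0
    z[4] <- max(z[4], min_alpha_at(z[2]))
    cf <- chemostat_closed_form(pe, z[1], z[2], z[3], z[4], z[5])
    if (is.null(cf)) return(z)
    ratio_X2 <- cf$states$X[2] / z[5]              # X2 per unit X1
    z[4] <- max(z[4], -z[3] / ratio_X2 * 1)        # A2 >= 0
    scl <- min(1, X_max / cf$states$X[2],
               if (cf$G_feed > 0) G_feed_max / cf$G_feed else 1)
    z[5] <- max(lower[5], z[5] * scl)
    z
  }
  feasible_ok <- function(z) {
    cf <- chemostat_closed_form(pe, z[1], z[2], z[3], z[4], z[5])
    !is.null(cf) && all(cineq(z) <= 1e-7) && all(unlist(cf$states) >= -1e-8)
  }

  set.seed(seed)
  starts <- list(
    ## structural guess: aerobic reactor 1, microaerobic reactor 2,
    ## biomass just below the caps
    c(mu_hi, mu_lo, max(0, min_alpha_at(mu_hi)), min_alpha_at(mu_lo),
      X_max * (mu_hi - mu_lo) / mu_hi),
    c(0.5 * (mu_hi + mu_lo), mu_lo, 0, 0, 0.5 * X_max))
  for (i in seq_len(max(0L, n_starts - 2L))) {
    starts[[i + 2L]] <- lower + runif(5) * (upper - lower)
  }
  best <- NULL; best_val <- -Inf; status <- "failed"
  consider <- function(z, st) {
    z <- repair(z)
    if (!feasible_ok(z)) return(invisible(NULL))
    cf <- chemostat_closed_form(pe, z[1], z[2], z[3], z[4], z[5])
    if (value_of(cf) > best_val) {
      best <<- cf; best_val <<- value_of(cf); status <<- st
    }
    invisible(NULL)
  }
  for (z0 in starts) {
    consider(z0, "start_heuristic")
    opt <- tryCatch(
      al_optimize(repair(z0), fobj, lower, upper, cineq = cineq,
                  maximize = TRUE,
                  parscale = c(0.1, 0.1, 0.1, 0.1, X_max / 2),
                  outer = 6L, inner = 80L),
      error = function(e) NULL)
    if (is.null(opt)) next
    consider(opt$par, if (opt$converged) "optimal" else "feasible_suboptimal")
  }
  if (is.null(best)) {
    stop_infeasible("no feasible two-reactor design found under the given constraints",
                    violated = c("X_max", "titer_floor", "G_feed_max"))
  }
  best$states$A <- pmax(best$states$A, 0)
  best$states$G <- pmax(best$states$G, 0)
  d <- chemostat_design(best$phi, best$G_feed, best$rates, best$states)
  d$objective <- objective
  d$psi <- c(psi1 = 1, psi2 = 1e-2)
  d$status <- status
  d
}

#' Steady-state process metrics of a two-reactor design
#'
#' Titer is the reactor-2 butanediol concentration `B2`; volumetric
#' productivity is reported both per reactor-2 volume (`phi * B2`, the
#' optimization objective) and per total volume of the two equal reactors
#' (`phi * B2 / 2`); yield is `B2 / G_feed`.
#'
#' @param design a [chemostat_design()].
#' @return list with `titer`, `productivity`, `productivity_total_volume`,
#'   `yield`.
#' @export
chemostat_metrics <- function(design) {
  stopifnot(inherits(design, "chemostat_design"))
  B2 <- design$states$B[2]
  list(titer = B2,
       productivity = design$phi * B2,
       productivity_total_volume = design$phi * B2 / 2,
       yield = if (design$G_feed > 0) B2 / design$G_feed else NA_real_)
}

#' Integrate the two-reactor cascade to steady state
#'
#' Stiff ODE integration of the eight species balances with the specific
#' rates frozen at the design values. The default initial condition is
#' the one used for start-up verification: reactor-1 biomass at its
#' steady-state value, all other concentrations 0.
#'
#' @param design a [chemostat_design()].
#' @param t_end integration horizon (h); default `30 / phi` (about thirty
#'   residence times).
#' @param init optional named numeric of length 8
#'   (`A1, B1, X1, G1, A2, B2, X2, G2`) overriding the default initial
#'   condition.
#' @param n_out number of output time points.
#' @return data frame `time_h` plus the 8 state columns.
#' @export
integrate_two_reactor <- function(design, t_end = NULL, init = NULL,
                                  n_out = 201L) {
  stopifnot(inherits(design, "chemostat_design"))
  phi <- design$phi
  if (is.null(t_end)) t_end <- 30 / max(phi, 1e-6)
  nm <- c("A1", "B1", "X1", "G1", "A2", "B2", "X2", "G2")
  if (is.null(init)) {
    init <- setNames(numeric(8), nm)
    init["X1"] <- design$states$X[1]
  }
  r <- design$rates; Gf <- design$G_feed
  rhs <- function(t, y, p) {
    y1 <- y[1:4]; y2 <- y[5:8]
    q1 <- c(r$alpha[1], r$beta[1], r$mu[1], r$gamma[1])
    q2 <- c(r$alpha[2], r$beta[2], r$mu[2], r$gamma[2])
    d1 <- phi * (c(0, 0, 0, Gf) - y1) + q1 * y1[3]
    d2 <- phi * (y1 - y2) + q2 * y2[3]
    list(c(d1, d2))
  }
  times <- seq(0, t_end, length.out = n_out)
  sol <- deSolve::ode(init, times, rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) {
    dcfba_stop(sprintf("two-reactor integration failed at t=%.3g h", max(sol[, 1])),
               "dcfba_numeric_error", last_state = sol[nrow(sol), ])
  }
  out <- as.data.frame(sol)
  names(out) <- c("time_h", nm)
  if (min(out$G1, out$G2) < -1e-6) {
    warning("glucose went negative during integration (batch-like depletion); the frozen-rate linearization is not valid beyond substrate exhaustion")
  }
  out
}
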