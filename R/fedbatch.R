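#' Fed-batch optimal-control problem
#'
#' Defines the growth-rate-controlled fed-batch optimization: maximize a
#' process metric (final titer or average productivity) over a
#' piecewise-constant growth-rate and acetoin-rate profile, subject to the
#' state dynamics `X' = mu X`, `B' = beta X`, `A' = alpha X`,
#' `Gcon' = |gamma| X`, the production-envelope couplings
#' `gamma = gamma(mu)`, `beta = delta(mu) - alpha`,
#' `alpha >= min_alpha(mu)`, a cap on total consumed glucose
#' (`Gcon(T) <= Gmax`), the path constraint `A(t) >= 0`, a fixed process
#' length `T` and growth-rate bounds `mu_lb <= mu <= mu_ub`. Volume is
#' fixed at 1 L, so concentrations and titers coincide.
#'
#' @param pe a [build_envelope()] production envelope.
#' @param t_final process length `T` (h); lengths below 0.5 h are refused.
#' @param Gmax maximum consumed glucose (g/L).
#' @param mu_lb,mu_ub growth-rate control bounds (1/h); default to the
#'   envelope domain. Must satisfy
#'   `mu_micro <= mu_lb < mu_ub <= mu_aero`.
#' @param X0 initial biomass (g/L).
#' @param objective `"titer"` or `"productivity"` (the `F1` choice).
#' @param psi objective weights `c(psi1, psi2, psi3)`; defaults
#'   `psi1 = 1` (titer) or `10` (productivity), `psi2 = 10`,
#'   `psi3 = 0.1`. `psi2` multiplies the embedded-FBA complementary
#'   slackness term, which is identically 0 in the envelope-reduced
#'   formulation used here.
#' @param nFE number of finite elements (default 30).
#' @param degree collocation degree (Radau points, 1--3; default 3).
#' @return an object of class `fedbatch_problem`.
#' @export
fedbatch_problem <- function(pe, t_final, Gmax, mu_lb = NULL, mu_ub = NULL,
                             X0 = 0.25,
                             objective = c("titer", "productivity"),
                             psi = NULL, nFE = 30L, degree = 3L) {
  stopifnot(inherits(pe, "production_envelope"))
  objective <- match.arg(objective)
  if (is.null(mu_lb)) mu_lb <- pe$mu_min
  if (is.null(mu_ub)) mu_ub <- pe$mu_max
  if (t_final < 0.5) stop_domain("process lengths below 0.5 h are refused")
  if (Gmax <= 0) stop_domain("Gmax must be positive")
  if (X0 <= 0) stop_domain("X0 must be positive")
  if (!(pe$mu_min <= mu_lb + 1e-12 && mu_lb <= mu_ub &&
        mu_ub <= pe$mu_max + 1e-12)) {
    stop_domain("need mu_micro <= mu_lb <= mu_ub <= mu_aero")
  }
  if (is.null(psi)) {
    psi <- c(psi1 = if (objective == "productivity") 10 else 1,
             psi2 = 10, psi3 = 0.1)
  }
  if (!(nFE >= 1 && degree %in% 1:3)) {
    stop_build("nFE must be >= 1 and degree in 1..3")
  }
  structure(list(pe = pe, t_final = t_final, Gmax = Gmax,
                 mu_lb = mu_lb, mu_ub = mu_ub, X0 = X0,
                 objective = objective, psi = psi,
                 nFE = as.integer(nFE), degree = as.integer(degree)),
            class = "fedbatch_problem")
}

#' @export
print.fedbatch_problem <- function(x, ...) {
  cat(sprintf(
    "<fedbatch_problem> T=%.4g h, Gmax=%.4g g/L, mu in [%.4g, %.4g] 1/h, X0=%.3g g/L\n  objective: %s; nFE=%d, degree=%d\n",
    x$t_final, x$Gmax, x$mu_lb, x$mu_ub, x$X0, x$objective, x$nFE, x$degree))
  invisible(x)
}

## ---- closed-form two-stage process simulation --------------------------

# (exp(mu*tau) - 1)/mu, stable for mu -> 0
growth_integral <- function(mu, tau) {
  if (abs(mu) < 1e-12) tau else expm1(mu * tau) / mu
}

# time until q * X0 * growth_integral(mu, t) reaches "amount" (Inf if never)
time_to_amount <- function(amount, q, mu, X0) {
  if (q * X0 <= 0) return(Inf)
  g <- amount / (q * X0)
  if (abs(mu) < 1e-12) g else {
    arg <- mu * g
    if (arg <= -1) Inf else log1p(arg) / mu
  }
}

# simulate the canonical two-stage policy with switch time t_s; returns
# per-segment controls and closed-form states at segment boundaries
two_stage_sim <- function(prob, t_s) {
  pe <- prob$pe; T <- prob$t_final
  t_s <- min(max(t_s, 0), T)
  r1 <- rates_at(pe, prob$mu_ub)
  alpha1 <- max(r1$min_alpha, 0)          # A(0)=0: uptake impossible
  r2 <- rates_at(pe, prob$mu_lb)

  segs <- matrix(numeric(0), ncol = 7,
                 dimnames = list(NULL, c("t0", "t1", "mu", "alpha", "beta",
                                         "gamma", "frozen")))
  st <- c(X = prob$X0, B = 0, A = 0, G = 0)  # G = consumed glucose
  t <- 0
  push <- function(t0, t1, mu, alpha, beta, gamma, st0) {
    tau <- t1 - t0
    gi <- growth_integral(mu, tau)
    st1 <- c(X = unname(st0["X"]) * (if (abs(mu) < 1e-12) 1 else exp(mu * tau)),
             B = unname(st0["B"] + beta * st0["X"] * gi),
             A = unname(st0["A"] + alpha * st0["X"] * gi),
             G = unname(st0["G"] + (-gamma) * st0["X"] * gi))
    segs <<- rbind(segs, c(t0, t1, mu, alpha, beta, gamma,
                           as.numeric(mu == 0 && gamma == 0 &&
                                        beta == 0 && alpha == 0)))
    st1
  }

  ## stage 1: aerobic growth at mu_ub
  if (t_s > 1e-12) {
    t_cap <- time_to_amount(prob$Gmax - st["G"], -r1$gamma, r1$mu, st["X"])
    t1 <- min(t_s, t_cap)
    if (t1 > 1e-12) {
      st <- push(t, t1, r1$mu, alpha1, r1$delta - alpha1, r1$gamma, st)
      t <- t1
    }
    if (t < t_s - 1e-12) {               # glucose exhausted: freeze
      st <- push(t, t_s, 0, 0, 0, 0, st)
      t <- t_s
    }
  }

  ## stage 2: microaerobic at mu_lb; acetoin uptake until depletion
  while (t < T - 1e-12) {
    budget <- prob$Gmax - st["G"]
    if (budget <= 1e-12) {
      st <- push(t, T, 0, 0, 0, 0, st); t <- T; break
    }
    alpha2 <- r2$min_alpha
    if (alpha2 < 0 && st["A"] <= 1e-12) alpha2 <- 0
    t_g <- time_to_amount(budget, -r2$gamma, r2$mu, st["X"])
    t_dep <- if (alpha2 < 0) {
      time_to_amount(unname(st["A"]), -alpha2, r2$mu, st["X"])
    } else Inf
    t1 <- min(t + t_g, t + t_dep, T)
    st <- push(t, t1, r2$mu, alpha2, r2$delta - alpha2, r2$gamma, st)
    if (abs(t1 - (t + t_dep)) < 1e-12) st["A"] <- 0   # exact event
    t <- t1
  }
  segs <- as.data.frame(segs)
  segs$frozen <- segs$frozen > 0
  metric <- if (prob$objective == "titer") st[["B"]] else st[["B"]] / T
  list(segments = segs, final = st, t_switch = t_s, metric = metric)
}

#' Brute-force two-stage oracle
#'
#' Independent reference optimizer for the fed-batch problem: optimal
#' profiles are two-stage (aerobic growth at `mu_ub`, then microaerobic
#' production at `mu_lb` with acetoin re-uptake until depletion), so only
#' the switch time needs searching. The oracle scans `t_s` on a uniform
#' grid over `[0, T]` using exact piecewise-exponential integration
#' (`X(t) = X_s e^{mu t}`, species via `(q/mu) X_s (e^{mu t} - 1)`), with
#' the glucose cap enforced by freezing the process once the cap is
#' reached, and optionally refines around the best grid point.
#'
#' @param prob a [fedbatch_problem()].
#' @param n_grid grid resolution (>= 50).
#' @param refine number of 10x local refinement passes (default 2).
#' @return object of class `fedbatch_oracle`: best switch time, objective
#'   metric, final states, segment table and process metrics.
#' @export
two_stage_oracle <- function(prob, n_grid = 201L, refine = 2L) {
  stopifnot(inherits(prob, "fedbatch_problem"))
  if (n_grid < 50) stop_domain("oracle grid resolution must be >= 50")
  scan <- function(lo, hi, n) {
    ts <- seq(lo, hi, length.out = n)
    vals <- vapply(ts, function(s) two_stage_sim(prob, s)$metric, numeric(1))
    list(ts = ts, vals = vals, best = ts[which.max(vals)])
  }
  g <- scan(0, prob$t_final, n_grid)
  best <- g$best
  step <- prob$t_final / (n_grid - 1)
  for (k in seq_len(refine)) {
    lo <- max(0, best - step); hi <- min(prob$t_final, best + step)
    g2 <- scan(lo, hi, 21L)
    best <- g2$best
    step <- (hi - lo) / 20
  }
  sim <- two_stage_sim(prob, best)
  fin <- sim$final
  t_s1 <- stage1_length(sim$segments, prob)
  metrics <- compute_metrics(B = fin[["B"]], A = fin[["A"]],
                             Gcon = fin[["G"]], X = fin[["X"]],
                             t_total = prob$t_final,
                             t_s1 = t_s1, t_s2 = prob$t_final - t_s1)
  structure(list(t_switch = best, objective_value = sim$metric,
                 final = fin, segments = sim$segments,
                 metrics = metrics, prob = prob),
            class = "fedbatch_oracle")
}

stage1_length <- function(segments, prob) {
  mid <- (prob$mu_lb + prob$mu_ub) / 2
  s1 <- segments$mu >= mid & !segments$frozen
  if (!any(s1)) 0 else max(segments$t1[s1])
}

#' @export
print.fedbatch_oracle <- function(x, ...) {
  cat(sprintf("<fedbatch_oracle> t_switch=%.4g h, %s=%.6g\n",
              x$t_switch, x$prob$objective, x$objective_value))
  invisible(x)
}

## ---- orthogonal collocation --------------------------------------------

# right-Radau collocation points on (0, 1]
radau_points <- function(degree) {
  switch(degree,
         c(1),
         c(1 / 3, 1),
         c(0.155051025721682, 0.644948974278318, 1))
}

# Lagrange differentiation matrix C (d x (d+1)) and the basis points
# tau = (0, radau); C[r, j] = dL_j/dtau at collocation point r
colloc_matrices <- function(degree) {
  tau <- c(0, radau_points(degree))
  d <- degree
  polys <- lapply(seq_along(tau), function(j) {
    p <- 1
    for (r in seq_along(tau)) if (r != j) {
      ## multiply p by (x - tau[r]) / (tau[j] - tau[r])
      p <- c(p, 0) - c(0, p * tau[r])
      p <- p / (tau[j] - tau[r])
    }
    p   # coefficients, highest power first
  })
  dpoly <- function(p) {
    n <- length(p) - 1
    if (n == 0) return(0)
    p[seq_len(n)] * (n:1)
  }
  evalp <- function(p, x) sum(p * x^(rev(seq_along(p)) - 1))
  C <- matrix(0, d, d + 1)
  for (j in seq_len(d + 1)) {
    dp <- dpoly(polys[[j]])
    for (r in seq_len(d)) C[r, j] <- evalp(dp, tau[r + 1])
  }
  list(tau = tau, C = C,
       Cd = C[, -1, drop = FALSE], C0 = C[, 1],
       Cd_inv = solve(C[, -1, drop = FALSE]))
}

#' Build the collocation NLP for a fed-batch problem
#'
#' Discretizes the control problem by orthogonal collocation on moving
#' finite elements: per element `k` the decision variables are the four
#' state values at each of the `degree + 1` basis points, the controls
#' `mu_k` and `alpha_k`, and the element length `h_k`
#' (`nFE * (4 * (degree + 1) + 2 + 1)` variables in total; the initial
#' state is fixed data). Constraints are the collocation residuals of the
#' state dynamics, state continuity across elements, `sum(h_k) = T`,
#' `Gcon(T) <= Gmax`, `A >= 0` at all collocation points, the envelope
#' couplings and `alpha_k >= min_alpha(mu_k)`, with
#' `h_k in [0.1, 10] * T/nFE`.
#'
#' Because the dynamics are linear in the states for given controls, the
#' returned handle evaluates states by exactly solving the collocation
#' equations element by element (a reduced-space formulation); the full
#' residual vector is exposed for verification.
#'
#' @param prob a [fedbatch_problem()].
#' @return an NLP handle (list) with the dimensions, bound vectors and
#'   evaluation closures used by [solve_fedbatch()].
#' @export
build_collocation_nlp <- function(prob) {
  stopifnot(inherits(prob, "fedbatch_problem"))
  cm <- colloc_matrices(prob$degree)
  nFE <- prob$nFE; d <- prob$degree
  h_nom <- prob$t_final / nFE
  h_lb <- 0.1 * h_nom; h_ub <- 10 * h_nom
  if (h_lb > h_ub) stop_build("inconsistent element length bounds")
  if (prob$mu_lb > prob$mu_ub) stop_build("inconsistent growth-rate bounds")
  pe <- prob$pe
  alpha_max <- max(pe$aerobic$alpha, pe$microaerobic$alpha)
  alpha_min <- min(pe$aerobic$alpha, pe$microaerobic$alpha)

  idx_mu <- seq_len(nFE)
  idx_alpha <- nFE + seq_len(nFE)
  idx_h <- 2L * nFE + seq_len(nFE)
  lower <- c(rep(prob$mu_lb, nFE), rep(alpha_min, nFE), rep(h_lb, nFE))
  upper <- c(rep(prob$mu_ub, nFE), rep(alpha_max, nFE), rep(h_ub, nFE))

  ## exact element-wise solve of the collocation equations (states are
  ## linear in the controls' presence): returns states at all collocation
  ## points plus element end states
  eval_states <- function(z) {
    mu <- z[idx_mu]; alpha <- z[idx_alpha]; h <- z[idx_h]
    r <- rates_at(pe, pmin(pmax(mu, pe$mu_min), pe$mu_max))
    beta <- r$delta - alpha
    gamma <- r$gamma
    Xc <- matrix(0, d, nFE); Bc <- matrix(0, d, nFE)
    Ac <- matrix(0, d, nFE); Gc <- matrix(0, d, nFE)
    x0 <- prob$X0; b0 <- 0; a0 <- 0; g0 <- 0
    ends <- matrix(0, 4, nFE)
    for (k in seq_len(nFE)) {
      M <- cm$Cd - diag(h[k] * mu[k], d)
      xk <- solve(M, -cm$C0 * x0)
      lin <- function(q, s0) cm$Cd_inv %*% (h[k] * q * xk - cm$C0 * s0)
      bk <- lin(beta[k], b0)
      ak <- lin(alpha[k], a0)
      gk <- lin(-gamma[k], g0)
      Xc[, k] <- xk; Bc[, k] <- bk; Ac[, k] <- ak; Gc[, k] <- gk
      x0 <- xk[d]; b0 <- bk[d]; a0 <- ak[d]; g0 <- gk[d]
      ends[, k] <- c(x0, b0, a0, g0)
    }
    list(X = Xc, B = Bc, A = Ac, G = Gc, ends = ends,
         mu = mu, alpha = alpha, h = h,
         min_alpha = r$min_alpha, beta = beta, gamma = gamma)
  }

  eval_solution <- function(z) {
    s <- eval_states(z)
    titer <- s$ends[2, nFE]
    prod <- titer / prob$t_final
    metric <- if (prob$objective == "titer") titer else prod
    list(states = s, titer = titer, productivity = prod, metric = metric,
         Gcon_T = s$ends[4, nFE], A_min = min(s$A), A_T = s$ends[3, nFE])
  }

  ## full collocation residual vector at a point (verification only)
  residuals <- function(z) {
    s <- eval_states(z)
    res <- c()
    x0 <- prob$X0; b0 <- 0; a0 <- 0; g0 <- 0
    for (k in seq_len(nFE)) {
      der <- function(v0, vc) cm$C %*% c(v0, vc)   # polynomial derivative
      res <- c(res,
               der(x0, s$X[, k]) - s$h[k] * s$mu[k] * s$X[, k],
               der(b0, s$B[, k]) - s$h[k] * s$beta[k] * s$X[, k],
               der(a0, s$A[, k]) - s$h[k] * s$alpha[k] * s$X[, k],
               der(g0, s$G[, k]) + s$h[k] * s$gamma[k] * s$X[, k])
      x0 <- s$X[prob$degree, k]; b0 <- s$B[prob$degree, k]
      a0 <- s$A[prob$degree, k]; g0 <- s$G[prob$degree, k]
    }
    c(res, sum(s$h) - prob$t_final)
  }

  list(prob = prob, colloc = cm,
       n_decision = nFE * (4L * (d + 1L) + 2L + 1L),
       n_reduced = 3L * nFE,
       idx = list(mu = idx_mu, alpha = idx_alpha, h = idx_h),
       lower = lower, upper = upper,
       eval_states = eval_states, eval_solution = eval_solution,
       residuals = residuals)
}

## map a two-stage simulation onto a moving-element control vector
profile_from_segments <- function(nlp, segments) {
  prob <- nlp$prob; nFE <- prob$nFE; T <- prob$t_final
  h_lb <- 0.1 * T / nFE
  segments <- segments[!(segments$frozen & segments$t1 - segments$t0 < 1e-5 * T), ,
                       drop = FALSE]
  segs <- segments[segments$t1 - segments$t0 > 1e-9, , drop = FALSE]
  ## merge segments too short to carry an element of admissible length
  repeat {
    len <- segs$t1 - segs$t0
    if (nrow(segs) <= 1 || all(len >= h_lb)) break
    i <- which(len < h_lb)[1]
    j <- if (i == 1) 2L else i - 1L
    keep <- segs[-i, , drop = FALSE]
    if (i == 1) keep$t0[1] <- segs$t0[1] else keep$t1[j] <- segs$t1[i]
    segs <- keep
  }
  len <- segs$t1 - segs$t0
  h_ub <- 10 * T / nFE
  ## allocate elements by integration "work" (fast-growth segments need
  ## short elements for the collocation polynomial to track exp(mu t))
  work <- len * (segs$mu + 1 / T)
  n_i <- pmax(1L, round(nFE * work / sum(work)))
  n_i <- pmax(n_i, ceiling(len / h_ub))          # respect max element length
  n_cap <- pmax(1L, floor(len / h_lb))           # and min element length
  n_i <- pmin(n_i, n_cap)
  guard <- 0L
  while (sum(n_i) != nFE && (guard <- guard + 1L) < 1000L) {
    if (sum(n_i) > nFE) {
      cand <- which(n_i > pmax(1L, ceiling(len / h_ub)))
      i <- cand[which.min(work[cand] / n_i[cand])]
      n_i[i] <- n_i[i] - 1L
    } else {
      cand <- which(n_i < n_cap)
      i <- cand[which.max(work[cand] / n_i[cand])]
      n_i[i] <- n_i[i] + 1L
    }
  }
  mu <- numeric(0); alpha <- numeric(0); h <- numeric(0)
  r_lb <- rates_at(prob$pe, prob$mu_lb)
  for (i in seq_len(nrow(segs))) {
    mu_i <- segs$mu[i]; al_i <- segs$alpha[i]
    if (segs$frozen[i]) {        # not representable: park at slowest growth
      mu_i <- prob$mu_lb; al_i <- max(r_lb$min_alpha, 0)
    }
    mu <- c(mu, rep(min(max(mu_i, prob$mu_lb), prob$mu_ub), n_i[i]))
    alpha <- c(alpha, rep(al_i, n_i[i]))
    h <- c(h, rep(len[i] / n_i[i], n_i[i]))
  }
  h <- h * (T / sum(h))
  c(mu, alpha, h)
}

#' Solve the fed-batch optimal-control problem
#'
#' Optimizes the collocation NLP from [build_collocation_nlp()] by an
#' augmented-Lagrangian method warm-started from the [two_stage_oracle()]
#' solution (plus seeded perturbed restarts), then repairs the iterate back
#' to feasibility (element lengths rescaled to sum to `T` exactly; acetoin
#' rates bumped minimally where the `A >= 0` path constraint is grazed).
#' The best feasible candidate is returned; ties are broken towards the
#' highest objective, then the earliest stage switch. Because the warm
#' start itself is a feasible candidate, the result is never worse than
#' (marginally below) the oracle optimum.
#'
#' @param prob a [fedbatch_problem()].
#' @param n_starts number of optimization starts including the oracle warm
#'   start (default 3).
#' @param n_grid oracle grid resolution.
#' @param seed seed for the perturbed restarts (deterministic).
#' @param inner,outer L-BFGS-B iteration and augmented-Lagrangian round
#'   caps.
#' @return object of class `fedbatch_solution`: control `profile`
#'   (per-element `mu`, `alpha`, `h`), collocation `trajectory`,
#'   weighted objective `F`, the raw `metric`, [compute_metrics()] output
#'   in `$metrics`, stage decomposition, solver `status` and the embedded
#'   oracle solution.
#' @export
solve_fedbatch <- function(prob, n_starts = 3L, n_grid = 201L, seed = 1L,
                           inner = 40L, outer = 3L) {
  stopifnot(inherits(prob, "fedbatch_problem"))
  nlp <- build_collocation_nlp(prob)
  oracle <- two_stage_oracle(prob, n_grid = n_grid)

  ## warm start from a marginally tightened glucose cap so that the
  ## collocation discretization of the oracle trajectory stays feasible;
  ## restrict the switch-time search to no-freeze policies (consumption at
  ## the final time at most the tightened cap), since frozen (glucose-
  ## exhausted) intervals are not representable in the NLP
  Gmax_m <- prob$Gmax * (1 - 1e-3)
  prob_inf <- prob; prob_inf$Gmax <- Inf
  gcon_T <- function(ts) two_stage_sim(prob_inf, ts)$final[["G"]]
  if (gcon_T(0) > prob$Gmax) {
    stop_infeasible(
      "glucose cap is exceeded even by the slowest-growing policy; no feasible process of this length",
      violated = "Gcon")
  }
  ts_cap <- if (gcon_T(prob$t_final) <= Gmax_m) prob$t_final else
    uniroot(function(ts) gcon_T(ts) - Gmax_m, c(0, prob$t_final),
            tol = 1e-10)$root
  prob_m <- prob; prob_m$Gmax <- Gmax_m
  ts_grid <- seq(0, ts_cap, length.out = min(n_grid, 101L))
  vals <- vapply(ts_grid, function(s) two_stage_sim(prob_m, s)$metric, numeric(1))
  ts_best <- ts_grid[which.max(vals)]
  step <- if (length(ts_grid) > 1) ts_grid[2] - ts_grid[1] else 0
  if (step > 0) {
    fine <- seq(max(0, ts_best - step), min(ts_cap, ts_best + step),
                length.out = 21L)
    vals_f <- vapply(fine, function(s) two_stage_sim(prob_m, s)$metric, numeric(1))
    ts_best <- fine[which.max(vals_f)]
  }
  z_warm <- profile_from_segments(nlp, two_stage_sim(prob_m, ts_best)$segments)

  repair <- function(z) {
    z <- pmin(pmax(z, nlp$lower), nlp$upper)
    h <- z[nlp$idx$h]
    for (i in 1:3) {
      h <- pmin(pmax(h * (prob$t_final / sum(h)), nlp$lower[nlp$idx$h]),
                nlp$upper[nlp$idx$h])
    }
    h[length(h)] <- h[length(h)] + (prob$t_final - sum(h))
    z[nlp$idx$h] <- h
    ## envelope lower bound on alpha
    r <- rates_at(prob$pe, z[nlp$idx$mu])
    z[nlp$idx$alpha] <- pmax(z[nlp$idx$alpha], r$min_alpha)
    ## bump alpha up where A dips below zero (monotone in alpha)
    for (pass in 1:2) {
      s <- nlp$eval_states(z)
      bad <- which(apply(s$A, 2, min) < -1e-10)
      if (!length(bad)) break
      for (k in bad) {
        lo <- z[nlp$idx$alpha[k]]; hi <- max(nlp$upper[nlp$idx$alpha])
        f <- function(a) {
          zz <- z; zz[nlp$idx$alpha[k]] <- a
          min(nlp$eval_states(zz)$A[, k])
        }
        if (f(hi) < -1e-10) { z[nlp$idx$alpha[k]] <- hi; next }
        z[nlp$idx$alpha[k]] <- uniroot(function(a) f(a) + 1e-10, c(lo, hi),
                                       tol = 1e-12)$root
      }
    }
    z
  }
  feasible <- function(sol, z) {
    r <- rates_at(prob$pe, z[nlp$idx$mu])
    sol$Gcon_T <= prob$Gmax * (1 + 1e-6) &&
      sol$A_min >= -1e-8 &&
      all(z[nlp$idx$alpha] >= r$min_alpha - 1e-8) &&
      abs(sum(z[nlp$idx$h]) - prob$t_final) <= 1e-8 * prob$t_final
  }

  A_scale <- max(1, abs(oracle$final[["A"]]), prob$X0)
  cineq <- function(z) {
    sol <- nlp$eval_solution(z)
    r <- rates_at(prob$pe, z[nlp$idx$mu])
    c((sol$Gcon_T - prob$Gmax) / prob$Gmax,
      -as.numeric(sol$states$A) / A_scale,
      (r$min_alpha - z[nlp$idx$alpha]) / 0.3)
  }
  ceq <- function(z) (sum(z[nlp$idx$h]) - prob$t_final) / prob$t_final
  fobj <- function(z) nlp$eval_solution(z)$metric
  parscale <- c(rep(0.1, prob$nFE), rep(0.1, prob$nFE),
                rep(prob$t_final / prob$nFE, prob$nFE))

  set.seed(seed)
  starts <- list(z_warm)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1L)) {
      zi <- z_warm
      zi[nlp$idx$mu] <- pmin(pmax(
        zi[nlp$idx$mu] + runif(prob$nFE, -0.2, 0.2) * (prob$mu_ub - prob$mu_lb),
        prob$mu_lb), prob$mu_ub)
      starts[[i + 1L]] <- zi
    }
  }

  candidates <- list()
  for (z0 in starts) {
    z0r <- repair(z0)
    sol0 <- nlp$eval_solution(z0r)
    candidates[[length(candidates) + 1L]] <-
      list(z = z0r, sol = sol0, feasible = feasible(sol0, z0r), status = "oracle_warm_start")
    opt <- tryCatch(
      al_optimize(z0r, fobj, nlp$lower, nlp$upper, ceq = ceq, cineq = cineq,
                  maximize = TRUE, parscale = parscale,
                  outer = outer, inner = inner),
      error = function(e) NULL)
    if (is.null(opt)) next
    zr <- repair(opt$par)
    solr <- nlp$eval_solution(zr)
    candidates[[length(candidates) + 1L]] <-
      list(z = zr, sol = solr, feasible = feasible(solr, zr),
           status = if (opt$converged) "optimal" else "feasible_suboptimal")
  }
  feas <- Filter(function(cdd) cdd$feasible, candidates)
  if (!length(feas)) {
    stop_infeasible(
      "no feasible fed-batch solution found (glucose cap too tight for the process length?)",
      violated = "Gcon")
  }
  vals <- vapply(feas, function(cdd) cdd$sol$metric, numeric(1))
  best_val <- max(vals)
  top <- feas[vals >= best_val - 1e-9 * max(1, abs(best_val))]
  ts1 <- vapply(top, function(cdd) {
    profile_stage1(cdd$z, nlp)
  }, numeric(1))
  best <- top[[which.min(ts1)]]

  z <- best$z; s <- nlp$eval_states(z)
  profile <- data.frame(element = seq_len(prob$nFE),
                        mu = z[nlp$idx$mu], alpha = z[nlp$idx$alpha],
                        h = z[nlp$idx$h])
  t_bounds <- cumsum(profile$h)
  tau <- nlp$colloc$tau[-1]
  times <- c(0, unlist(lapply(seq_len(prob$nFE), function(k) {
    (t_bounds[k] - profile$h[k]) + tau * profile$h[k]
  })))
  trajectory <- data.frame(
    time_h = times,
    X = c(prob$X0, as.numeric(s$X)),
    B = c(0, as.numeric(s$B)),
    A = c(0, as.numeric(s$A)),
    Gcon = c(0, as.numeric(s$G)))
  t_s1 <- profile_stage1(z, nlp)
  sol <- best$sol
  metrics <- compute_metrics(B = sol$titer, A = sol$A_T,
                             Gcon = sol$Gcon_T,
                             X = s$ends[1, prob$nFE],
                             t_total = prob$t_final,
                             t_s1 = t_s1, t_s2 = prob$t_final - t_s1)
  structure(list(profile = profile, trajectory = trajectory,
                 metric = sol$metric, titer = sol$titer,
                 productivity = sol$productivity,
                 F = eval_objective(metrics, psi = prob$psi,
                                    objective = prob$objective),
                 metrics = metrics, t_s1 = t_s1, t_s2 = prob$t_final - t_s1,
                 status = best$status, oracle = oracle, nlp = nlp,
                 prob = prob),
            class = "fedbatch_solution")
}

profile_stage1 <- function(z, nlp) {
  prob <- nlp$prob
  mu <- z[nlp$idx$mu]; h <- z[nlp$idx$h]
  mid <- (prob$mu_lb + prob$mu_ub) / 2
  below <- which(mu < mid)
  if (!length(below)) sum(h) else if (below[1] == 1) 0 else sum(h[seq_len(below[1] - 1L)])
}

#' @export
print.fedbatch_solution <- function(x, ...) {
  cat(sprintf(
    "<fedbatch_solution> %s-optimal: titer=%.4g g/L, P=%.4g g/L/h (t_S1=%.3g h, t_S2=%.3g h)\n  status: %s; oracle %s=%.6g\n",
    x$prob$objective, x$titer, x$productivity, x$t_s1, x$t_s2, x$status,
    x$prob$objective, x$oracle$objective_value))
  invisible(x)
}

#' Simulate a piecewise-constant control profile
#'
#' High-accuracy forward integration of the fed-batch dynamics under a
#' given per-element control profile, with event handling: when acetoin is
#' depleted while `alpha < 0`, the acetoin rate switches to 0 (and the
#' butanediol rate to `delta(mu)`); when cumulative glucose consumption
#' reaches `Gmax`, all rates freeze.
#'
#' @param pe a [build_envelope()] object.
#' @param profile data frame with columns `mu`, `alpha`, `h` (one row per
#'   element), e.g. the `$profile` of a [solve_fedbatch()] solution.
#' @param X0 initial biomass (g/L).
#' @param Gmax optional glucose cap (g/L), default `Inf`.
#' @param dt_out output sampling step (h).
#' @param rtol,atol integrator tolerances.
#' @return data frame `time_h`, `X`, `B`, `A`, `Gcon`.
#' @export
simulate_piecewise <- function(pe, profile, X0, Gmax = Inf, dt_out = 0.1,
                               rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(pe, "production_envelope"))
  if (any(profile$mu < pe$mu_min - 1e-9 | profile$mu > pe$mu_max + 1e-9)) {
    stop_domain("control profile contains growth rates outside the envelope domain")
  }
  r_all <- rates_at(pe, profile$mu)
  if (any(profile$alpha < r_all$min_alpha - 1e-9)) {
    stop_domain("control profile contains acetoin rates below min_alpha(mu)")
  }
  state <- c(X = X0, B = 0, A = 0, Gcon = 0)
  out <- data.frame(time_h = 0, X = X0, B = 0, A = 0, Gcon = 0)
  t0 <- 0
  frozen <- FALSE
  for (k in seq_len(nrow(profile))) {
    h <- profile$h[k]
    if (h <= 1e-12) next
    mu <- profile$mu[k]; alpha <- profile$alpha[k]
    delta <- r_all$delta[k]; gamma <- r_all$gamma[k]
    t_end <- t0 + h
    while (t0 < t_end - 1e-12) {
      if (frozen) {
        times <- unique(c(seq(t0, t_end, by = dt_out), t_end))
        seg <- data.frame(time_h = times[-1],
                          X = state[["X"]], B = state[["B"]],
                          A = state[["A"]], Gcon = state[["Gcon"]])
        out <- rbind(out, seg)
        t0 <- t_end
        break
      }
      a_eff <- if (state[["A"]] <= 1e-12 && alpha < 0) 0 else alpha
      b_eff <- delta - a_eff
      rhs <- function(t, y, p) {
        list(c(mu * y[1], b_eff * y[1], a_eff * y[1], -gamma * y[1]))
      }
      roots <- function(t, y, p) {
        c(if (a_eff < 0) y[3] else 1,
          if (is.finite(Gmax)) Gmax - y[4] else 1)
      }
      times <- unique(c(seq(t0, t_end, by = dt_out), t_end))
      sol <- deSolve::lsodar(state, times, rhs, parms = NULL,
                             rootfunc = roots, rtol = rtol, atol = atol)
      n <- nrow(sol)
      state <- setNames(as.numeric(sol[n, -1]), c("X", "B", "A", "Gcon"))
      out <- rbind(out, setNames(as.data.frame(sol[-1, , drop = FALSE]),
                                 c("time_h", "X", "B", "A", "Gcon")))
      t_reached <- sol[n, 1]
      if (t_reached < t_end - 1e-10) {      # a root stopped the integrator
        if (is.finite(Gmax) && state[["Gcon"]] >= Gmax - 1e-8) {
          frozen <- TRUE
        } else {
          state[["A"]] <- max(state[["A"]], 0)
        }
      }
      t0 <- t_reached
    }
    t0 <- t_end
  }
  rownames(out) <- NULL
  out$A <- pmax(out$A, 0)
  out
}

#' Weighted control objective
#'
#' Evaluates `F = psi1 * F1 + psi2 * F2 + psi3 * F3(T)` where `F1` is the
#' chosen terminal metric (titer or productivity), `F2` is the embedded-FBA
#' complementary-slackness term (identically 0 in the envelope-reduced
#' formulation, but accepted as an input for the general form) and the
#' running term `integral of dF3/dt` telescopes to the terminal
#' productivity `F3(T) = P`.
#'
#' @param x a `fedbatch_solution` or a [compute_metrics()] result.
#' @param psi weights `c(psi1, psi2, psi3)`; defaults as in
#'   [fedbatch_problem()].
#' @param objective `F1` choice, `"titer"` or `"productivity"`; defaults to
#'   the solution's own objective when `x` is a solution.
#' @param F2 value of the complementary-slackness term (default 0).
#' @return the scalar objective `F`.
#' @export
eval_objective <- function(x, psi = NULL, objective = NULL, F2 = 0) {
  if (inherits(x, "fedbatch_solution")) {
    if (is.null(psi)) psi <- x$prob$psi
    if (is.null(objective)) objective <- x$prob$objective
    x <- x$metrics
  }
  stopifnot(inherits(x, "process_metrics"))
  objective <- match.arg(objective, c("titer", "productivity"))
  if (is.null(psi)) psi <- c(if (objective == "productivity") 10 else 1, 10, 0.1)
  F1 <- if (objective == "titer") x$titer else x$productivity
  unname(psi[1] * F1 + psi[2] * F2 + psi[3] * x$productivity)
}
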