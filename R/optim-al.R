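# Augmented-Lagrangian driver over L-BFGS-B.
#
# The collocation and chemostat NLPs are smooth, box-constrained problems
# with a handful of equality/inequality constraints. They are solved by a
# classical augmented-Lagrangian outer loop (Rockafellar form for the
# inequalities) with stats::optim(method = "L-BFGS-B") as the inner solver.
# Callers are expected to scale constraints to O(1).

al_optimize <- function(z0, f, lower, upper,
                        ceq = NULL, cineq = NULL,
                        maximize = TRUE, parscale = NULL,
                        outer = 5L, inner = 60L,
                        rho0 = 10, rho_growth = 5, ctol = 1e-7) {
  sgn <- if (maximize) -1 else 1           # optim minimizes
  z0 <- pmin(pmax(z0, lower), upper)
  n_eq <- if (is.null(ceq)) 0L else length(ceq(z0))
  n_in <- if (is.null(cineq)) 0L else length(cineq(z0))
  lambda <- numeric(n_eq); mu <- numeric(n_in)
  rho <- rho0
  if (is.null(parscale)) parscale <- pmax(abs(z0), 1e-2)

  penalized <- function(z) {
    val <- sgn * f(z)
    if (n_eq) {
      h <- ceq(z)
      val <- val + sum(lambda * h) + 0.5 * rho * sum(h^2)
    }
    if (n_in) {
      g <- cineq(z)
      s <- pmax(0, mu + rho * g)
      val <- val + sum(s^2 - mu^2) / (2 * rho)
    }
    if (!is.finite(val)) val <- 1e10
    val
  }
  violation <- function(z) {
    v <- 0
    if (n_eq) v <- max(v, max(abs(ceq(z))))
    if (n_in) v <- max(v, max(0, cineq(z)))
    v
  }

  z <- z0
  prev_viol <- Inf
  for (k in seq_len(outer)) {
    opt <- optim(z, penalized, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = inner, parscale = parscale,
                                factr = 1e7))
    z <- opt$par
    viol <- violation(z)
    if (n_eq) lambda <- lambda + rho * ceq(z)
    if (n_in) mu <- pmax(0, mu + rho * cineq(z))
    if (viol <= ctol) break
    if (viol > 0.25 * prev_viol) rho <- rho * rho_growth
    prev_viol <- viol
  }
  list(par = z, value = f(z), violation = violation(z),
       converged = violation(z) <= ctol)
}
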