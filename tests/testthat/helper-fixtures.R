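# Shared fixtures, built in code at test time.

fixture_pe <- function() default_envelope()

# a small, quick fed-batch problem on the fixture envelope
fixture_problem <- function(t_final = 24, objective = "productivity",
                            Gmax = 200, mu_lb = NULL, nFE = 12L) {
  fedbatch_problem(fixture_pe(), t_final = t_final, Gmax = Gmax,
                   mu_lb = mu_lb, X0 = 0.25, objective = objective,
                   nFE = nFE)
}

# Independent LP oracle: a textbook Big-M *tableau* simplex (standard
# inequality form, Bland pivoting). Deliberately a different algorithm
# family and problem transformation than the package's bounded-variable
# revised simplex, so the two routes share no code path.
# Solves max c'x s.t. A x <= b, x >= 0.
tableau_lp <- function(cc, A, b, max_iter = 20000L, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  geq <- b < 0
  A[geq, ] <- -A[geq, , drop = FALSE]; b[geq] <- -b[geq]
  k <- sum(geq)
  Slk <- diag(m); Slk[cbind(which(geq), which(geq))] <- -1
  Art <- matrix(0, m, k); Art[cbind(which(geq), seq_len(k))] <- 1
  Tb <- cbind(A, Slk, Art)
  M <- 1e6 * (1 + max(abs(cc)))
  cost <- c(cc, rep(0, m), rep(-M, k))
  basis <- ifelse(geq, n + m + cumsum(geq), n + seq_len(m))
  rhs <- b
  for (it in seq_len(max_iter)) {
    y <- cost[basis] %*% Tb
    red <- cost - as.numeric(y)
    ent <- which(red > tol)[1]
    if (is.na(ent)) {
      if (any(basis > n + m & rhs > 1e-6)) {
        return(list(status = "infeasible", value = NA_real_))
      }
      x <- numeric(n)
      in_x <- basis <= n
      x[basis[in_x]] <- rhs[in_x]
      return(list(status = "optimal", value = sum(cc * x), x = x))
    }
    col <- Tb[, ent]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded", value = Inf))
    ratio <- rhs[pos] / col[pos]
    cand <- pos[ratio <= min(ratio) + tol]
    piv <- cand[which.min(basis[cand])]            # Bland tie-break
    pr <- Tb[piv, ] / col[piv]; prhs <- rhs[piv] / col[piv]
    upd <- -Tb[, ent]
    Tb <- Tb + outer(upd, pr); rhs <- rhs + upd * prhs
    Tb[piv, ] <- pr; rhs[piv] <- prhs
    basis[piv] <- ent
  }
  list(status = "maxiter", value = NA_real_)
}

# oracle for max c'x s.t. A x = b, lb <= x <= ub (finite bounds):
# shift to y = x - lb >= 0, equalities as paired inequalities
linprog_oracle <- function(cc, A, b, lb, ub) {
  A <- as.matrix(A)
  beq <- b - as.numeric(A %*% lb)
  Ai <- rbind(A, -A, diag(length(cc)))
  bi <- c(beq, -beq, ub - lb)
  r <- tableau_lp(cc, Ai, bi)
  if (r$status != "optimal") return(NULL)
  r$value + sum(cc * lb)
}

# FBA through the independent oracle: max flux of `objective` on `net`
fba_oracle <- function(net, objective) {
  cc <- as.numeric(net$reactions == objective)
  lb <- pmax(net$lower, -1000); ub <- pmin(net$upper, 1000)
  linprog_oracle(cc, as.matrix(net$stoich),
                 rep(0, length(net$metabolites)), lb, ub)
}

# forward-Euler replay of a segment table with fixed step, using the
# closed form of the Euler recursion within each constant-rate segment
euler_replay <- function(segments, X0, dt = 1e-4) {
  st <- c(X = X0, B = 0, A = 0, G = 0)
  for (i in seq_len(nrow(segments))) {
    n <- max(1L, round((segments$t1[i] - segments$t0[i]) / dt))
    mu <- segments$mu[i]
    grow <- (1 + mu * dt)^n
    gi <- if (abs(mu) < 1e-14) n * dt else (grow - 1) / mu
    st <- c(X = st[["X"]] * grow,
            B = st[["B"]] + segments$beta[i] * st[["X"]] * gi,
            A = st[["A"]] + segments$alpha[i] * st[["X"]] * gi,
            G = st[["G"]] - segments$gamma[i] * st[["X"]] * gi)
  }
  st
}
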