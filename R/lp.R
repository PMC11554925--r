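# Bounded-variable two-phase primal simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  l <= x <= u
# with possibly infinite bounds and free variables. Written for the small,
# dense LPs of flux balance analysis on reduced networks (tens of columns);
# clarity and bit-stable determinism are preferred over speed. Bland's rule
# is used throughout, so the method terminates on degenerate problems.

#' Solve a bounded-variable linear program
#'
#' @param obj objective coefficients (length n).
#' @param mat constraint matrix (m x n), equality constraints `mat %*% x = rhs`.
#' @param rhs right-hand side (length m).
#' @param lower,upper variable bounds, may be `-Inf`/`Inf`.
#' @param maximize logical; maximize (default) or minimize.
#' @param tol pivot/reduced-cost tolerance (default 1e-9).
#' @param max_iter simplex iteration cap.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `x` (primal solution, `NA` unless optimal), `objective`, and for
#'   infeasible problems `violated`: the row names (or indices) whose balance
#'   could not be closed.
#' @keywords internal
#' @export
lp_solve <- function(obj, mat, rhs, lower, upper, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  mat <- as.matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lower) == n, length(upper) == n)
  if (any(lower > upper + tol)) {
    stop_model("variable bounds violate lower <= upper")
  }
  sense <- if (maximize) 1 else -1
  cc <- sense * as.numeric(obj)

  ## augment with one artificial column per row
  lb <- c(as.numeric(lower), rep(0, m))
  ub <- c(as.numeric(upper), rep(Inf, m))
  status <- integer(n + m)              # 0 basic, 1 at lb, 2 at ub, 3 free at 0
  x <- numeric(n + m)
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && (!is.finite(ub[j]) || abs(lb[j]) <= abs(ub[j]))) {
      status[j] <- 1L; x[j] <- lb[j]
    } else if (is.finite(ub[j])) {
      status[j] <- 2L; x[j] <- ub[j]
    } else {
      status[j] <- 3L; x[j] <- 0
    }
  }
  r <- as.numeric(rhs) - as.numeric(mat %*% x[seq_len(n)])
  sig <- ifelse(r >= 0, 1, -1)
  A <- cbind(mat, diag(sig, nrow = m, ncol = m), deparse.level = 0)
  x[n + seq_len(m)] <- abs(r)
  status[n + seq_len(m)] <- 0L
  basis <- n + seq_len(m)

  bvec <- as.numeric(rhs)
  run_simplex <- function(cost, x, status, basis, allow_unbounded) {
    for (iter in seq_len(max_iter)) {
      B <- A[, basis, drop = FALSE]
      nonbasic <- which(status != 0L)
      ## refresh basic values from the nonbasic ones (no incremental drift)
      x[basis] <- tryCatch(
        solve(B, bvec - A[, nonbasic, drop = FALSE] %*% x[nonbasic]),
        error = function(e) stop_solver("singular simplex basis"))
      y <- solve(t(B), cost[basis])
      entering <- 0L; dir <- 0
      for (j in nonbasic) {                       # Bland: smallest index
        d <- cost[j] - sum(y * A[, j])
        if (status[j] == 1L && d > tol) { entering <- j; dir <- 1; break }
        if (status[j] == 2L && d < -tol) { entering <- j; dir <- -1; break }
        if (status[j] == 3L && abs(d) > tol) {
          entering <- j; dir <- if (d > 0) 1 else -1; break
        }
      }
      if (entering == 0L) {
        return(list(x = x, status = status, basis = basis, optimal = TRUE))
      }
      w <- solve(B, A[, entering])
      ## ratio test: basic variables move as xB - theta * dir * w
      theta <- Inf; leave_pos <- 0L; leave_to <- 0L
      for (i in seq_len(m)) {
        bi <- basis[i]; di <- dir * w[i]
        if (di > tol) {
          if (is.finite(lb[bi])) {
            t_i <- (x[bi] - lb[bi]) / di
            if (t_i < theta - tol ||
                (t_i < theta + tol && (leave_pos == 0L || bi < basis[leave_pos]))) {
              theta <- min(theta, t_i); leave_pos <- i; leave_to <- 1L
            }
          }
        } else if (di < -tol) {
          if (is.finite(ub[bi])) {
            t_i <- (ub[bi] - x[bi]) / (-di)
            if (t_i < theta - tol ||
                (t_i < theta + tol && (leave_pos == 0L || bi < basis[leave_pos]))) {
              theta <- min(theta, t_i); leave_pos <- i; leave_to <- 2L
            }
          }
        }
      }
      span <- if (is.finite(lb[entering]) && is.finite(ub[entering])) {
        ub[entering] - lb[entering]
      } else Inf
      if (span < theta - tol) { theta <- span; leave_pos <- 0L }
      if (!is.finite(theta)) {
        if (allow_unbounded) {
          return(list(x = x, status = status, basis = basis, optimal = FALSE,
                      unbounded = TRUE))
        }
        stop_solver("phase-1 subproblem unbounded (should not happen)")
      }
      theta <- max(theta, 0)
      x[entering] <- x[entering] + dir * theta
      x[basis] <- x[basis] - dir * theta * w
      if (leave_pos == 0L) {            # bound-to-bound flip
        status[entering] <- if (dir > 0) 2L else 1L
        x[entering] <- if (dir > 0) ub[entering] else lb[entering]
      } else {
        out <- basis[leave_pos]
        x[out] <- if (leave_to == 1L) lb[out] else ub[out]   # snap
        status[out] <- leave_to
        basis[leave_pos] <- entering
        status[entering] <- 0L
      }
    }
    stop_solver("simplex iteration limit reached")
  }

  ## phase 1: drive artificials to zero
  need_phase1 <- any(x[n + seq_len(m)] > tol)
  if (need_phase1) {
    c1 <- c(rep(0, n), rep(-1, m))
    res <- run_simplex(c1, x, status, basis, allow_unbounded = FALSE)
    x <- res$x; status <- res$status; basis <- res$basis
    infeas <- sum(x[n + seq_len(m)])
    if (infeas > 1e-7 * max(1, max(abs(rhs)))) {
      bad <- which(x[n + seq_len(m)] > tol)
      nm <- rownames(mat)
      violated <- if (!is.null(nm)) nm[bad] else bad
      return(list(status = "infeasible", x = rep(NA_real_, n),
                  objective = NA_real_, violated = violated))
    }
  }
  ## phase 2: pin artificials at zero and optimize the true objective
  ub[n + seq_len(m)] <- 0
  x[n + seq_len(m)][status[n + seq_len(m)] != 0L] <- 0
  c2 <- c(cc, rep(0, m))
  res <- run_simplex(c2, x, status, basis, allow_unbounded = TRUE)
  if (isTRUE(res$unbounded)) {
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = sense * Inf, violated = NULL))
  }
  xopt <- res$x[seq_len(n)]
  list(status = "optimal", x = xopt,
       objective = sum(as.numeric(obj) * xopt), violated = NULL)
}
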