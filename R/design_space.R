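#' Sweep grid for mapping the process solution space
#'
#' @param T_values process lengths (h), strictly increasing, >= 2 values.
#'   The default spans short processes densely (10--25 h in 10 steps) and
#'   long ones more coarsely (25--60 h in 8 steps).
#' @param mu_lb_values minimal-growth-rate constraints (1/h), strictly
#'   increasing, >= 2 values; default 0.005--0.055 in 11 equidistant steps.
#' @param Gmax glucose cap (g/L) shared by all runs.
#' @param objectives subset of `c("titer", "productivity")`.
#' @return a list of class `sweep_grid`.
#' @export
sweep_grid <- function(T_values = unique(c(seq(10, 25, length.out = 10),
                                           seq(25, 60, length.out = 8))),
                       mu_lb_values = seq(0.005, 0.055, length.out = 11),
                       Gmax = 200,
                       objectives = c("titer", "productivity")) {
  objectives <- match.arg(objectives, several.ok = TRUE)
  chk <- function(v, nm) {
    if (length(v) < 2 || any(diff(v) <= 0)) {
      stop_config(sprintf("%s must be strictly increasing with >= 2 values", nm))
    }
  }
  chk(T_values, "T_values"); chk(mu_lb_values, "mu_lb_values")
  if (Gmax <= 0) stop_config("Gmax must be positive")
  structure(list(T_values = T_values, mu_lb_values = mu_lb_values,
                 Gmax = Gmax, objectives = objectives),
            class = "sweep_grid")
}

#' Map the titer--productivity solution space
#'
#' Runs one optimization per grid point and objective and records the
#' resulting process metrics. The default `"oracle"` mode uses the
#' deterministic [two_stage_oracle()] (fast, embarrassingly parallel in
#' structure); `"nlp"` additionally polishes each point with
#' [solve_fedbatch()]. Failed points are recorded with their status, not
#' dropped.
#'
#' @param grid a [sweep_grid()].
#' @param pe a [build_envelope()] envelope.
#' @param X0 initial biomass (g/L).
#' @param mode `"oracle"` (default) or `"nlp"`.
#' @param n_grid oracle switch-time grid resolution.
#' @param ... passed to [solve_fedbatch()] in `"nlp"` mode.
#' @return data frame of class `solution_space_map` with one row per
#'   (T, mu_lb, objective): `titer`, `productivity`, `yield`, `Gcon`,
#'   `t_s1`, `t_s1_frac`, `glucose_consumed` (flag: `Gcon >= 0.999 Gmax`)
#'   and `status`.
#' @export
sweep_solution_space <- function(grid, pe, X0 = 0.25,
                                 mode = c("oracle", "nlp"),
                                 n_grid = 201L, ...) {
  stopifnot(inherits(grid, "sweep_grid"), inherits(pe, "production_envelope"))
  mode <- match.arg(mode)
  combos <- expand.grid(T = grid$T_values, mu_lb = grid$mu_lb_values,
                        objective = grid$objectives,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    Ti <- combos$T[i]; mu_lb <- combos$mu_lb[i]; objv <- combos$objective[i]
    rec <- data.frame(T = Ti, mu_lb = mu_lb, objective = objv,
                      titer = NA_real_, productivity = NA_real_,
                      yield = NA_real_, Gcon = NA_real_, A_final = NA_real_,
                      t_s1 = NA_real_, t_s1_frac = NA_real_,
                      glucose_consumed = NA, status = "failed")
    res <- tryCatch({
      prob <- fedbatch_problem(pe, t_final = Ti, Gmax = grid$Gmax,
                               mu_lb = mu_lb, X0 = X0, objective = objv)
      if (mode == "oracle") {
        o <- two_stage_oracle(prob, n_grid = n_grid)
        list(m = o$metrics, status = "optimal")
      } else {
        s <- solve_fedbatch(prob, n_grid = n_grid, ...)
        list(m = s$metrics, status = s$status)
      }
    }, dcfba_error = function(e) NULL)
    if (is.null(res)) return(rec)
    m <- res$m
    rec$titer <- m$titer; rec$productivity <- m$productivity
    rec$yield <- m$yield; rec$Gcon <- m$glucose_consumed
    rec$A_final <- m$acetoin_final
    rec$t_s1 <- m$t_s1; rec$t_s1_frac <- m$t_s1 / Ti
    rec$glucose_consumed <- m$glucose_consumed >= 0.999 * grid$Gmax
    rec$status <- res$status
    rec
  })
  out <- do.call(rbind, rows)
  attr(out, "Gmax") <- grid$Gmax
  class(out) <- c("solution_space_map", "data.frame")
  out
}

#' Classify proportionality and trade-off regions
#'
#' Finds the productivity-maximizing process length `T*` at the smallest
#' swept `mu_lb` and labels every record: lengths below `T*` lie in the
#' proportionality region (maximal titer and productivity co-increase with
#' `T`), lengths above in the trade-off region (titer gains cost
#' productivity). A non-unimodal productivity-vs-T profile triggers a
#' classification warning listing all local maxima.
#'
#' @param map a [sweep_solution_space()] result containing
#'   productivity-objective records at >= 4 distinct process lengths for
#'   the smallest `mu_lb`.
#' @return list with `T_star` and `map`: the input with a `region` column
#'   (`"proportionality"`, `"optimum"`, `"trade-off"`).
#' @export
classify_regions <- function(map) {
  stopifnot(inherits(map, "solution_space_map"))
  mu0 <- min(map$mu_lb)
  prof <- map[map$mu_lb == mu0 & map$objective == "productivity" &
                is.finite(map$productivity), , drop = FALSE]
  prof <- prof[order(prof$T), ]
  if (length(unique(prof$T)) < 4) {
    stop_insufficient_data(
      "need productivity records at >= 4 distinct T values at the smallest mu_lb")
  }
  P <- prof$productivity
  n <- length(P)
  is_max <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || P[i] >= P[i - 1]
    right_ok <- i == n || P[i] >= P[i + 1]
    strict <- (i > 1 && P[i] > P[i - 1]) || (i < n && P[i] > P[i + 1]) || n == 1
    left_ok && right_ok && strict
  }, logical(1))
  maxima <- prof$T[is_max]
  T_star <- prof$T[which.max(P)]
  if (length(maxima) > 1) {
    warning(sprintf(
      "productivity-vs-T profile is not unimodal; local maxima at T = %s (using global maximum T* = %.4g)",
      paste(signif(maxima, 4), collapse = ", "), T_star))
  }
  map$region <- ifelse(map$T < T_star, "proportionality",
                       ifelse(map$T > T_star, "trade-off", "optimum"))
  list(T_star = T_star, map = map)
}

#' Extract the titer--productivity Pareto front
#'
#' Returns the non-dominated set (no other record has both a higher titer
#' and a higher productivity) of the selected records, sorted by
#' increasing titer with strictly decreasing productivity.
#'
#' @param map a [sweep_solution_space()] result, optionally carrying the
#'   `region` column from [classify_regions()].
#' @param region restrict to this region label when the column is present
#'   (default `"trade-off"`; use `NULL` for all records).
#' @return data frame of front points (`titer`, `productivity`, plus the
#'   originating `T`, `mu_lb`, `objective`, `t_s1_frac`); empty when no
#'   candidate records exist.
#' @export
extract_pareto_front <- function(map, region = "trade-off") {
  d <- as.data.frame(map)
  if (!is.null(region) && "region" %in% names(d)) {
    d <- d[d$region %in% c(region, "optimum"), , drop = FALSE]
  }
  d <- d[is.finite(d$titer) & is.finite(d$productivity), , drop = FALSE]
  if (!nrow(d)) return(d)
  d <- d[order(-d$titer, -d$productivity), ]
  keep <- logical(nrow(d))
  best_p <- -Inf
  for (i in seq_len(nrow(d))) {
    if (d$productivity[i] > best_p + 1e-12) {
      keep[i] <- TRUE
      best_p <- d$productivity[i]
    }
  }
  front <- d[keep, , drop = FALSE]
  front <- front[order(front$titer), , drop = FALSE]
  rownames(front) <- NULL
  front
}

#' Quadratic fit of the Pareto front
#'
#' Least-squares fit of `productivity = a * titer^2 + b * titer + c` to
#' the front points, as a compact summary of the trade-off boundary.
#'
#' @param front a data frame with `titer` and `productivity` columns
#'   (>= 4 rows), e.g. from [extract_pareto_front()].
#' @return list with coefficients `a`, `b`, `c`, the `r_squared` of the
#'   fit on the front points, and the `lm` fit object.
#' @export
fit_pareto_quadratic <- function(front) {
  if (nrow(front) < 4) {
    stop_insufficient_data("need at least 4 front points for a quadratic fit")
  }
  fit <- lm(productivity ~ I(titer^2) + titer, data = front)
  co <- coef(fit)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((front$productivity - mean(front$productivity))^2)
  list(a = unname(co["I(titer^2)"]), b = unname(co["titer"]),
       c = unname(co["(Intercept)"]),
       r_squared = 1 - ss_res / ss_tot, fit = fit)
}
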