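# Design-space sweeps in these tests use coarse grids; the full-resolution
# structural claims are exercised in test-acceptance.R.

make_map <- function(T, P, titer = NULL, mu_lb = 0.005) {
  d <- data.frame(T = T, mu_lb = mu_lb, objective = "productivity",
                  titer = if (is.null(titer)) P * T else titer,
                  productivity = P, yield = NA, Gcon = NA,
                  t_s1 = NA, t_s1_frac = NA, glucose_consumed = NA,
                  status = "optimal")
  class(d) <- c("solution_space_map", "data.frame")
  d
}

test_that("sweep produces one complete record per grid point and objective", {
  g <- sweep_grid(T_values = c(15, 25), mu_lb_values = c(0.005, 0.03))
  map <- sweep_solution_space(g, fixture_pe())
  expect_equal(nrow(map), 2 * 2 * 2)
  expect_true(all(map$status == "optimal"))
  expect_true(all(is.finite(map$titer)))
  ## records flagged as glucose-consuming really are
  expect_true(all(map$Gcon[map$glucose_consumed] >= 0.999 * g$Gmax))
  ## deterministic rerun
  map2 <- sweep_solution_space(g, fixture_pe())
  expect_equal(map$titer, map2$titer, tolerance = 1e-9)
})

test_that("lowering the minimal growth rate never hurts either objective", {
  g <- sweep_grid(T_values = c(16, 24, 40), mu_lb_values = c(0.005, 0.04))
  map <- sweep_solution_space(g, fixture_pe())
  for (Ti in g$T_values) {
    for (obj in c("titer", "productivity")) {
      sub <- map[map$T == Ti & map$objective == obj, ]
      lo <- sub[sub$mu_lb == 0.005, ]; hi <- sub[sub$mu_lb == 0.04, ]
      metric <- if (obj == "titer") "titer" else "productivity"
      expect_gte(lo[[metric]], hi[[metric]] * (1 - 1e-9))
    }
  }
})

test_that("region classification finds the productivity peak and labels both sides", {
  ## boundary case: monotone increasing profile -> T* at the grid end
  m1 <- make_map(T = c(4, 6, 8, 10), P = c(1, 2, 3, 4))
  c1 <- classify_regions(m1)
  expect_equal(c1$T_star, 10)
  expect_true(all(c1$map$region %in% c("proportionality", "optimum")))
  ## interior peak
  m2 <- make_map(T = c(4, 6, 8, 10, 12), P = c(1, 2, 3, 2.5, 2))
  c2 <- classify_regions(m2)
  expect_equal(c2$T_star, 8)
  expect_equal(c2$map$region,
               c("proportionality", "proportionality", "optimum",
                 "trade-off", "trade-off"))
  ## non-unimodal profile warns and reports all local maxima
  m3 <- make_map(T = c(4, 6, 8, 10, 12), P = c(1, 3, 2, 3.5, 1))
  expect_warning(c3 <- classify_regions(m3), "not unimodal")
  expect_equal(c3$T_star, 10)
  expect_error(classify_regions(make_map(T = c(4, 6, 8), P = 1:3)),
               class = "dcfba_insufficient_data_error")
})

test_that("pareto front extraction returns exactly the non-dominated set", {
  ## two mutually dominating points: singleton front
  m <- make_map(T = c(10, 12), P = c(2, 1), titer = c(30, 20))
  f <- extract_pareto_front(m, region = NULL)
  expect_equal(nrow(f), 1)
  expect_equal(f$titer, 30)
  ## randomized records vs a brute-force O(n^2) dominance oracle
  set.seed(7)
  n <- 40
  mr <- make_map(T = seq_len(n), P = runif(n, 0.5, 3),
                 titer = runif(n, 20, 70))
  fr <- extract_pareto_front(mr, region = NULL)
  dominated <- function(i, d) any(d$titer > d$titer[i] + 1e-12 &
                                    d$productivity > d$productivity[i] + 1e-12)
  brute <- mr[!vapply(seq_len(n), dominated, logical(1), d = mr), ]
  expect_setequal(round(fr$titer, 10), round(brute$titer, 10))
  ## ordering contract
  expect_true(all(diff(fr$titer) > 0))
  expect_true(all(diff(fr$productivity) < 0))
})

test_that("quadratic front fit recovers exact coefficients and rejects tiny inputs", {
  x <- c(20, 30, 40, 50, 60)
  front <- data.frame(titer = x, productivity = -0.003 * x^2 + 0.26 * x - 3)
  fq <- fit_pareto_quadratic(front)
  expect_equal(fq$a, -0.003, tolerance = 1e-9)
  expect_equal(fq$b, 0.26, tolerance = 1e-9)
  expect_equal(fq$c, -3, tolerance = 1e-9)
  expect_equal(fq$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_pareto_quadratic(front[1:3, ]),
               class = "dcfba_insufficient_data_error")
})

test_that("grid validation rejects malformed sweeps", {
  expect_error(sweep_grid(T_values = c(10)), class = "dcfba_config_error")
  expect_error(sweep_grid(T_values = c(10, 10)), class = "dcfba_config_error")
  expect_error(sweep_grid(mu_lb_values = c(0.05, 0.01)),
               class = "dcfba_config_error")
})
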