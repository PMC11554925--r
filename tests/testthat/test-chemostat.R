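test_that("steady-state residuals vanish for null and washout states", {
  rates0 <- data.frame(mu = c(0, 0), alpha = c(0, 0), beta = c(0, 0),
                       gamma = c(0, 0))
  s0 <- data.frame(A = c(0, 0), B = c(0, 0), X = c(0, 0), G = c(0, 0))
  d0 <- chemostat_design(0, 0, rates0, s0)
  expect_equal(unname(steady_state_residual(d0)), rep(0, 8))
  ## washout: no biomass, glucose passes through at the feed concentration
  rates <- data.frame(mu = c(0.3, 0.1), alpha = c(0.1, -0.1),
                      beta = c(0.05, 0.2), gamma = c(-1.5, -0.3))
  sw <- data.frame(A = c(0, 0), B = c(0, 0), X = c(0, 0), G = c(50, 50))
  dw <- chemostat_design(0.25, 50, rates, sw)
  expect_equal(unname(steady_state_residual(dw)), rep(0, 8))
})

test_that("optimized design is aerobic-then-microaerobic and exactly steady", {
  pe <- fixture_pe()
  d <- optimize_chemostat(pe, "productivity", seed = 1)
  ## structure: reactor 1 on the aerobic side, reactor 2 microaerobic
  expect_gt(d$rates$mu[1], (pe$mu_min + pe$mu_max) / 2)
  expect_lt(d$rates$mu[2], pe$mu_min + 0.1 * (pe$mu_max - pe$mu_min))
  expect_equal(d$phi, d$rates$mu[1])       # non-washout steady state
  expect_lt(max(abs(steady_state_residual(d))), 1e-8)
  ## complete glucose consumption in reactor 2
  expect_lt(d$states$G[2], 1e-6)
  expect_true(all(unlist(d$states) >= -1e-9))
  ## biomass cap respected
  expect_lte(max(d$states$X), 25 * (1 + 1e-7))
})

test_that("optimized productivity dominates a seeded random feasible sample", {
  pe <- fixture_pe()
  d <- optimize_chemostat(pe, "productivity", seed = 1)
  set.seed(99)
  best_random <- -Inf
  tried <- 0L
  while (tried < 100L) {
    mu1 <- runif(1, pe$mu_min + 1e-3, pe$mu_max)
    mu2 <- runif(1, pe$mu_min, mu1 * 0.99)
    a1 <- runif(1, max(0, rates_at(pe, mu1)$min_alpha), 0.2)
    a2 <- runif(1, rates_at(pe, mu2)$min_alpha, 0.2)
    X1 <- runif(1, 0.1, 25)
    cf <- dcfba:::chemostat_closed_form(pe, mu1, mu2, a1, a2, X1)
    if (is.null(cf)) next
    tried <- tried + 1L
    ok <- all(unlist(cf$states) >= 0) && max(cf$states$X) <= 25 &&
      cf$G_feed <= 600
    if (ok) best_random <- max(best_random, cf$phi * cf$states$B[2])
  }
  expect_gt(best_random, 0)                  # the sampler did find designs
  expect_gte(d$metrics$productivity, best_random)
})

test_that("titer-optimized design reaches at least the productivity design's titer", {
  pe <- fixture_pe()
  dp <- optimize_chemostat(pe, "productivity", seed = 1)
  dt <- optimize_chemostat(pe, "titer", seed = 1)
  expect_gte(dt$metrics$titer, dp$metrics$titer * (1 - 1e-6))
  ## infeasible titer floor
  expect_error(optimize_chemostat(pe, "productivity", titer_floor = 1e3),
               class = "dcfba_infeasible_error")
})

test_that("chemostat metrics are consistent and stoichiometrically sane", {
  rates <- data.frame(mu = c(0.1, 0.05), alpha = c(0.1, -0.05),
                      beta = c(0.02, 0.1), gamma = c(-0.5, -0.3))
  st <- data.frame(A = c(1, 0.5), B = c(10, 50), X = c(5, 8), G = c(2, 0))
  d <- chemostat_design(0.1, 120, rates, st)
  expect_equal(d$metrics$productivity, 0.1 * 50)
  expect_equal(d$metrics$productivity_total_volume, 0.1 * 50 / 2)
  expect_equal(d$metrics$yield, 50 / 120)
  ## optimized design yield below the strain's stoichiometric ceiling
  net <- builtin_network()
  free <- set_bounds(net, "ATPM", lower = 0)
  free <- fix_flux(free, "BIOMASS", 0)
  free <- fix_flux(free, "EX_glc", -10)
  ymax <- fba_optimize(free, objective = "EX_btd")$objective *
    molar_masses[["butanediol"]] / (10 * molar_masses[["glucose"]])
  pe <- fixture_pe()
  dopt <- optimize_chemostat(pe, "productivity", seed = 1)
  expect_lte(dopt$metrics$yield, ymax + 1e-6)
})

test_that("dynamic start-up converges to the optimized steady state", {
  pe <- fixture_pe()
  d <- optimize_chemostat(pe, "productivity", seed = 1)
  ss <- with(d$states, c(A[1], B[1], X[1], G[1], A[2], B[2], X[2], G[2]))
  ## fixed point: start at the steady state, stay there
  tr0 <- integrate_two_reactor(d, t_end = 5 / d$phi,
                               init = setNames(ss, c("A1", "B1", "X1", "G1",
                                                     "A2", "B2", "X2", "G2")))
  dev0 <- max(abs(unlist(tr0[nrow(tr0), -1]) - ss)) / max(ss)
  expect_lt(dev0, 1e-6)
  ## start-up initial condition: X1 at steady state, everything else 0
  tr <- integrate_two_reactor(d, t_end = 20 / d$phi)
  fin <- unlist(tr[nrow(tr), -1])
  expect_lt(max(abs(fin - ss)) / max(ss), 0.01)
  ## residual trace decreases towards the fixed point
  mid <- unlist(tr[ceiling(nrow(tr) / 2), -1])
  expect_lt(max(abs(fin - ss)), max(abs(mid - ss)) + 1e-12)
})

test_that("phi = 0 with biomass behaves batch-like and flags glucose depletion", {
  rates <- data.frame(mu = c(0.3, 0.005), alpha = c(0.2, -0.1),
                      beta = c(0.05, 0.2), gamma = c(-1.9, -0.28))
  st <- data.frame(A = c(0, 0), B = c(0, 0), X = c(1, 0), G = c(5, 0))
  d <- chemostat_design(0, 10, rates, st)
  expect_warning(tr <- integrate_two_reactor(d, t_end = 20,
                                             init = c(A1 = 0, B1 = 0, X1 = 1,
                                                      G1 = 5, A2 = 0, B2 = 0,
                                                      X2 = 0, G2 = 0)),
                 "glucose")
  expect_gt(tail(tr$X1, 1), 1)               # unwashed biomass grows
  expect_lt(tail(tr$G1, 1), 0)               # depletion overshoots zero
})
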