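test_that("rate fitting inverts noise-free piecewise-exponential data exactly", {
  pe <- fixture_pe()
  ts <- generate_timeseries(pe, generator_config(noise_cv = 0))
  fa <- fit_condition_rates(ts, "aerobic")
  fm <- fit_condition_rates(ts, "microaerobic")
  a <- pe$aerobic; m <- pe$microaerobic
  expect_equal(fa$mu, a$mu, tolerance = 1e-6)
  expect_equal(fa$gamma, a$gamma, tolerance = 1e-6)
  expect_equal(fa$alpha, a$alpha, tolerance = 1e-6)
  expect_equal(fa$beta, a$beta, tolerance = 1e-6)
  expect_equal(fm$mu, m$mu, tolerance = 1e-6)
  expect_equal(fm$gamma, m$gamma, tolerance = 1e-6)
  expect_equal(fm$alpha, m$alpha, tolerance = 1e-6)   # re-uptake window
  expect_equal(fm$beta, m$beta, tolerance = 1e-6)
  expect_equal(fm$delta, m$delta, tolerance = 1e-6)   # delta = alpha + beta
})

test_that("rate fitting stays within 5% under 2% multiplicative noise", {
  pe <- fixture_pe()
  ts <- generate_timeseries(pe, generator_config(noise_cv = 0.02, seed = 42))
  fa <- fit_condition_rates(ts, "aerobic")
  fm <- fit_condition_rates(ts, "microaerobic")
  rel <- function(est, true) abs(est - true) / abs(true)
  expect_lt(rel(fa$mu, pe$aerobic$mu), 0.05)
  expect_lt(rel(fa$gamma, pe$aerobic$gamma), 0.05)
  expect_lt(rel(fa$alpha, pe$aerobic$alpha), 0.05)
  expect_lt(rel(fm$mu, pe$microaerobic$mu), 0.05)
  expect_lt(rel(fm$gamma, pe$microaerobic$gamma), 0.05)
  expect_lt(rel(fm$alpha, pe$microaerobic$alpha), 0.05)
  ## standard errors are finite and small relative to the estimates
  expect_true(all(is.finite(fa$se)))
})

test_that("rate fitting validates its inputs", {
  pe <- fixture_pe()
  ts <- generate_timeseries(pe, generator_config(noise_cv = 0))
  expect_error(fit_condition_rates(ts, "aerobic", window = c(2, 2.5)),
               class = "dcfba_insufficient_data_error")
  bad <- ts; bad$biomass_gDW_L[bad$condition == "aerobic"][2] <- 0
  expect_error(fit_condition_rates(bad, "aerobic"),
               class = "dcfba_data_error")
  expect_error(fit_condition_rates(ts[, -2], "aerobic"),
               class = "dcfba_data_error")
})

test_that("envelope interpolation is affine with exact anchors", {
  pe <- fixture_pe()
  a <- pe$aerobic; m <- pe$microaerobic
  ## endpoints reproduce the anchors exactly
  r_a <- rates_at(pe, a$mu)
  expect_equal(r_a$gamma, a$gamma)
  expect_equal(r_a$delta, a$delta)
  expect_equal(r_a$min_alpha, a$alpha)
  r_m <- rates_at(pe, m$mu)
  expect_equal(r_m$gamma, m$gamma)
  expect_equal(r_m$min_alpha, m$alpha)
  ## midpoint is the componentwise anchor mean
  mid <- (a$mu + m$mu) / 2
  r_mid <- rates_at(pe, mid)
  expect_equal(r_mid$gamma, (a$gamma + m$gamma) / 2)
  expect_equal(r_mid$delta, (a$delta + m$delta) / 2)
  expect_equal(r_mid$min_alpha, (a$alpha + m$alpha) / 2)
  ## beta_max decomposition
  expect_equal(r_mid$beta_max, r_mid$delta - r_mid$min_alpha)
  ## second finite difference of an affine map vanishes
  mus <- seq(m$mu, a$mu, length.out = 9)
  g <- rates_at(pe, mus)$gamma
  expect_lt(max(abs(diff(diff(g)))), 1e-12)
  ## gamma increases towards 0 as mu decreases, matching the anchor order
  expect_gt(m$gamma, a$gamma)
  expect_true(all(diff(g) < 0))
})

test_that("envelope construction and evaluation reject invalid input", {
  pe <- fixture_pe()
  a <- pe$aerobic
  expect_error(build_envelope(a, a), class = "dcfba_domain_error")
  expect_error(rates_at(pe, pe$mu_max + 1e-3), class = "dcfba_domain_error")
  expect_error(rates_at(pe, pe$mu_min - 1e-3), class = "dcfba_domain_error")
})

test_that("envelope verification reports infeasible points instead of raising", {
  net <- builtin_network()
  pe <- fixture_pe()
  ok <- verify_envelope(pe, net, n_samples = 11)
  expect_true(all(ok$feasible))
  ## single-point report sits at the microaerobic end
  one <- verify_envelope(pe, net, n_samples = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$mu, pe$mu_min)
  ## a diol rate above the stoichiometric yield ceiling must be flagged
  a <- pe$aerobic; m <- pe$microaerobic
  hot <- build_envelope(
    condition_rates("aerobic", a$mu, a$gamma, a$alpha, a$beta + 5 * a$delta),
    condition_rates("microaerobic", m$mu, m$gamma, m$alpha, m$beta + 5 * m$delta))
  bad <- verify_envelope(hot, net, n_samples = 11)
  expect_true(any(!bad$feasible))
})

test_that("envelope JSON serialization round-trips", {
  pe <- fixture_pe()
  path <- tempfile(fileext = ".json")
  write_envelope(pe, path)
  pe2 <- read_envelope(path)
  expect_equal(pe2$gamma_co, pe$gamma_co)
  expect_equal(pe2$delta_co, pe$delta_co)
  expect_equal(pe2$min_alpha_co, pe$min_alpha_co)
  expect_equal(rates_at(pe2, 0.3), rates_at(pe, 0.3))
})
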