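test_that("single-stage closed form matches the oracle at a forced switch", {
  pe <- fixture_pe()
  ## switch forced to T: one aerobic stage; closed-form titer, with the
  ## aerobic phase truncated when the glucose cap is reached
  prob <- fixture_problem(t_final = 6, objective = "titer", Gmax = 1e4)
  sim <- dcfba:::two_stage_sim(prob, prob$t_final)
  a <- pe$aerobic
  beta_a <- a$delta - a$alpha
  expect_equal(sim$final[["B"]],
               (beta_a / a$mu) * prob$X0 * (exp(a$mu * 6) - 1),
               tolerance = 1e-10)
  ## with a binding cap the process freezes at the cap time
  prob2 <- fixture_problem(t_final = 6, objective = "titer", Gmax = 10)
  sim2 <- dcfba:::two_stage_sim(prob2, 6)
  expect_equal(sim2$final[["G"]], 10, tolerance = 1e-9)
  t_cap <- log1p(10 * a$mu / (-a$gamma * prob2$X0)) / a$mu
  expect_equal(sim2$final[["B"]],
               (beta_a / a$mu) * prob2$X0 * (exp(a$mu * t_cap) - 1),
               tolerance = 1e-9)
})

test_that("oracle metric agrees with a fine-step forward Euler replay", {
  prob <- fixture_problem(t_final = 20, objective = "productivity")
  o <- two_stage_oracle(prob)
  eu <- euler_replay(o$segments, prob$X0, dt = 1e-4)
  expect_equal(eu[["B"]], o$metrics$titer, tolerance = 1e-3)
  expect_equal(eu[["G"]], o$metrics$glucose_consumed, tolerance = 1e-3)
})

test_that("productivity-optimal switch aligns acetoin depletion with glucose exhaustion", {
  prob <- fixture_problem(t_final = 20, objective = "productivity")
  o <- two_stage_oracle(prob)
  ## at the optimum: everything converted, all glucose used
  expect_lt(o$metrics$acetoin_final, 1e-3)
  expect_gt(o$metrics$glucose_consumed, 0.999 * prob$Gmax)
  ## the last active segment ends at T: depletion time = exhaustion time
  act <- o$segments[!o$segments$frozen, ]
  expect_equal(max(act$t1), prob$t_final, tolerance = prob$t_final / 200)
})

test_that("collocation NLP dimensions and fixed-control reduction are exact", {
  prob <- fixture_problem(t_final = 24, nFE = 12)
  nlp <- build_collocation_nlp(prob)
  expect_equal(nlp$n_decision, 12 * (4 * (3 + 1) + 2 + 1))
  ## degree 1, one element, mu pinned: the NLP is an implicit-Euler step
  pe <- fixture_pe()
  probf <- fedbatch_problem(pe, t_final = 0.5, Gmax = 1e3, mu_lb = 0.4,
                            mu_ub = 0.4, X0 = 0.25, nFE = 1, degree = 1)
  nlpf <- build_collocation_nlp(probf)
  r <- rates_at(pe, 0.4)
  z <- c(0.4, r$min_alpha, 0.5)
  sol <- nlpf$eval_solution(z)
  x1 <- 0.25 / (1 - 0.5 * 0.4)
  expect_equal(sol$states$ends[1, 1], x1, tolerance = 1e-12)
  expect_equal(sol$titer, 0.5 * (r$delta - r$min_alpha) * x1,
               tolerance = 1e-12)
  ## the full collocation residual vanishes at reduced-space solutions
  expect_lt(max(abs(nlpf$residuals(z))), 1e-10)
})

test_that("NLP solution matches the two-stage oracle and satisfies all constraints", {
  prob <- fixture_problem(t_final = 24, objective = "productivity", nFE = 12)
  s <- solve_fedbatch(prob, n_starts = 1, inner = 20, outer = 2)
  o <- s$oracle
  expect_gt(s$metric, o$objective_value * 0.99)
  ## refined oracle upper bound
  o_fine <- two_stage_oracle(prob, n_grid = 2001, refine = 2)
  expect_lt(s$metric, o_fine$objective_value * 1.01)
  ## trajectory invariants
  tr <- s$trajectory
  expect_true(all(tr$X >= -1e-8 & tr$B >= -1e-8 & tr$A >= -1e-8))
  expect_true(all(diff(tr$Gcon) >= -1e-8))
  expect_lte(max(tr$Gcon), prob$Gmax * (1 + 1e-6))
  expect_true(all(diff(tr$time_h) > 0))
  ## element lengths sum to T; collocation residuals vanish
  expect_equal(sum(s$profile$h), prob$t_final, tolerance = 1e-9)
  z <- c(s$profile$mu, s$profile$alpha, s$profile$h)
  expect_lt(max(abs(s$nlp$residuals(z))), 1e-8)
  ## the optimal profile is two-stage: at most 2 growth-rate clusters
  ## (values distinct beyond 1e-3)
  mu_sorted <- sort(s$profile$mu)
  expect_lte(1 + sum(diff(mu_sorted) > 1e-3), 2)
  ## productivity-optimal run converts everything
  expect_lt(s$metrics$acetoin_final, 1e-3 * max(1, s$titer))
  expect_gt(s$metrics$glucose_consumed, prob$Gmax * (1 - 2e-3))
  ## reported metrics equal an independent recomputation on the trajectory
  expect_equal(s$metrics$productivity, s$titer / prob$t_final,
               tolerance = 1e-9)
})

test_that("relaxing the glucose cap never hurts and refining the grid barely moves the optimum", {
  pe <- fixture_pe()
  for (Tf in c(18, 30)) {
    p1 <- fedbatch_problem(pe, Tf, Gmax = 200, objective = "titer")
    p2 <- fedbatch_problem(pe, Tf, Gmax = 220, objective = "titer")
    o1 <- two_stage_oracle(p1); o2 <- two_stage_oracle(p2)
    expect_gte(o2$objective_value, o1$objective_value * (1 - 1e-9))
  }
  prob8 <- fixture_problem(t_final = 24, nFE = 8)
  prob16 <- fixture_problem(t_final = 24, nFE = 16)
  s8 <- solve_fedbatch(prob8, n_starts = 1, inner = 15, outer = 1)
  s16 <- solve_fedbatch(prob16, n_starts = 1, inner = 15, outer = 1)
  expect_lt(abs(s8$metric - s16$metric) / s16$metric, 0.005)
})

test_that("piecewise simulation handles events and rejects out-of-domain controls", {
  pe <- fixture_pe()
  ## constant microaerobic profile with acetoin uptake from a zero stock:
  ## the A >= 0 event must clamp alpha immediately
  prof <- data.frame(mu = pe$mu_min, alpha = pe$microaerobic$alpha, h = 5)
  tr <- simulate_piecewise(pe, prof, X0 = 1)
  expect_true(all(tr$A >= -1e-9))
  expect_true(all(diff(tr$B) >= 0))
  ## two-stage profile: acetoin crosses zero exactly once, stays at 0
  prob <- fixture_problem(t_final = 20, objective = "productivity")
  o <- two_stage_oracle(prob)
  act <- o$segments[!o$segments$frozen, ]
  prof2 <- data.frame(mu = act$mu, alpha = act$alpha, h = act$t1 - act$t0)
  tr2 <- simulate_piecewise(pe, prof2, X0 = prob$X0, Gmax = prob$Gmax)
  expect_true(all(tr2$A >= -1e-9))
  expect_equal(tail(tr2$B, 1), o$metrics$titer, tolerance = 1e-6)
  sign_changes <- sum(diff(tr2$A > 1e-9) != 0)
  expect_lte(sign_changes, 2)   # up once, down once
  ## domain violations
  expect_error(simulate_piecewise(pe, data.frame(mu = 0.9, alpha = 0, h = 1), 1),
               class = "dcfba_domain_error")
  expect_error(
    simulate_piecewise(pe, data.frame(mu = 0.5, alpha = -0.2, h = 1), 1),
    class = "dcfba_domain_error")
})

test_that("zero-rate control keeps all states constant", {
  pe0 <- build_envelope(
    condition_rates("aerobic", 0.6, -1, 0, 0),
    condition_rates("microaerobic", 0, 0, 0, 0))
  prof <- data.frame(mu = 0, alpha = 0, h = 3)
  tr <- simulate_piecewise(pe0, prof, X0 = 2)
  expect_equal(unique(tr$X), 2)
  expect_equal(max(abs(tr$B)), 0)
})

test_that("objective weighting is linear with the documented defaults", {
  m <- compute_metrics(B = 50, A = 0, Gcon = 150, X = 10, t_total = 25)
  ## psi1 = 1, F1 = titer: F = titer + 0.1 * P
  expect_equal(eval_objective(m, objective = "titer"), 50 + 0.1 * 2)
  expect_equal(eval_objective(m, psi = c(1, 0, 0), objective = "titer"), 50)
  f1 <- eval_objective(m, psi = c(1, 10, 0.1), objective = "productivity", F2 = 0.3)
  f2 <- eval_objective(m, psi = 2 * c(1, 10, 0.1), objective = "productivity", F2 = 0.3)
  expect_equal(f2, 2 * f1)
  ## default productivity weights: psi1 = 10
  expect_equal(eval_objective(m, objective = "productivity"), 10 * 2 + 0.1 * 2)
})

test_that("an impossible glucose cap is reported as infeasible", {
  prob <- fixture_problem(t_final = 24, Gmax = 1e-3)
  expect_error(solve_fedbatch(prob, n_starts = 1, inner = 5, outer = 1),
               class = "dcfba_infeasible_error")
})
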