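# Core model: right-hand side, closed-form and numerical engines, steady
# state, and the structural invariants of the linear delay system.

test_that("model_rhs implements the four-process kinetics", {
  p <- sflt_params(k_prod = 1000, tau = 0, k_out_Si = 0.5, k_deg_Si = 0.5,
                   k_deg_Sx = 0.2)
  # empty system with production off is stationary
  expect_equal(unname(model_rhs(p, c(0, 0), u = 0)), c(0, 0))
  # pure production
  expect_equal(model_rhs(p, c(0, 0), u = 1)[["dS_i"]], 1000)
  # algebra of the stated form
  p2 <- sflt_params(k_prod = 0, tau = 0, k_out_Si = 0.5, k_deg_Si = 0.5,
                    k_deg_Sx = 0.1)
  d <- model_rhs(p2, c(100, 30), u = 1)
  expect_equal(d[["dS_i"]], -100)
  expect_equal(d[["dS_x"]], 50 - 0.1 * 30)
})

test_that("model_rhs rejects invalid states and gates", {
  p <- base_params()
  expect_error(model_rhs(p, c(-1, 0), u = 1), "negative")
  expect_error(model_rhs(p, c(0, 0), u = 2), "gate")
})

test_that("parameter validation enforces non-negativity and completeness", {
  expect_error(sflt_params(-1, 0, 1, 1, 1), ">= 0")
  expect_error(sflt_params(1, 0, NA, 1, 1), "finite")
  expect_error(do.call(sflt_params, list(k_prod = 1, tau = 0, k_out_Si = 1,
                                         k_deg_Si = 1)), "k_deg_Sx")
})

test_that("no-production decay follows the closed form", {
  # k_prod = 0, S_i(0) = S0: S_i decays mono-exponentially and S_x collects
  # the secreted fraction phi of what leaves the cell
  S0 <- 1234
  p <- sflt_params(k_prod = 0, tau = 0, k_out_Si = 0.7, k_deg_Si = 0.3,
                   k_deg_Sx = 0)
  tt <- c(0, 0.5, 1, 2, 5, 10)
  tr <- closed_form_solution(p, tt, S_i0 = S0, S_x0 = 0, u = 0)
  a <- 1.0
  phi <- 0.7
  expect_equal(tr$S_i, S0 * exp(-a * tt), tolerance = 1e-12)
  expect_equal(tr$S_x, S0 * phi * (1 - exp(-a * tt)), tolerance = 1e-12)
})

test_that("synthesis onset matches the analytic saturating exponential", {
  # independently derived: with delay tau and constant production from t = 0,
  # S_i(t) = (k_prod/a) (1 - e^{-a (t - tau)}) for t >= tau
  p <- sflt_params(k_prod = 1000, tau = 0.5, k_out_Si = 0.5, k_deg_Si = 0.5,
                   k_deg_Sx = 0.1)
  tr <- simulate_secretion(p, onset_protocol(4, sample_times = c(0, 1, 2, 4)))
  expect_equal(tr$S_i[3], 1000 * (1 - exp(-1.5)), tolerance = 1e-10)
  expect_equal(tr$S_i[1], 0)
})

test_that("ballistic accumulation when nothing degrades or secretes", {
  p <- sflt_params(k_prod = 500, tau = 0, k_out_Si = 0, k_deg_Si = 0,
                   k_deg_Sx = 0)
  tr <- simulate_secretion(p, onset_protocol(10, sample_times = c(0, 1, 5, 10)))
  expect_equal(tr$S_i, 500 * c(0, 1, 5, 10), tolerance = 1e-12)
  expect_equal(tr$S_x, rep(0, 4))
})

test_that("zero-length segment returns the initial condition unchanged", {
  p <- base_params()
  tr <- closed_form_solution(p, times = 0, S_i0 = 42, S_x0 = 17, u = 1)
  expect_equal(tr$S_i, 42)
  expect_equal(tr$S_x, 17)
})

test_that("degenerate double root (k_out_Si + k_deg_Si == k_deg_Sx) is finite", {
  p <- sflt_params(k_prod = 1000, tau = 0, k_out_Si = 0.6, k_deg_Si = 0.4,
                   k_deg_Sx = 1.0)
  tt <- seq(0, 24, length.out = 49)
  tr <- closed_form_solution(p, tt, S_i0 = 100, S_x0 = 50, u = 1)
  expect_true(all(is.finite(tr$S_x)))
  # cross-check against the numerical engine at the resonant point
  proto <- sflt_protocol(kind = "onset", horizon = 24, history = "zero",
                         production_schedule = data.frame(time = 0, value = 1),
                         sample_times = tt)
  tra <- simulate_secretion(p, proto, engine = "analytic")
  tro <- simulate_secretion(p, proto, engine = "ode")
  expect_lt(max_rel_discrepancy(tra, tro), 1e-6)
})

test_that("analytic and numerical engines agree across random parameter sets", {
  set.seed(101)
  worst <- 0
  for (i in 1:30) {
    p <- draw_params()
    proto <- onset_protocol(48)
    tra <- simulate_secretion(p, proto, engine = "analytic")
    tro <- simulate_secretion(p, proto, engine = "ode")
    worst <- max(worst, max_rel_discrepancy(tra, tro))
    expect_true(all(as.matrix(tibble::as_tibble(tra)) >= -1e-9))
  }
  expect_lt(worst, 1e-6)
})

test_that("mass balance holds to solver tolerance on random simulations", {
  set.seed(202)
  for (i in 1:25) {
    p <- draw_params()
    tr <- simulate_secretion(p, onset_protocol(48))
    expect_lt(mass_balance_error(tr), 1e-6)
  }
  # and on a protocol with steady-state history and a media change
  tr2 <- run_accumulation(base_params(), sample_times = seq(0, 24, by = 2))
  expect_lt(mass_balance_error(tr2), 1e-6)
})

test_that("steady state algebra and convergence", {
  ss <- steady_state(sflt_params(60000, 0.5, 1, 1, 0.1))
  expect_equal(ss$S_i_star, 30000)
  expect_equal(ss$secretion_flux_star, 30000)
  expect_equal(ss$fraction_secreted, 0.5)
  expect_equal(steady_state(sflt_params(1, 0, 1, 0, 0))$fraction_secreted, 1)
  expect_equal(steady_state(sflt_params(1, 0, 1, 3, 0))$fraction_secreted, 0.25)
  expect_error(steady_state(sflt_params(1, 0, 0, 0, 1)), "steady state")

  # long-time convergence from an empty system
  set.seed(303)
  for (i in 1:5) {
    p <- draw_params(rate_lo = 0.05, rate_hi = 2)
    a <- p$k_out_Si + p$k_deg_Si
    Tc <- 10 / a + p$tau
    tr <- simulate_secretion(p, onset_protocol(Tc, sample_times = c(0, Tc)))
    ss <- steady_state(p)
    expect_lt(abs(tr$S_i[2] - ss$S_i_star) / ss$S_i_star, 1e-3)
  }
})

test_that("trajectories are linear in k_prod", {
  set.seed(404)
  p <- draw_params()
  c_scale <- 3.7
  p2 <- sflt_params(p$k_prod * c_scale, p$tau, p$k_out_Si, p$k_deg_Si,
                    p$k_deg_Sx)
  tr1 <- simulate_secretion(p, onset_protocol(24))
  tr2 <- simulate_secretion(p2, onset_protocol(24))
  for (ch in trajectory_channels) {
    expect_equal(tr2[[ch]], c_scale * tr1[[ch]], tolerance = 1e-12)
  }
})

test_that("the delay time-shifts the zero-history trajectory", {
  p0 <- sflt_params(2000, 0, 0.4, 0.2, 0.05)
  ptau <- sflt_params(2000, 1.5, 0.4, 0.2, 0.05)
  tt <- seq(0, 20, by = 0.5)
  tr0 <- simulate_secretion(p0, onset_protocol(24, sample_times = tt))
  trt <- simulate_secretion(ptau, onset_protocol(24, sample_times = tt + 1.5))
  expect_equal(trt$S_i, tr0$S_i, tolerance = 1e-10)
  expect_equal(trt$S_x, tr0$S_x, tolerance = 1e-10)
})

test_that("simulation rejects events outside the horizon and bad grids", {
  p <- base_params()
  proto <- sflt_protocol(kind = "custom", horizon = 10, history = "steady_state",
                         media_events = c(0, 12), sample_times = c(0, 5))
  expect_error(simulate_secretion(p, proto), "horizon")
  expect_error(simulate_secretion(p, protocol_accumulation(24), times = c(-1, 5)),
               "within")
})

test_that("parameter JSON round trip preserves values and rejects unknown keys", {
  p <- base_params()
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  expect_equal(read_params(path), p)
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(k_prod = 1, tau = 0, k_out_Si = 1, k_deg_Si = 1,
                            k_deg_Sx = 0, k_extra = 9), bad, auto_unbox = TRUE)
  expect_error(read_params(bad), "k_extra")
})
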