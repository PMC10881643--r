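# Protocol runners: accumulation, pulse-chase, cell-free decay, inhibitor
# treatment, and YAML round trips.

test_that("accumulation starts from fresh media at the secretion steady state", {
  p <- base_params()
  tr <- run_accumulation(p, sample_times = seq(0, 48, by = 2))
  expect_equal(tr$S_x[1], 0)
  expect_equal(tr$S_i, rep(steady_state(p)$S_i_star, nrow(tr)),
               tolerance = 1e-12)
})

test_that("with a stable extracellular pool, media sFLT1 accumulates at the steady-state flux", {
  p <- sflt_params(k_prod = 60000, tau = 0.5, k_out_Si = 0.5, k_deg_Si = 0.5,
                   k_deg_Sx = 0)
  tt <- seq(0, 48, by = 0.5)
  tr <- run_accumulation(p, sample_times = tt)
  expect_true(all(diff(tr$S_x) >= 0))
  # finite-difference slope at 48 h vs steady-state secretion flux
  flux <- steady_state(p)$secretion_flux_star
  slope <- (tr$S_x[length(tt)] - tr$S_x[length(tt) - 1]) / 0.5
  expect_lt(abs(slope - flux) / flux, 0.01)
  # and the cumulative media content is exactly the integrated flux
  expect_equal(tr$S_x[length(tt)], flux * 48, tolerance = 1e-6)
})

test_that("pulse-chase fold changes self-normalize and ignore production scale", {
  p <- base_params()
  pc <- run_pulse_chase(p, pulse_duration = 2, sample_times = 0:8)
  expect_equal(pc$intracellular[1], 1)
  p2 <- sflt_params(2 * p$k_prod, p$tau, p$k_out_Si, p$k_deg_Si, p$k_deg_Sx)
  pc2 <- run_pulse_chase(p2, pulse_duration = 2, sample_times = 0:8)
  expect_equal(pc2$intracellular, pc$intracellular, tolerance = 1e-12)
  expect_equal(pc2$extracellular, pc$extracellular, tolerance = 1e-12)
})

test_that("labelled intracellular signal decays strictly once the label has matured", {
  set.seed(55)
  for (i in 1:10) {
    p <- draw_params(rate_lo = 0.05, rate_hi = 2, tau_hi = 1.5)
    pc <- run_pulse_chase(p, pulse_duration = 2,
                          sample_times = seq(0, 8, by = 0.5))
    after <- pc$time >= p$tau
    expect_true(all(diff(pc$intracellular[after]) < 0))
  }
})

test_that("pulse-chase errors when the label has not matured by chase start", {
  p <- sflt_params(1000, tau = 3, k_out_Si = 0.5, k_deg_Si = 0.5,
                   k_deg_Sx = 0)
  expect_error(run_pulse_chase(p, pulse_duration = 2, sample_times = 0:4),
               "normalization")
})

test_that("cell-free decay is a pure exponential in the media pool", {
  p <- sflt_params(0, 0, 0, 0, k_deg_Sx = log(2) / 72)
  tr <- run_cell_free_decay(p, S_x0 = 10, sample_times = c(0, 36, 72))
  expect_equal(tr$S_x[3], 5, tolerance = 1e-12)
  p0 <- sflt_params(0, 0, 0, 0, k_deg_Sx = 0)
  tr0 <- run_cell_free_decay(p0, S_x0 = 7, sample_times = seq(0, 72, by = 12))
  expect_equal(tr0$S_x, rep(7, 7))
  trz <- run_cell_free_decay(p, S_x0 = 0, sample_times = c(0, 24))
  expect_equal(trz$S_x, c(0, 0))
  expect_error(run_cell_free_decay(p, S_x0 = -1, sample_times = 0), ">= 0")
})

test_that("inhibitor treatment ratios behave at the endpoints and in between", {
  p <- base_params()
  expect_equal(unlist(run_inhibitor_treatment(p, "k_out_Si", 0)),
               c(R_x = 1, R_i = 1), tolerance = 1e-12)
  expect_equal(run_inhibitor_treatment(p, "k_out_Si", 1)$R_x, 0)
  # stronger secretion blockade leaves less sFLT1 in the fresh media window
  r09 <- run_inhibitor_treatment(p, "k_out_Si", 0.9)$R_x
  r06 <- run_inhibitor_treatment(p, "k_out_Si", 0.6)$R_x
  expect_lt(r09, r06)
  expect_error(run_inhibitor_treatment(p, "k_nope", 0.5), "valid names")
})

test_that("protocol YAML round trip preserves the declarative description", {
  proto <- protocol_pulse_chase(pulse_duration = 2, sample_times = 0:6)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(proto, path)
  back <- read_protocol(path)
  expect_equal(back$kind, proto$kind)
  expect_equal(back$horizon, proto$horizon)
  expect_equal(back$pulse_duration, proto$pulse_duration)
  expect_equal(back$sample_times, proto$sample_times)
  expect_equal(back$production_schedule, proto$production_schedule)
  # a protocol with inhibitions and media events survives too
  proto2 <- protocol_inhibitor_treatment("k_out_Si", 0.6, duration = 18)
  path2 <- withr::local_tempfile(fileext = ".yaml")
  write_protocol(proto2, path2)
  back2 <- read_protocol(path2)
  p <- base_params()
  expect_equal(simulate_secretion(p, back2, times = 18)$S_x,
               simulate_secretion(p, proto2, times = 18)$S_x,
               tolerance = 1e-12)
})
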