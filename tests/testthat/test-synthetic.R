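# Synthetic data generator: determinism, noise calibration, and the
# per-replicate normalization structure of densitometry-style fold changes.

test_that("zero noise reproduces the model predictions exactly", {
  p <- base_params()
  proto <- protocol_accumulation(24, sample_times = c(4, 8, 16, 24))
  ds <- generate_dataset(p, proto, noise_cv = 0, n_replicates = 3,
                         unit = "molecules_per_cell", seed = 1)
  po <- predict_observables(p, ds)
  expect_equal(po$value, po$prediction, tolerance = 1e-14)
})

test_that("generation is fully determined by the seed", {
  p <- base_params()
  proto <- protocol_pulse_chase(pulse_duration = 2, sample_times = 0:6)
  d1 <- generate_dataset(p, proto, noise_cv = 0.2, seed = 7)
  d2 <- generate_dataset(p, proto, noise_cv = 0.2, seed = 7)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_dataset(p, proto, noise_cv = 0.2, seed = 8)
  expect_false(identical(d1$value, d3$value))
})

test_that("multiplicative noise has the nominal coefficient of variation", {
  p <- base_params()
  proto <- protocol_accumulation(24, sample_times = c(6, 12, 18, 24))
  ds <- generate_dataset(p, proto, noise_cv = 0.2, n_replicates = 2500,
                         unit = "molecules_per_cell", seed = 3)
  po <- predict_observables(p, ds)
  factors <- po$value / po$prediction  # 10^4 independent lognormal draws
  expect_lt(abs(stats::sd(factors) / mean(factors) - 0.2), 0.02)
  expect_lt(abs(mean(factors) - 1), 0.01)
})

test_that("replicate means approach the noise-free curve", {
  p <- base_params()
  proto <- protocol_accumulation(24, sample_times = c(4, 8, 16, 24))
  ds <- generate_dataset(p, proto, noise_cv = 0.2, n_replicates = 200,
                         unit = "molecules_per_cell", seed = 5)
  po <- predict_observables(p, ds)
  agg <- tapply(po$value / po$prediction, po$time_h, mean)
  expect_true(all(abs(agg - 1) < 0.05))
})

test_that("fold-change replicates are unity at their own reference point", {
  p <- base_params()
  proto <- protocol_accumulation(24, sample_times = c(4, 8, 16, 24))
  ds <- generate_dataset(p, proto, noise_cv = 0.3, n_replicates = 5,
                         unit = "fold_change",
                         normalization = list(mode = "ref_time", ref_time = 24),
                         seed = 11)
  at_ref <- ds$value[ds$time_h == 24]
  expect_equal(at_ref, rep(1, 5))
  # but the reference itself carried noise, so other times scatter
  expect_gt(stats::sd(ds$value[ds$time_h == 8]), 0)
})

test_that("the fit benchmark is reproducible and well-formed", {
  b1 <- generate_fit_benchmark(13)
  b2 <- generate_fit_benchmark(13)
  expect_identical(unclass(b1$params), unclass(b2$params))
  expect_identical(as.data.frame(b1$datasets$pulse_chase),
                   as.data.frame(b2$datasets$pulse_chase))
  expect_s3_class(b1$datasets$accumulation, "sflt_dataset")
  expect_s3_class(b1$datasets$pulse_chase, "sflt_dataset")
  expect_true(all(b1$datasets$accumulation$value >= 0))
  expect_equal(unique(b1$datasets$accumulation$unit), "ng_per_ml")
  expect_length(unique(b1$datasets$pulse_chase$replicate), 3)
})
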