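# Observable prediction, the weighted objective, multi-start estimation and
# profile-likelihood uncertainty.

test_that("predictions live in the dataset's own normalization", {
  p <- base_params()
  proto <- protocol_accumulation(horizon = 24,
                                 sample_times = c(2, 6, 12, 18, 24))
  ds <- generate_dataset(p, proto, noise_cv = 0, n_replicates = 1,
                         unit = "fold_change",
                         normalization = list(mode = "ref_time", ref_time = 24),
                         seed = 1)
  po <- predict_observables(p, ds)
  expect_equal(po$prediction[po$time_h == 24], 1)
  # fold-change predictions are invariant to the production scale
  p2 <- sflt_params(3 * p$k_prod, p$tau, p$k_out_Si, p$k_deg_Si, p$k_deg_Sx)
  expect_equal(predict_observables(p2, ds)$prediction, po$prediction,
               tolerance = 1e-12)
})

test_that("noise-free generated data are reproduced exactly by the predictor", {
  bm <- generate_fit_benchmark(3, noise_cv = 0)
  for (ds in bm$datasets) {
    po <- predict_observables(bm$params, ds)
    expect_lt(max(abs(po$prediction - po$value)), 1e-8)
  }
})

test_that("objective is a weighted sum of scaled squared residuals", {
  bm <- generate_fit_benchmark(4, noise_cv = 0)
  expect_equal(objective(bm$params, bm$datasets), 0, tolerance = 1e-20)

  # a single residual of 2 sigma with unit weight contributes 4
  ds <- bm$datasets$accumulation
  rec <- tibble::as_tibble(as.data.frame(ds))
  rec$sigma <- rec$value * 0.1
  rec$value[1] <- rec$value[1] + 2 * rec$sigma[1]
  ds2 <- sflt_dataset(rec, geometry = dataset_geometry(ds),
                      protocol = dataset_protocol(ds))
  expect_equal(objective(bm$params, list(ds2), weights = 1), 4,
               tolerance = 1e-10)
  # doubling the dataset weight doubles its contribution
  expect_equal(objective(bm$params, list(ds2), weights = 2), 8,
               tolerance = 1e-10)
})

test_that("objective is invariant under record order", {
  bm <- generate_fit_benchmark(5, noise_cv = 0.2)
  ds <- bm$datasets$pulse_chase
  set.seed(9)
  shuffled <- sflt_dataset(
    tibble::as_tibble(as.data.frame(ds))[sample(nrow(ds)), ],
    normalization = dataset_normalization(ds),
    geometry = dataset_geometry(ds),
    protocol = dataset_protocol(ds)
  )
  p <- base_params()
  expect_equal(objective(p, list(ds)), objective(p, list(shuffled)),
               tolerance = 1e-12)
})

test_that("noise-free benchmark data return the generating parameters", {
  bm <- generate_fit_benchmark(11, noise_cv = 0)
  fit <- fit_secretion_model(bm$datasets, seed = 42)
  tru <- unlist(unclass(bm$params))
  est <- unlist(unclass(fit$params))
  expect_true(fit$converged)
  expect_lt(max(abs(est - tru) / tru), 0.01)
})

test_that("fitting is deterministic for a fixed seed", {
  bm <- generate_fit_benchmark(6, noise_cv = 0.2)
  f1 <- fit_secretion_model(bm$datasets, seed = 7)
  f2 <- fit_secretion_model(bm$datasets, seed = 7)
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$starts, f2$starts)
})

test_that("fold-change-only data leave the production rate unidentified", {
  bm <- generate_fit_benchmark(8, noise_cv = 0.2)
  fit_fc <- fit_secretion_model(bm$datasets["pulse_chase"], seed = 5)
  expect_true("k_prod" %in% fit_fc$non_identifiable)
  prof <- profile_likelihood(fit_fc, "k_prod")
  expect_false(attr(prof, "identifiable"))
  expect_equal(attr(prof, "ci_lower"), -Inf)

  # one absolute-concentration dataset pins the scale
  fit_both <- fit_secretion_model(bm$datasets, seed = 5)
  expect_length(fit_both$non_identifiable, 0)
  prof2 <- profile_likelihood(fit_both, "k_prod")
  expect_true(attr(prof2, "identifiable"))
  expect_true(is.finite(attr(prof2, "ci_lower")))
  expect_true(is.finite(attr(prof2, "ci_upper")))
})

test_that("profile cost equals the optimum at the fit and never dips below it", {
  bm <- generate_fit_benchmark(9, noise_cv = 0.2)
  fit <- fit_secretion_model(bm$datasets, seed = 3)
  prof <- profile_likelihood(fit, "k_out_Si")
  at_opt <- prof$profile_objective[prof$value == fit$params$k_out_Si]
  expect_equal(at_opt, fit$objective)
  expect_true(all(prof$profile_objective >= fit$objective - 1e-9))
  expect_error(profile_likelihood(fit, "k_out_Si", grid = c(1e-6, 1)),
               "bounds")
})

test_that("profile intervals for the secretion rate cover the truth", {
  study <- recovery_study(25)
  expect_gte(mean(study$covered), 0.8)
})

test_that("tidy and glance summarise fits in broom style", {
  bm <- generate_fit_benchmark(10, noise_cv = 0.2)
  fit <- fit_secretion_model(bm$datasets, seed = 2)
  td <- tidy(fit)
  expect_named(td, c("parameter", "estimate", "unit"))
  expect_equal(td$parameter, param_names())
  fit2 <- add_profiles(fit, "k_out_Si")
  td2 <- tidy(fit2)
  expect_true(all(c("conf.low", "conf.high", "identifiable") %in% names(td2)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$n_datasets, 2)
})
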