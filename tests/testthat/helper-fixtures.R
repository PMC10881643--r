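# Shared fixtures. Everything is generated in code; the expensive noisy
# recovery study is computed once per session and reused by the property and
# acceptance tests.

base_params <- function() {
  sflt_params(k_prod = 60000, tau = 0.5, k_out_Si = 0.5, k_deg_Si = 0.5,
              k_deg_Sx = 0.01)
}

draw_params <- function(rate_lo = 1e-3, rate_hi = 10, tau_hi = 4,
                        k_prod_lo = 1e2, k_prod_hi = 1e5) {
  rl <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  sflt_params(k_prod = rl(k_prod_lo, k_prod_hi),
              tau = stats::runif(1, 0, tau_hi),
              k_out_Si = rl(rate_lo, rate_hi),
              k_deg_Si = rl(rate_lo, rate_hi),
              k_deg_Sx = rl(rate_lo, rate_hi))
}

# synthesis onset from an empty system: gate turns on at t = 0
onset_protocol <- function(horizon = 48, sample_times = seq(0, horizon, length.out = 25)) {
  sflt_protocol(kind = "onset", horizon = horizon, history = "zero",
                production_schedule = data.frame(time = 0, value = 1),
                sample_times = sample_times)
}

trajectory_channels <- c("S_i", "S_x", "cum_produced", "cum_secreted",
                         "cum_deg_i", "cum_deg_x")

max_rel_discrepancy <- function(a, b) {
  worst <- 0
  for (ch in trajectory_channels) {
    sc <- max(abs(a[[ch]]), 1e-12)
    worst <- max(worst, max(abs(a[[ch]] - b[[ch]])) / sc)
  }
  worst
}

# -- cached noisy recovery study (25 seeds, CV 20%, n = 3) -------------------

.study_cache <- new.env(parent = emptyenv())

recovery_study <- function(n_seeds = 25) {
  key <- paste0("study_", n_seeds)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  rows <- lapply(seq_len(n_seeds), function(s) {
    bm <- generate_fit_benchmark(s, noise_cv = 0.2, n_replicates = 3)
    fit <- fit_secretion_model(bm$datasets, seed = s + 1000)
    prof <- profile_likelihood(fit, "k_out_Si")
    tru <- unlist(unclass(bm$params))
    est <- unlist(unclass(fit$params))
    data.frame(
      seed = s,
      t(abs(est - tru) / tru),
      covered = attr(prof, "ci_lower") <= tru[["k_out_Si"]] &&
        tru[["k_out_Si"]] <= attr(prof, "ci_upper"),
      converged = fit$converged
    )
  })
  out <- do.call(rbind, rows)
  .study_cache[[key]] <- out
  out
}
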