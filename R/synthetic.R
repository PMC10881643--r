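# Synthetic time-course generator. Emulates the statistical structure of
# densitometry-style secretion data: sparse sampling, a handful of
# replicates, multiplicative (lognormal) noise, and fold-change
# normalization computed per replicate from the noisy raw signal — noise
# first, then normalization, which is how fold changes are actually formed
# from band intensities and induces the realistic exact-1 reference point
# and correlated scatter.

#' Generate a synthetic time-course dataset
#'
#' Simulates a protocol noise-free, converts to the requested unit,
#' multiplies every raw observation by an independent lognormal factor with
#' mean 1 and coefficient of variation `noise_cv`, and then applies the
#' normalization per replicate (for fold-change data). Fully determined by
#' `seed`.
#'
#' @param params True [sflt_params()].
#' @param protocol An [sflt_protocol] (accumulation, pulse_chase or
#'   cell_free_decay).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0.2 is typical immunoblot replicate scatter).
#' @param n_replicates Number of replicates.
#' @param unit One of `"fold_change"`, `"ng_per_ml"`, `"molecules_per_cell"`.
#' @param geometry [sflt_geometry()]; required for `"ng_per_ml"`.
#' @param normalization For fold-change accumulation/cell-free data: list
#'   with `mode` (`"ref_time"` or `"max"`) and `ref_time`. Pulse-chase data
#'   use the protocol's own normalization conventions.
#' @param compartments Which compartments to observe; default depends on the
#'   protocol kind (media only for accumulation and cell-free, both for
#'   pulse-chase).
#' @param seed Integer seed.
#' @param experiment_id Identifier stored in the records.
#' @return An [sflt_dataset()].
#' @export
generate_dataset <- function(params, protocol, noise_cv = 0.2,
                             n_replicates = 3,
                             unit = c("fold_change", "ng_per_ml",
                                      "molecules_per_cell"),
                             geometry = NULL, normalization = NULL,
                             compartments = NULL, seed = 1,
                             experiment_id = NULL) {
  stopifnot(inherits(params, "sflt_params"), inherits(protocol, "sflt_protocol"))
  unit <- match.arg(unit)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (unit == "ng_per_ml" && is.null(geometry)) {
    stop("unit 'ng_per_ml' requires a geometry", call. = FALSE)
  }
  kind <- protocol$kind
  if (is.null(compartments)) {
    compartments <- switch(kind,
      pulse_chase = c("intracellular", "extracellular"),
      accumulation = "extracellular",
      cell_free_decay = "extracellular",
      stop("cannot generate data for protocol kind '", kind, "'",
           call. = FALSE))
  }
  if (kind == "cell_free_decay" && !identical(compartments, "extracellular")) {
    stop("cell-free incubations have no intracellular compartment",
         call. = FALSE)
  }
  times <- protocol$sample_times
  if (is.null(times) || length(times) == 0) {
    stop("protocol has no sample_times", call. = FALSE)
  }
  if (unit == "fold_change" && kind != "pulse_chase") {
    normalization <- normalization %||% list(mode = "ref_time",
                                             ref_time = max(times))
    if (normalization$mode == "ref_time" &&
        !any(abs(times - normalization$ref_time) < 1e-9)) {
      stop("normalization ref_time must be one of the sample times",
           call. = FALSE)
    }
  }

  grid <- tidyr::expand_grid(compartment = compartments, time_h = times)
  spec <- list(
    kind = kind, unit = unit,
    time = grid$time_h,
    comp = match(grid$compartment, c("intracellular", "extracellular")),
    value = NA_real_, scale = NA_real_, n = nrow(grid),
    norm_mode = "none", ref_time = NA_real_,
    gfactor = if (!is.null(geometry)) {
      geometry$n_cells / (AVOGADRO * geometry$media_volume_ml) *
        geometry$molecular_weight_g_per_mol * 1e9
    } else NA_real_,
    pulse_duration = protocol$pulse_duration %||% 1,
    pc_norm_i = (protocol$normalization %||% list())$intracellular %||% "chase_start",
    pc_norm_x = (protocol$normalization %||% list())$extracellular %||% "max",
    S_x0 = protocol$S_x0 %||% 1
  )
  raw <- .raw_predict(unclass(params), spec)
  if (is.null(raw)) {
    stop("model observables undefined at these parameters", call. = FALSE)
  }
  if (unit == "ng_per_ml") raw <- raw * spec$gfactor

  sdlog <- sqrt(log(1 + noise_cv^2))
  set.seed(seed)
  reps <- purrr::map_dfr(seq_len(n_replicates), function(r) {
    noisy <- raw
    if (noise_cv > 0) {
      noisy <- raw * stats::rlnorm(length(raw), meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog)
    }
    out <- grid
    out$replicate <- r
    out$value <- NA_real_
    if (unit == "fold_change") {
      for (cmp in unique(grid$compartment)) {
        sel <- grid$compartment == cmp
        ref <- if (kind == "pulse_chase") {
          mode <- if (cmp == "intracellular") spec$pc_norm_i else spec$pc_norm_x
          if (mode == "chase_start") {
            noisy[sel][which.min(abs(grid$time_h[sel]))]
          } else if (mode == "chase_start_intracellular") {
            sel_i <- grid$compartment == "intracellular"
            if (!any(sel_i)) {
              stop("shared-reference normalization needs the intracellular ",
                   "compartment in the dataset", call. = FALSE)
            }
            noisy[sel_i][which.min(abs(grid$time_h[sel_i]))]
          } else {
            max(noisy[sel])
          }
        } else if (normalization$mode == "ref_time") {
          noisy[sel][which(abs(grid$time_h[sel] - normalization$ref_time) < 1e-9)[1]]
        } else {
          max(noisy[sel])
        }
        if (!is.finite(ref) || ref <= 0) {
          stop("normalization reference is 0 for replicate ", r,
               "; switch normalization mode", call. = FALSE)
        }
        out$value[sel] <- noisy[sel] / ref
      }
    } else {
      out$value <- noisy
    }
    out
  })

  reps$experiment_id <- experiment_id %||% paste0(kind, "_synthetic")
  reps$protocol <- kind
  reps$unit <- unit
  sflt_dataset(reps[, c("experiment_id", "protocol", "time_h", "compartment",
                        "value", "unit", "replicate")],
               normalization = if (unit == "fold_change" &&
                                   kind != "pulse_chase") normalization,
               geometry = geometry, protocol = protocol)
}

#' Standard parameter-recovery benchmark
#'
#' Draws a ground-truth parameter set and generates the paired dataset
#' types the model is fitted to in practice: a pulse-chase fold-change
#' time course (both compartments, 8 chase points over 8 h after a 3 h
#' pulse) and a media accumulation concentration time course (6 points over
#' 24 h with explicit geometry). Noise CV 0.2, n = 3 replicates.
#'
#' Truth is drawn log-uniformly over ranges where both experiment classes
#' are informative: secretion and intracellular degradation rates in
#' `[0.1, 1]`/h (intracellular half-lives of tens of minutes to hours),
#' slow extracellular degradation in `[0.005, 0.05]`/h (media half-lives of
#' 14 h to days — conditioned media sFLT1 is long-lived), production in
#' `[1e4, 1e5]` molecules/cell/h, and a maturation delay uniform in
#' `[0.25, 2]` h.
#'
#' @param seed Integer seed; determines both the truth and the noise.
#' @param noise_cv Noise level (default 0.2).
#' @param n_replicates Replicates per dataset (default 3).
#' @return A list with elements `params` (the truth, an [sflt_params()])
#'   and `datasets` (list of the two [sflt_dataset()]s).
#' @export
generate_fit_benchmark <- function(seed = 1, noise_cv = 0.2, n_replicates = 3) {
  set.seed(seed)
  runif_log <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  truth <- sflt_params(
    k_prod = runif_log(1e4, 1e5),
    tau = stats::runif(1, 0.25, 2),
    k_out_Si = runif_log(0.1, 1),
    k_deg_Si = runif_log(0.1, 1),
    k_deg_Sx = runif_log(0.005, 0.05)
  )
  # shared-reference pulse-chase convention: lysate and media label on one
  # scale, so the secreted fraction (hence the k_out_Si/k_deg_Si split) is
  # preserved in the fold changes
  pc_proto <- protocol_pulse_chase(
    pulse_duration = 3,
    sample_times = c(0, 0.5, 1, 2, 3, 4, 6, 8),
    normalization = list(intracellular = "chase_start",
                         extracellular = "chase_start_intracellular")
  )
  acc_proto <- protocol_accumulation(
    horizon = 24, sample_times = c(2, 4, 8, 12, 18, 24)
  )
  geom <- sflt_geometry(n_cells = 5e5, media_volume_ml = 2,
                        molecular_weight_g_per_mol = 1e5)
  pc <- generate_dataset(truth, pc_proto, noise_cv = noise_cv,
                         n_replicates = n_replicates, unit = "fold_change",
                         seed = seed * 2 + 1,
                         experiment_id = "pulse_chase_benchmark")
  acc <- generate_dataset(truth, acc_proto, noise_cv = noise_cv,
                          n_replicates = n_replicates, unit = "ng_per_ml",
                          geometry = geom, seed = seed * 2 + 2,
                          experiment_id = "accumulation_benchmark")
  list(params = truth, datasets = list(pulse_chase = pc, accumulation = acc))
}
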