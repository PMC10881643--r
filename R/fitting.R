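# Parameter estimation from heterogeneous time-course datasets.
#
# The observable map (protocol simulation -> unit conversion -> the dataset's
# own normalization) is compiled once per dataset into a closure operating on
# plain numeric vectors, so the weighted least-squares objective is cheap
# enough for multi-start simplex optimisation and profile likelihoods.

# ---- compiled per-dataset prediction ---------------------------------------

# Internal numeric summary of one dataset, precomputed once.
.dataset_spec <- function(dataset) {
  stopifnot(inherits(dataset, "sflt_dataset"))
  kind <- unique(dataset$protocol)
  if (length(kind) != 1) {
    stop("a dataset must contain a single protocol kind", call. = FALSE)
  }
  unit <- unique(dataset$unit)
  comp <- match(dataset$compartment, c("intracellular", "extracellular"))
  scale <- ifelse(is.finite(dataset$sigma), dataset$sigma, mean(dataset$value))
  if (any(scale <= 0)) {
    stop("residual scale (sigma or dataset mean) must be positive", call. = FALSE)
  }
  norm <- dataset_normalization(dataset)
  geom <- dataset_geometry(dataset)
  proto <- dataset_protocol(dataset)
  gfactor <- if (!is.null(geom)) {
    geom$n_cells / (AVOGADRO * geom$media_volume_ml) *
      geom$molecular_weight_g_per_mol * 1e9
  } else NA_real_
  if (unit == "ng_per_ml" && !is.finite(gfactor)) {
    stop("concentration data need an explicit geometry", call. = FALSE)
  }
  pc_norm <- if (kind == "pulse_chase") {
    (proto$normalization %||% list(intracellular = "chase_start",
                                   extracellular = "max"))
  }
  list(
    kind = kind, unit = unit,
    time = dataset$time_h, comp = comp, value = dataset$value, scale = scale,
    n = nrow(dataset),
    norm_mode = norm$mode %||% "none",
    ref_time = norm$ref_time %||% NA_real_,
    gfactor = gfactor,
    pulse_duration = proto$pulse_duration %||% 1,
    pc_norm_i = pc_norm$intracellular %||% "chase_start",
    pc_norm_x = pc_norm$extracellular %||% "max",
    S_x0 = proto$S_x0 %||% 1
  )
}

# Labelled-cohort state at absolute times Tabs (pulse on during [tau,
# tau + Tp) after gate shifting; zero history). Plain-list params.
.pc_state <- function(p, Tp, Tabs) {
  S_i <- numeric(length(Tabs))
  S_x <- numeric(length(Tabs))
  t1 <- p$tau
  t2 <- p$tau + Tp
  in_pulse <- Tabs > t1 & Tabs <= t2
  post <- Tabs > t2
  if (any(in_pulse)) {
    seg <- .propagate_segment(p, 0, 0, p$k_prod, Tabs[in_pulse] - t1)
    S_i[in_pulse] <- seg$S_i
    S_x[in_pulse] <- seg$S_x
  }
  if (any(post)) {
    end <- .propagate_segment(p, 0, 0, p$k_prod, Tp)
    seg <- .propagate_segment(p, end$S_i, end$S_x, 0, Tabs[post] - t2)
    S_i[post] <- seg$S_i
    S_x[post] <- seg$S_x
  }
  list(S_i = S_i, S_x = S_x)
}

# Raw model observables (molecules/cell, before unit conversion and
# normalization) at the spec's times. Returns list(raw) or NULL when the
# parameter point is degenerate for this observable map.
.raw_predict <- function(p, spec) {
  a <- p$k_out_Si + p$k_deg_Si
  raw <- numeric(spec$n)
  if (spec$kind == "accumulation") {
    if (a <= 0) return(NULL)
    S_i_star <- p$k_prod / a
    is_i <- spec$comp == 1
    raw[is_i] <- S_i_star
    tx <- spec$time[!is_i]
    raw[!is_i] <- p$k_out_Si * S_i_star * .phi1(p$k_deg_Sx, tx)
  } else if (spec$kind == "pulse_chase") {
    st <- .pc_state(p, spec$pulse_duration, spec$pulse_duration + spec$time)
    raw[spec$comp == 1] <- st$S_i[spec$comp == 1]
    raw[spec$comp == 2] <- st$S_x[spec$comp == 2]
  } else if (spec$kind == "cell_free_decay") {
    raw <- spec$S_x0 * exp(-p$k_deg_Sx * spec$time)
  } else {
    stop("no predictor for protocol kind '", spec$kind, "'", call. = FALSE)
  }
  raw
}

# Full prediction in the dataset's unit and normalization. NULL signals an
# invalid parameter point (e.g. normalization reference 0).
.predict_spec <- function(p, spec) {
  raw <- .raw_predict(p, spec)
  if (is.null(raw)) return(NULL)
  if (spec$unit == "molecules_per_cell") return(raw)
  if (spec$unit == "ng_per_ml") return(raw * spec$gfactor)

  # fold_change: normalize the model prediction exactly as the data were
  pred <- raw
  if (spec$kind == "pulse_chase") {
    Tp <- spec$pulse_duration
    for (ci in 1:2) {
      sel <- spec$comp == ci
      if (!any(sel)) next
      mode <- if (ci == 1) spec$pc_norm_i else spec$pc_norm_x
      ref <- if (mode == "chase_start") {
        st0 <- .pc_state(p, Tp, Tp)
        if (ci == 1) st0$S_i else st0$S_x
      } else if (mode == "chase_start_intracellular") {
        .pc_state(p, Tp, Tp)$S_i
      } else {
        max(raw[sel])
      }
      if (!is.finite(ref) || ref <= 0) return(NULL)
      pred[sel] <- raw[sel] / ref
    }
  } else {
    for (ci in 1:2) {
      sel <- spec$comp == ci
      if (!any(sel)) next
      ref <- switch(spec$norm_mode,
        ref_time = {
          rspec <- spec
          rspec$time <- spec$ref_time
          rspec$comp <- ci
          rspec$n <- 1L
          .raw_predict(p, rspec)
        },
        max = max(raw[sel]),
        none = 1,
        stop("unknown normalization mode '", spec$norm_mode, "'",
             call. = FALSE)
      )
      if (is.null(ref) || !is.finite(ref) || ref <= 0) return(NULL)
      pred[sel] <- raw[sel] / ref
    }
  }
  pred
}

#' Predict a dataset's observables from model parameters
#'
#' Runs the protocol that produced the dataset, converts the trajectory to
#' the dataset's unit (via its geometry, for concentrations) and applies the
#' dataset's own normalization to the model prediction — so model and data
#' live in exactly the same observable space.
#'
#' @param params An [sflt_params()] object.
#' @param dataset An [sflt_dataset()].
#' @return The dataset tibble with a `prediction` column appended.
#' @export
predict_observables <- function(params, dataset) {
  stopifnot(inherits(params, "sflt_params"))
  spec <- .dataset_spec(dataset)
  pred <- .predict_spec(unclass(params), spec)
  if (is.null(pred)) {
    stop("prediction undefined at these parameters (zero normalization ",
         "reference or degenerate steady state); switch normalization mode ",
         "or adjust parameters", call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(dataset))
  out$prediction <- pred
  out
}

# ---- objective --------------------------------------------------------------

.dataset_weights <- function(specs, weights) {
  if (is.null(weights)) {
    vapply(specs, function(s) 1 / s$n, numeric(1))
  } else {
    if (length(weights) != length(specs)) {
      stop("need one weight per dataset", call. = FALSE)
    }
    weights
  }
}

.compile_objective <- function(datasets, weights = NULL) {
  if (length(datasets) == 0) stop("at least one dataset required", call. = FALSE)
  if (inherits(datasets, "sflt_dataset")) datasets <- list(datasets)
  specs <- lapply(datasets, .dataset_spec)
  w <- .dataset_weights(specs, weights)
  function(p) {
    total <- 0
    for (d in seq_along(specs)) {
      spec <- specs[[d]]
      pred <- .predict_spec(p, spec)
      if (is.null(pred) || any(!is.finite(pred))) {
        # degenerate observable map: large penalty with a slope back towards
        # configurations where the pulse label matures before chase start
        return(1e10 * (1 + max(0, p$tau)))
      }
      r <- (pred - spec$value) / spec$scale
      total <- total + w[[d]] * sum(r * r)
    }
    unname(total)
  }
}

#' Weighted least-squares objective
#'
#' Sum over datasets of weighted squared residuals between data and
#' [predict_observables()] predictions. Residuals are scaled by the
#' per-point `sigma` when the dataset provides one, otherwise by the
#' dataset's mean value (relative error). By default each dataset receives
#' equal total weight regardless of how many points it has (weight `1/n_d`
#' per point), so a small absolute-concentration dataset is not swamped by a
#' dense fold-change one.
#'
#' @param params An [sflt_params()] object.
#' @param datasets A list of [sflt_dataset()] objects (or a single one).
#' @param weights Optional numeric vector, one weight per dataset; replaces
#'   the default `1/n_d` weights.
#' @return The scalar cost (dimensionless, >= 0).
#' @export
objective <- function(params, datasets, weights = NULL) {
  stopifnot(inherits(params, "sflt_params"))
  f <- .compile_objective(datasets, weights)
  f(unclass(params))
}

# ---- bounds and parameter transform ----------------------------------------

#' Default fitting bounds
#'
#' Box bounds spanning the biologically plausible range: first-order rates in
#' `[1e-4, 1e2]` per hour (half-lives from seconds to months), delay in
#' `[0, 8]` h, production in `[1, 1e7]` molecules/cell/h. Rates and
#' production are optimised on the log scale; the delay linearly.
#'
#' @return A named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(k_prod = c(1, 1e7), tau = c(0, 8), k_out_Si = c(1e-4, 1e2),
       k_deg_Si = c(1e-4, 1e2), k_deg_Sx = c(1e-4, 1e2))
}

.log_scaled <- c(k_prod = TRUE, tau = FALSE, k_out_Si = TRUE,
                 k_deg_Si = TRUE, k_deg_Sx = TRUE)

.to_z <- function(theta, bounds) {
  vapply(param_names(), function(nm) {
    if (.log_scaled[[nm]]) log(theta[[nm]]) else theta[[nm]]
  }, numeric(1))
}

.z_box <- function(bounds) {
  lo <- vapply(param_names(), function(nm) {
    if (.log_scaled[[nm]]) log(bounds[[nm]][1]) else bounds[[nm]][1]
  }, numeric(1))
  hi <- vapply(param_names(), function(nm) {
    if (.log_scaled[[nm]]) log(bounds[[nm]][2]) else bounds[[nm]][2]
  }, numeric(1))
  list(lo = lo, hi = hi)
}

.from_z <- function(z) {
  p <- as.list(ifelse(.log_scaled[param_names()], exp(z), z))
  names(p) <- param_names()
  p
}

# objective in z-space with soft box handling: evaluate at the clamped point
# and add a quadratic penalty for the excursion
.z_objective <- function(fobj, box) {
  width <- pmax(box$hi - box$lo, 1e-8)
  function(z) {
    zc <- pmin(pmax(z, box$lo), box$hi)
    pen <- sum(((z - zc) / width)^2) * 1e6
    fobj(.from_z(zc)) + pen
  }
}

# ---- fit --------------------------------------------------------------------

#' Fit the secretion model to time-course data
#'
#' Multi-start bounded least-squares estimation of the five kinetic
#' parameters. Rates and production rate are optimised on the log scale, the
#' delay linearly. Starting points are a Latin hypercube over the bounds;
#' the most promising starts are refined with Nelder-Mead simplex (the
#' objective's normalization corners make derivative-free search the robust
#' choice) and the best optimum is polished with restarted simplex runs.
#' Deterministic for a given `seed`.
#'
#' @param datasets A list of [sflt_dataset()] objects (or a single one).
#' @param bounds Named list of `c(lower, upper)` per parameter; see
#'   [default_bounds()].
#' @param n_starts Number of Latin-hypercube starting points.
#' @param n_local How many of the best starts get a full local optimisation.
#' @param weights Optional per-dataset weights (default: equal total weight).
#' @param seed Integer seed controlling the start design.
#' @return An object of class `sflt_fit`: optimal `params`, `objective`,
#'   per-record `residuals` tibble, a `starts` tibble with the dispersion of
#'   the multi-start results, `converged` flag, and `non_identifiable` — the
#'   structurally non-identifiable parameters (`k_prod` when only
#'   fold-change data are fitted, since fold changes are invariant to the
#'   production scale).
#' @export
fit_secretion_model <- function(datasets, bounds = default_bounds(),
                                n_starts = 20, n_local = 5, weights = NULL,
                                seed = 1) {
  if (inherits(datasets, "sflt_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0) stop("at least one dataset required", call. = FALSE)
  stopifnot(n_starts >= 1)
  for (nm in param_names()) {
    b <- bounds[[nm]]
    if (is.null(b) || length(b) != 2 || b[1] > b[2] ||
        (.log_scaled[[nm]] && b[1] <= 0)) {
      stop("invalid bounds for parameter '", nm, "'", call. = FALSE)
    }
  }

  fobj <- .compile_objective(datasets, weights)
  box <- .z_box(bounds)
  fz <- .z_objective(fobj, box)

  set.seed(seed)
  design <- lhs::randomLHS(n_starts, 5)
  z_starts <- t(box$lo + t(design) * (box$hi - box$lo))
  colnames(z_starts) <- param_names()

  start_obj <- apply(z_starts, 1, fz)
  take <- order(start_obj)[seq_len(min(n_local, n_starts))]

  local_runs <- lapply(take, function(i) {
    stats::optim(z_starts[i, ], fz, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  })
  local_obj <- vapply(local_runs, function(r) r$value, numeric(1))
  best <- local_runs[[which.min(local_obj)]]

  # restarted simplex polish: rebuilds the simplex around the incumbent
  for (i in 1:2) {
    best2 <- stats::optim(best$par, fz, method = "Nelder-Mead",
                          control = list(maxit = 3000, reltol = 1e-14))
    if (best2$value <= best$value) best <- best2
  }

  z_hat <- pmin(pmax(best$par, box$lo), box$hi)
  p_hat <- .from_z(z_hat)
  theta <- do.call(sflt_params, p_hat)

  residuals <- purrr::map_dfr(seq_along(datasets), function(d) {
    out <- predict_observables(theta, datasets[[d]])
    out$dataset <- d
    out$residual <- out$prediction - out$value
    out
  })

  units <- vapply(datasets, function(d) unique(d$unit), character(1))
  non_id <- if (all(units == "fold_change")) "k_prod" else character(0)

  starts <- tibble::tibble(
    start = seq_len(n_starts),
    screening_objective = start_obj,
    refined = seq_len(n_starts) %in% take,
    local_objective = NA_real_
  )
  starts$local_objective[take] <- local_obj

  structure(
    list(params = theta, objective = fobj(p_hat), residuals = residuals,
         starts = starts, converged = best$convergence == 0 ||
           best$value <= min(local_obj),
         non_identifiable = non_id, datasets = datasets, weights = weights,
         bounds = bounds, seed = seed, profiles = list()),
    class = "sflt_fit"
  )
}

#' @export
print.sflt_fit <- function(x, ...) {
  cat("<sflt_fit> objective =", signif(x$objective, 6),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$params)
  if (length(x$non_identifiable) > 0) {
    cat("  structurally non-identifiable:",
        paste(x$non_identifiable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted model into one row per parameter
#'
#' @param x An `sflt_fit`.
#' @param ... Unused.
#' @return A tibble with `parameter`, `estimate`, and — for parameters with
#'   a computed [profile_likelihood()] — `conf.low`, `conf.high`,
#'   `identifiable`.
#' @export
tidy.sflt_fit <- function(x, ...) {
  out <- tidy(x$params)
  names(out)[names(out) == "value"] <- "estimate"
  if (length(x$profiles) > 0) {
    out$conf.low <- NA_real_
    out$conf.high <- NA_real_
    out$identifiable <- NA
    for (nm in names(x$profiles)) {
      pr <- x$profiles[[nm]]
      i <- match(nm, out$parameter)
      out$conf.low[i] <- attr(pr, "ci_lower")
      out$conf.high[i] <- attr(pr, "ci_upper")
      out$identifiable[i] <- attr(pr, "identifiable")
    }
  }
  out
}

#' One-row summary of a fit
#'
#' @param x An `sflt_fit`.
#' @param ... Unused.
#' @return A tibble with objective value, data size, multi-start dispersion
#'   and convergence flag.
#' @export
glance.sflt_fit <- function(x, ...) {
  refined <- x$starts$local_objective[x$starts$refined]
  tibble::tibble(
    objective = x$objective,
    n_obs = nrow(x$residuals),
    n_datasets = length(x$datasets),
    n_starts = nrow(x$starts),
    start_dispersion = stats::sd(refined),
    converged = x$converged
  )
}

# ---- profile likelihood ------------------------------------------------------

#' Profile likelihood for one parameter
#'
#' Fixes `param` at each grid value, re-optimises all other parameters
#' (warm-started from the fit optimum), and reports the profile cost curve.
#' The 95% confidence interval is the region where the profile stays within
#' `threshold * s2` of the optimum, where `threshold` is 3.84 by default
#' (the chi-square 95% quantile with 1 df) and `s2` is the weighted
#' residual variance estimated at the optimum,
#' `s2 = objective / (sum(w) * (1 - p/N))` — the factor that converts the
#' package's weighted relative-error cost onto the deviance scale the
#' chi-square quantile applies to (`s2` is close to 1 when proper per-point
#' sigmas are supplied, and close to the squared noise CV under the default
#' mean-value scaling). Crossings are located by linear interpolation. A
#' profile that never rises above the scaled threshold across the whole
#' searched range marks the parameter non-identifiable: the flag is lowered
#' and the interval reported as `(-Inf, Inf)`.
#'
#' @param fit An `sflt_fit`.
#' @param param Parameter name to profile.
#' @param grid Grid of parameter values (natural scale). Default: for
#'   log-scaled parameters, the optimum times `10^seq(-2, 2)` (11 points)
#'   clipped to the bounds; for `tau`, +/- 2 h around the optimum.
#' @param threshold Cost offset defining the confidence region.
#' @return An `sflt_profile` tibble (`value`, `profile_objective`) with
#'   attributes `ci_lower`, `ci_upper`, `identifiable`, `param`,
#'   `threshold`, `optimum`.
#' @export
profile_likelihood <- function(fit, param, grid = NULL, threshold = 3.84) {
  stopifnot(inherits(fit, "sflt_fit"))
  if (!param %in% param_names()) {
    stop("unknown parameter '", param, "'", call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge; no profile", call. = FALSE)
  b <- fit$bounds[[param]]
  opt_val <- fit$params[[param]]
  if (is.null(grid)) {
    if (.log_scaled[[param]]) {
      grid <- opt_val * 10^seq(-2, 2, length.out = 11)
    } else {
      grid <- seq(opt_val - 2, opt_val + 2, length.out = 11)
    }
    grid <- pmin(pmax(grid, b[1]), b[2])
  }
  if (any(grid < b[1] - 1e-12) || any(grid > b[2] + 1e-12)) {
    stop("profile grid outside the bounds for '", param, "'", call. = FALSE)
  }
  grid <- sort(unique(c(grid, opt_val)))

  fobj <- .compile_objective(fit$datasets, fit$weights)
  box <- .z_box(fit$bounds)
  i_par <- match(param, param_names())
  z_opt <- .to_z(unclass(fit$params), fit$bounds)

  eval_profile_point <- function(v) {
    if (abs(v - opt_val) < 1e-15) return(fit$objective)
    z_fix <- if (.log_scaled[[param]]) log(v) else v
    f_red <- function(z_free) {
      z <- z_opt
      z[-i_par] <- z_free
      z[i_par] <- z_fix
      zc <- pmin(pmax(z, box$lo), box$hi)
      zc[i_par] <- z_fix
      pen <- sum(((z - zc) / pmax(box$hi - box$lo, 1e-8))^2) * 1e6
      fobj(.from_z(zc)) + pen
    }
    r <- stats::optim(z_opt[-i_par], f_red, method = "Nelder-Mead",
                      control = list(maxit = 1200, reltol = 1e-11))
    min(r$value, f_red(z_opt[-i_par]))
  }
  prof <- vapply(grid, eval_profile_point, numeric(1))

  specs <- lapply(fit$datasets, .dataset_spec)
  w <- .dataset_weights(specs, fit$weights)
  n_tot <- sum(vapply(specs, function(s) s$n, numeric(1)))
  w_tot <- sum(w * vapply(specs, function(s) s$n, numeric(1)))
  s2 <- fit$objective / (w_tot * max(1 - 5 / n_tot, 0.1))
  thr <- threshold * s2

  # extend the grid outwards while the profile has not yet crossed the
  # threshold and the box bound has not been reached, so an interval that is
  # finite within the bounds is found even when it lies outside the initial
  # span
  step_out <- function(v, up) {
    if (.log_scaled[[param]]) {
      if (up) min(v * 10, b[2]) else max(v / 10, b[1])
    } else {
      if (up) min(v + 2, b[2]) else max(v - 2, b[1])
    }
  }
  for (side in c("lower", "upper")) {
    for (iter in 1:8) {
      base <- min(prof, fit$objective)
      edge_i <- if (side == "lower") which.min(grid) else which.max(grid)
      crossed <- if (side == "lower") {
        any(prof[grid < opt_val] - base > thr)
      } else {
        any(prof[grid > opt_val] - base > thr)
      }
      at_bound <- abs(grid[edge_i] - (if (side == "lower") b[1] else b[2])) < 1e-12
      if (crossed || at_bound) break
      v_new <- step_out(grid[edge_i], up = side == "upper")
      grid <- c(grid, v_new)
      prof <- c(prof, eval_profile_point(v_new))
    }
  }
  o <- order(grid)
  grid <- grid[o]
  prof <- prof[o]

  base <- min(prof, fit$objective)
  rel <- prof - base
  identifiable <- !all(rel <= thr)
  ci_lower <- -Inf
  ci_upper <- Inf
  if (identifiable) {
    i_opt <- which.min(abs(grid - opt_val))
    # walk outwards from the optimum to the first threshold crossing
    lo_idx <- i_opt
    while (lo_idx > 1 && rel[lo_idx - 1] <= thr) lo_idx <- lo_idx - 1
    if (lo_idx > 1) {
      # linear interpolation between (x1, y1) above and (x2, y2) below
      x1 <- grid[lo_idx - 1]; x2 <- grid[lo_idx]
      y1 <- rel[lo_idx - 1]; y2 <- rel[lo_idx]
      ci_lower <- x1 + (y1 - thr) / (y1 - y2) * (x2 - x1)
    }
    hi_idx <- i_opt
    while (hi_idx < length(grid) && rel[hi_idx + 1] <= thr) {
      hi_idx <- hi_idx + 1
    }
    if (hi_idx < length(grid)) {
      x1 <- grid[hi_idx]; x2 <- grid[hi_idx + 1]
      y1 <- rel[hi_idx]; y2 <- rel[hi_idx + 1]
      ci_upper <- x1 + (thr - y1) / (y2 - y1) * (x2 - x1)
    }
  }

  out <- tibble::tibble(value = grid, profile_objective = prof)
  attr(out, "param") <- param
  attr(out, "threshold") <- threshold
  attr(out, "threshold_scaled") <- thr
  attr(out, "s2") <- s2
  attr(out, "optimum") <- fit$objective
  attr(out, "ci_lower") <- ci_lower
  attr(out, "ci_upper") <- ci_upper
  attr(out, "identifiable") <- identifiable
  class(out) <- c("sflt_profile", class(out))
  out
}

#' @rdname profile_likelihood
#' @param object An `sflt_fit`.
#' @param params Character vector of parameters to profile.
#' @param ... Passed to [profile_likelihood()].
#' @details `add_profiles()` computes profiles for several parameters and
#'   stores them in the fit object so that [tidy.sflt_fit()] reports
#'   intervals.
#' @export
add_profiles <- function(object, params = param_names(), ...) {
  for (nm in params) {
    object$profiles[[nm]] <- profile_likelihood(object, nm, ...)
  }
  object
}
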