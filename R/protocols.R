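# Declarative experiment protocols. Each protocol mirrors one of the four
# experiment classes the model is confronted with: media-change accumulation,
# pulse-chase, cell-free media decay, and inhibitor treatment.

new_protocol <- function(kind, horizon, production_schedule = NULL,
                         media_events = numeric(0), inhibitions = list(),
                         history = c("steady_state", "zero"),
                         sample_times = NULL, S_x0 = NULL,
                         pulse_duration = NULL, normalization = NULL) {
  history <- match.arg(history)
  if (!is.numeric(horizon) || horizon <= 0) {
    stop("horizon must be a positive duration in hours", call. = FALSE)
  }
  if (!is.null(sample_times)) {
    if (any(sample_times < 0) || any(sample_times > horizon + 1e-9)) {
      stop("sample_times must lie within [0, horizon]", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, horizon = horizon,
         production_schedule = production_schedule,
         media_events = media_events, inhibitions = inhibitions,
         history = history, sample_times = sample_times, S_x0 = S_x0,
         pulse_duration = pulse_duration, normalization = normalization),
    class = "sflt_protocol"
  )
}

#' General protocol constructor
#'
#' Builds an arbitrary protocol from its parts. The kind-specific helpers
#' ([protocol_accumulation()], [protocol_pulse_chase()],
#' [protocol_cell_free_decay()], [protocol_inhibitor_treatment()]) cover the
#' standard designs; this constructor is for custom ones (e.g. synthesis
#' onset from an empty system, or multiple media changes).
#'
#' @param kind Protocol kind label.
#' @param horizon Total simulated time, h.
#' @param production_schedule Data frame with columns `time`, `value`: the
#'   production gate u(t) is piecewise constant, `value` in `{0, 1}` from
#'   each `time` onward. `NULL` means the history gate continues.
#' @param media_events Times at which the extracellular pool is reset to 0.
#' @param inhibitions List of `list(parameter, fraction, onset)` entries.
#' @param history `"steady_state"` (unperturbed culture, gate on for t < 0)
#'   or `"zero"` (empty system, gate off for t < 0).
#' @param sample_times Default observation grid, h.
#' @param S_x0 Explicit initial extracellular amount (optional).
#' @param pulse_duration,normalization Pulse-chase settings (optional).
#' @return An `sflt_protocol`.
#' @export
sflt_protocol <- function(kind = "custom", horizon,
                          production_schedule = NULL,
                          media_events = numeric(0), inhibitions = list(),
                          history = c("steady_state", "zero"),
                          sample_times = NULL, S_x0 = NULL,
                          pulse_duration = NULL, normalization = NULL) {
  new_protocol(kind = kind, horizon = horizon,
               production_schedule = production_schedule,
               media_events = media_events, inhibitions = inhibitions,
               history = history, sample_times = sample_times, S_x0 = S_x0,
               pulse_duration = pulse_duration, normalization = normalization)
}

#' @export
print.sflt_protocol <- function(x, ...) {
  cat("<sflt_protocol:", x$kind, ">\n")
  cat("  horizon:", x$horizon, "h; history:", x$history, "\n")
  if (length(x$media_events)) {
    cat("  media changes at:", paste(x$media_events, collapse = ", "), "h\n")
  }
  if (length(x$inhibitions)) {
    for (i in x$inhibitions) {
      cat(sprintf("  inhibition: %s by %.0f%% from t = %g h\n",
                  i$parameter, 100 * i$fraction, i$onset %||% 0))
    }
  }
  invisible(x)
}

#' Media-change accumulation protocol
#'
#' Cells at constitutive steady state receive fresh medium at t = 0 (the
#' extracellular pool is reset); secreted sFLT1 then accumulates in the
#' medium and is sampled over time. This is the design behind conditioned-
#' media time courses.
#'
#' @param horizon Total simulated time, h.
#' @param sample_times Observation times, h. Default: 25 evenly spaced points.
#' @return An `sflt_protocol` of kind `"accumulation"`.
#' @export
protocol_accumulation <- function(horizon = 24,
                                  sample_times = seq(0, horizon, length.out = 25)) {
  new_protocol("accumulation", horizon = horizon,
               media_events = 0, history = "steady_state",
               sample_times = sample_times)
}

#' Cell-free media decay protocol
#'
#' Conditioned medium is removed from cells and incubated alone, so the only
#' active process is extracellular degradation: `S_x(t) = S_x0 e^(-k_deg_Sx t)`.
#'
#' @param S_x0 Initial extracellular amount, molecules/cell-equivalent.
#' @param horizon Total incubation, h (the stability experiment ran to 72 h).
#' @param sample_times Observation times, h.
#' @return An `sflt_protocol` of kind `"cell_free_decay"`.
#' @export
protocol_cell_free_decay <- function(S_x0 = 1, horizon = 72,
                                     sample_times = seq(0, horizon, length.out = 13)) {
  if (S_x0 < 0) stop("S_x0 must be >= 0", call. = FALSE)
  new_protocol("cell_free_decay", horizon = horizon, history = "zero",
               S_x0 = S_x0, sample_times = sample_times)
}

#' Pulse-chase protocol
#'
#' Protein synthesised during a labelling pulse is followed through the
#' secretory pathway; readouts are fold changes of the labelled cohort in
#' each compartment during the chase.
#'
#' @param pulse_duration Length of the labelling pulse, h.
#' @param sample_times Chase sampling times, h after chase start.
#' @param normalization Named list with entries `intracellular` (one of
#'   `"chase_start"` or `"max"`) and `extracellular` (`"max"`,
#'   `"chase_start"`, or `"chase_start_intracellular"`); the convention used
#'   to express the labelled signals as fold changes. The default
#'   normalizes each compartment to its own reference. The shared-reference
#'   convention `extracellular = "chase_start_intracellular"` (both
#'   compartments relative to the intracellular label at chase start, as
#'   when lysate and media signals share one measurement scale) additionally
#'   preserves the secreted fraction, making the split of `k_out_Si` versus
#'   `k_deg_Si` recoverable from fold-change data alone.
#' @return An `sflt_protocol` of kind `"pulse_chase"`.
#' @export
protocol_pulse_chase <- function(pulse_duration = 1,
                                 sample_times = seq(0, 8, by = 1),
                                 normalization = list(intracellular = "chase_start",
                                                      extracellular = "max")) {
  if (pulse_duration <= 0) stop("pulse_duration must be > 0", call. = FALSE)
  new_protocol("pulse_chase", horizon = pulse_duration + max(sample_times),
               history = "zero", sample_times = sample_times,
               pulse_duration = pulse_duration, normalization = normalization)
}

#' Inhibitor treatment protocol
#'
#' Both arms start from constitutive steady state with a media change at
#' t = 0; the treated arm additionally has one rate parameter scaled by
#' `(1 - fraction)` from t = 0 (inhibitors are modelled as constant
#' fractional reductions, no pharmacokinetic ramp). Readouts are
#' treated/control ratios of extracellular and intracellular sFLT1 at the
#' end of the media window (18 h by default, the experimental window).
#'
#' @param target_param Name of the inhibited parameter (see [param_names()]).
#' @param fraction Fractional inhibition f in `[0, 1]`.
#' @param duration Media window, h.
#' @return An `sflt_protocol` of kind `"inhibitor_treatment"`.
#' @export
protocol_inhibitor_treatment <- function(target_param = "k_out_Si",
                                         fraction = 0, duration = 18) {
  if (!target_param %in% param_names()) {
    stop("unknown parameter '", target_param, "'; valid names: ",
         paste(param_names(), collapse = ", "), call. = FALSE)
  }
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  new_protocol("inhibitor_treatment", horizon = duration, media_events = 0,
               history = "steady_state",
               inhibitions = list(list(parameter = target_param,
                                       fraction = fraction, onset = 0)),
               sample_times = c(0, duration))
}

# ---- protocol runners ------------------------------------------------------

#' Run a media-change accumulation experiment
#'
#' @param params An [sflt_params()] object.
#' @param sample_times Observation times, h.
#' @param horizon Protocol horizon, h; defaults to the last sample.
#' @return An `sflt_trajectory`; `S_x` starts at 0 (fresh medium) and
#'   `S_i` starts at the constitutive steady state.
#' @export
run_accumulation <- function(params, sample_times = seq(0, 24, length.out = 25),
                             horizon = max(sample_times)) {
  proto <- protocol_accumulation(horizon = max(horizon, max(sample_times)),
                                 sample_times = sample_times)
  simulate_secretion(params, proto)
}

#' Run a cell-free media decay experiment
#'
#' @param params An [sflt_params()] object (only `k_deg_Sx` acts).
#' @param S_x0 Initial extracellular amount.
#' @param sample_times Observation times, h.
#' @return A tibble with columns `time` and `S_x`; no intracellular channel
#'   exists in a cell-free incubation.
#' @export
run_cell_free_decay <- function(params, S_x0 = 1,
                                sample_times = seq(0, 72, length.out = 13)) {
  stopifnot(inherits(params, "sflt_params"))
  if (S_x0 < 0) stop("S_x0 must be >= 0", call. = FALSE)
  if (any(sample_times < 0)) stop("sample_times must be >= 0", call. = FALSE)
  tibble::tibble(time = sample_times,
                 S_x = S_x0 * exp(-params$k_deg_Sx * sample_times))
}

#' Run a pulse-chase experiment on the labelled cohort
#'
#' The labelled cohort obeys the same kinetics as total sFLT1 but with
#' production switched on only during the pulse window; the chase starts at
#' t = 0. Because the system is linear, the labelled fold changes are
#' independent of the absolute production rate.
#'
#' @param params An [sflt_params()] object.
#' @param pulse_duration Labelling pulse length, h.
#' @param sample_times Chase times, h after chase start.
#' @param normalization See [protocol_pulse_chase()].
#' @return A tibble with columns `time` (chase time, h), `intracellular` and
#'   `extracellular` (labelled fold changes per the normalization).
#' @export
run_pulse_chase <- function(params, pulse_duration = 1,
                            sample_times = seq(0, 8, by = 1),
                            normalization = list(intracellular = "chase_start",
                                                 extracellular = "max")) {
  stopifnot(inherits(params, "sflt_params"))
  if (pulse_duration <= 0) stop("pulse_duration must be > 0", call. = FALSE)
  if (any(sample_times < 0)) stop("chase sample_times must be >= 0", call. = FALSE)
  horizon <- pulse_duration + max(sample_times)
  proto <- new_protocol(
    "pulse_chase", horizon = horizon, history = "zero",
    production_schedule = tibble::tibble(time = c(0, pulse_duration),
                                         value = c(1, 0)),
    sample_times = unique(c(pulse_duration, pulse_duration + sample_times)),
    pulse_duration = pulse_duration, normalization = normalization
  )
  traj <- simulate_secretion(params, proto)
  at <- function(tt) {
    i <- match(TRUE, abs(traj$time - tt) < 1e-9)
    traj[i, ]
  }
  chase <- purrr::map_dfr(pulse_duration + sample_times, at)
  ref_i <- switch(normalization$intracellular %||% "chase_start",
                  chase_start = at(pulse_duration)$S_i,
                  max = max(chase$S_i),
                  stop("unknown intracellular normalization", call. = FALSE))
  ref_x <- switch(normalization$extracellular %||% "max",
                  chase_start = at(pulse_duration)$S_x,
                  max = max(chase$S_x),
                  chase_start_intracellular = at(pulse_duration)$S_i,
                  stop("unknown extracellular normalization", call. = FALSE))
  if (ref_i <= 0) {
    stop("intracellular normalization reference is 0 (no labelled protein ",
         "at chase start; with tau >= pulse_duration the label has not yet ",
         "matured) - switch normalization mode to 'max'", call. = FALSE)
  }
  if (ref_x <= 0) {
    stop("extracellular normalization reference is 0 - switch normalization ",
         "mode", call. = FALSE)
  }
  tibble::tibble(time = sample_times,
                 intracellular = chase$S_i / ref_i,
                 extracellular = chase$S_x / ref_x)
}

#' Run an inhibitor treatment and report treated/control ratios
#'
#' Simulates the paired-arm design: control and treated cultures both get
#' fresh medium at t = 0 from constitutive steady state; the treated arm has
#' `target_param` reduced to `(1 - f)` of baseline. Returns the
#' treated/control ratios of extracellular (`R_x`) and intracellular (`R_i`)
#' sFLT1 at the end of the window.
#'
#' @param params Baseline [sflt_params()].
#' @param target_param Inhibited parameter name.
#' @param f Fractional inhibition in `[0, 1]`.
#' @param duration Media window, h (18 h matches the inhibitor experiments).
#' @return One-row tibble with columns `R_x`, `R_i`.
#' @export
run_inhibitor_treatment <- function(params, target_param = "k_out_Si", f = 0,
                                    duration = 18) {
  stopifnot(inherits(params, "sflt_params"))
  proto_t <- protocol_inhibitor_treatment(target_param, f, duration)
  proto_c <- protocol_inhibitor_treatment(target_param, 0, duration)
  tr_t <- simulate_secretion(params, proto_t, times = duration)
  tr_c <- simulate_secretion(params, proto_c, times = duration)
  tibble::tibble(R_x = tr_t$S_x / tr_c$S_x,
                 R_i = tr_t$S_i / tr_c$S_i)
}

# ---- protocol (de)serialization --------------------------------------------

#' Read or write a protocol as YAML
#'
#' Protocols are serialised as plain YAML so experiment designs can live in
#' version control next to data.
#'
#' @param path File path.
#' @return `read_protocol` returns an `sflt_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  sched <- NULL
  if (!is.null(y$production_schedule)) {
    sched <- tibble::tibble(
      time = vapply(y$production_schedule, function(s) as.numeric(s$time), 1),
      value = vapply(y$production_schedule, function(s) as.numeric(s$value), 1)
    )
  }
  inh <- lapply(y$inhibitions %||% list(), function(i) {
    list(parameter = i$parameter, fraction = as.numeric(i$fraction),
         onset = as.numeric(i$onset %||% 0))
  })
  new_protocol(
    kind = y$kind, horizon = as.numeric(y$horizon),
    production_schedule = sched,
    media_events = as.numeric(unlist(y$media_events %||% list())),
    inhibitions = inh,
    history = y$history %||% "steady_state",
    sample_times = as.numeric(unlist(y$sample_times %||% list())),
    S_x0 = if (!is.null(y$S_x0)) as.numeric(y$S_x0),
    pulse_duration = if (!is.null(y$pulse_duration)) as.numeric(y$pulse_duration),
    normalization = y$normalization
  )
}

#' @rdname read_protocol
#' @param protocol An `sflt_protocol`.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "sflt_protocol"))
  y <- unclass(protocol)
  if (!is.null(y$production_schedule)) {
    y$production_schedule <- purrr::pmap(y$production_schedule,
                                         function(time, value) {
                                           list(time = time, value = value)
                                         })
  }
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}
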