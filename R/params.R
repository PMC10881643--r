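#' Kinetic parameter set for the sFLT1 secretion model
#'
#' Bundles the five kinetic parameters of the two-compartment delay model of
#' constitutive sFLT1 secretion. Intracellular sFLT1 (`S_i`) is produced at
#' rate `k_prod` (after a synthesis-to-availability delay `tau` representing
#' ER-to-Golgi transit), then either secreted into the medium (`k_out_Si`) or
#' degraded intracellularly (`k_deg_Si`); extracellular sFLT1 (`S_x`) decays
#' at `k_deg_Sx`.
#'
#' @param k_prod Production rate, molecules cell^-1 h^-1. Must be >= 0.
#' @param tau Synthesis-to-availability delay, h. Must be >= 0.
#' @param k_out_Si First-order secretion rate constant, h^-1.
#' @param k_deg_Si First-order intracellular degradation rate constant, h^-1.
#' @param k_deg_Sx First-order extracellular degradation rate constant, h^-1.
#'
#' @return An object of class `sflt_params`: a named list of the five
#'   parameters, validated.
#'
#' @examples
#' p <- sflt_params(k_prod = 60000, tau = 0.5, k_out_Si = 0.5,
#'                  k_deg_Si = 0.5, k_deg_Sx = 0.01)
#' steady_state(p)
#' @export
sflt_params <- function(k_prod, tau, k_out_Si, k_deg_Si, k_deg_Sx) {
  p <- list(k_prod = k_prod, tau = tau, k_out_Si = k_out_Si,
            k_deg_Si = k_deg_Si, k_deg_Sx = k_deg_Sx)
  validate_sflt_params(p)
  structure(p, class = "sflt_params")
}

#' Names of the model parameters
#' @return Character vector of the five parameter names.
#' @export
param_names <- function() {
  c("k_prod", "tau", "k_out_Si", "k_deg_Si", "k_deg_Sx")
}

validate_sflt_params <- function(p) {
  nm <- param_names()
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (k in nm) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", k, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("parameter '", k, "' must be >= 0", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sflt_params <- function(x, ...) {
  cat("<sflt_params>\n")
  cat(sprintf("  k_prod   = %g molecules/cell/h\n", x$k_prod))
  cat(sprintf("  tau      = %g h\n", x$tau))
  cat(sprintf("  k_out_Si = %g /h\n", x$k_out_Si))
  cat(sprintf("  k_deg_Si = %g /h\n", x$k_deg_Si))
  cat(sprintf("  k_deg_Sx = %g /h\n", x$k_deg_Sx))
  invisible(x)
}

#' @export
as.data.frame.sflt_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

#' Tidy a parameter set into a one-row-per-parameter tibble
#'
#' @param x An `sflt_params` object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`, `unit`.
#' @export
tidy.sflt_params <- function(x, ...) {
  tibble::tibble(
    parameter = param_names(),
    value = vapply(param_names(), function(k) x[[k]], numeric(1)),
    unit = c("molecules/cell/h", "h", "1/h", "1/h", "1/h")
  )
}

#' Read a parameter set from a JSON file
#'
#' The file must be a JSON object with exactly the five keys `k_prod`, `tau`,
#' `k_out_Si`, `k_deg_Si`, `k_deg_Sx`. Unknown keys are rejected so that a
#' typo cannot silently fall back to a default.
#'
#' @param path Path to a JSON file.
#' @return An `sflt_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(obj), param_names())
  if (length(unknown) > 0) {
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "),
         "; valid keys are ", paste(param_names(), collapse = ", "),
         call. = FALSE)
  }
  do.call(sflt_params, as.list(obj)[param_names()])
}

#' Write a parameter set to a JSON file
#'
#' @param params An `sflt_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sflt_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Apply a named list of fractional inhibitions to a parameter set.
# Each entry scales the named parameter by (1 - f).
apply_inhibitions <- function(params, inhibitions) {
  if (length(inhibitions) == 0) return(params)
  p <- unclass(params)
  for (inh in inhibitions) {
    nm <- inh$parameter
    if (!nm %in% param_names()) {
      stop("unknown parameter '", nm, "'; valid names: ",
           paste(param_names(), collapse = ", "), call. = FALSE)
    }
    f <- inh$fraction
    if (!is.numeric(f) || f < 0 || f > 1) {
      stop("inhibition fraction must lie in [0, 1]", call. = FALSE)
    }
    p[[nm]] <- p[[nm]] * (1 - f)
  }
  structure(p, class = "sflt_params")
}
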