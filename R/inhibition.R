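# Fractional-inhibition analysis: the forward map from a fractional
# reduction of one rate parameter to the 18-h extracellular sFLT1 ratio, and
# its inverse. The inverse is how an observed fold change in conditioned
# media is translated into "this inhibitor blocks secretion by X%".

#' Sweep fractional inhibition of a rate parameter
#'
#' For each fraction f on the grid, simulates paired control/treated arms
#' ([run_inhibitor_treatment()]) and records the extracellular ratio `R_x`
#' at the end of the media window. For `target_param = "k_out_Si"` the curve
#' runs from (0, 1) to (1, 0) and is strictly decreasing.
#'
#' @param params Baseline [sflt_params()].
#' @param target_param Inhibited parameter name.
#' @param fractions Grid of fractions in `[0, 1]`.
#' @param duration Media window, h.
#' @return A tibble of class `sflt_sweep` with columns `fraction_inhibition`
#'   and `extracellular_ratio` (plus `intracellular_ratio`).
#' @export
inhibition_sweep <- function(params, target_param = "k_out_Si",
                             fractions = seq(0, 1, length.out = 101),
                             duration = 18) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("inhibition fractions must lie in [0, 1]", call. = FALSE)
  }
  rows <- purrr::map_dfr(fractions, function(f) {
    run_inhibitor_treatment(params, target_param, f, duration)
  })
  out <- tibble::tibble(fraction_inhibition = fractions,
                        extracellular_ratio = rows$R_x,
                        intracellular_ratio = rows$R_i)
  attr(out, "target_param") <- target_param
  attr(out, "duration") <- duration
  class(out) <- c("sflt_sweep", class(out))
  out
}

#' Invert an observed extracellular ratio into a fractional inhibition
#'
#' Finds the fractional inhibition f of `target_param` whose simulated
#' treated/control extracellular ratio at the end of the media window equals
#' the observed ratio. The map f -> R_x is monotone decreasing for the
#' supported targets, so the root is isolated by bisection (robust, no
#' derivatives) to `|R_x(f) - observed| < tol`.
#'
#' @param params Baseline [sflt_params()].
#' @param observed_R_x Observed treated/control extracellular ratio in
#'   `[0, 1]`.
#' @param target_param Inhibited parameter name. The analysis is routinely
#'   applied to `"k_out_Si"`; other rate parameters are supported but their
#'   ratio maps need not span `[0, 1]`.
#' @param duration Media window, h.
#' @param tol Bisection tolerance on `R_x`.
#' @return The fractional inhibition f in `[0, 1]`.
#' @examples
#' p <- sflt_params(60000, 0.5, 0.5, 0.5, 0.01)
#' invert_inhibition(p, observed_R_x = 0.4)
#' @export
invert_inhibition <- function(params, observed_R_x,
                              target_param = "k_out_Si", duration = 18,
                              tol = 1e-8) {
  stopifnot(inherits(params, "sflt_params"))
  if (!is.numeric(observed_R_x) || length(observed_R_x) != 1 ||
      !is.finite(observed_R_x)) {
    stop("observed_R_x must be a single finite number", call. = FALSE)
  }
  if (observed_R_x > 1) {
    stop("observed_R_x > 1: inhibition of '", target_param,
         "' cannot raise extracellular sFLT1 above control", call. = FALSE)
  }
  if (observed_R_x < 0) stop("observed_R_x must be >= 0", call. = FALSE)

  rx <- function(f) {
    run_inhibitor_treatment(params, target_param, f, duration)$R_x
  }
  r0 <- rx(0)
  r1 <- rx(1)
  if (!(r1 < r0)) {
    stop("ratio map for target '", target_param,
         "' is not decreasing on [0, 1]; inversion undefined", call. = FALSE)
  }
  if (abs(observed_R_x - r0) <= tol) return(0)
  if (abs(observed_R_x - r1) <= tol) return(1)
  if (observed_R_x > r0 || observed_R_x < r1) {
    stop("observed_R_x = ", observed_R_x, " is outside the attainable range [",
         signif(r1, 6), ", ", signif(r0, 6), "] for target '", target_param,
         "'", call. = FALSE)
  }
  lo <- 0; hi <- 1
  r_lo <- r0
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    r_mid <- rx(mid)
    if (abs(r_mid - observed_R_x) < tol) return(mid)
    if (r_mid > observed_R_x) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * 4) break
  }
  (lo + hi) / 2
}
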