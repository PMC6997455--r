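#' Empirical calibration of the reactor twin
#'
#' Houses the empirical constants that tie the simulated reactor to the
#' characterized physical system: the linear gold-shell growth law, the
#' unimodal 585 nm transmission response to gold-precursor flowrate, the
#' detector noise scale, droplet generation frequency, and the operational
#' limits (secondary-droplet ceiling, free-gold side-product onset).
#'
#' Defaults anchor the shell-growth slope so that the characterized optimum
#' flowrate of 9.7 uL/min yields a 3.5 nm shell, and centre the transmission
#' minimum at that same optimum.
#'
#' @param shell_slope Gold-shell growth per unit flowrate, nm/(uL/min).
#' @param response_center Flowrate of minimum transmission, uL/min.
#' @param response_amplitude Peak added absorbance (decadic) at the response
#'   centre, dimensionless.
#' @param response_width Gaussian width of the absorbance response, uL/min.
#' @param baseline_transmission Transmission of the oil/carrier phase as a
#'   fraction of detector full scale.
#' @param trace_noise_sd Additive Gaussian noise on trace samples, fraction of
#'   full scale.
#' @param droplet_frequency Droplet generation rate, droplets/min.
#' @param secondary_droplet_limit Injection flowrate above which satellite
#'   droplets of pure reagent form, uL/min.
#' @param side_product_onset Gold flowrate above which free gold nanoparticles
#'   form as a side product, uL/min.
#' @param core_diameter_mean,core_diameter_sd Iron oxide core size model, nm.
#' @param shell_thickness_sd Spread of shell thickness at fixed flowrate, nm.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(shell_slope = 3.5 / 9.7,
                              response_center = 9.7,
                              response_amplitude = 0.5,
                              response_width = 5,
                              baseline_transmission = 0.95,
                              trace_noise_sd = 0.01,
                              droplet_frequency = 60,
                              secondary_droplet_limit = 30,
                              side_product_onset = 12,
                              core_diameter_mean = 5.8,
                              core_diameter_sd = 1.4,
                              shell_thickness_sd = 0.6) {
  if (shell_slope <= 0) stop("shell_slope must be positive", call. = FALSE)
  if (response_width <= 0) stop("response_width must be positive", call. = FALSE)
  if (baseline_transmission <= 0 || baseline_transmission > 1)
    stop("baseline_transmission must lie in (0, 1]", call. = FALSE)
  if (trace_noise_sd < 0) stop("trace_noise_sd must be non-negative", call. = FALSE)
  if (droplet_frequency <= 0) stop("droplet_frequency must be positive", call. = FALSE)
  if (secondary_droplet_limit <= 0)
    stop("secondary_droplet_limit must be positive", call. = FALSE)
  structure(
    list(shell_slope = shell_slope,
         response_center = response_center,
         response_amplitude = response_amplitude,
         response_width = response_width,
         baseline_transmission = baseline_transmission,
         trace_noise_sd = trace_noise_sd,
         droplet_frequency = droplet_frequency,
         secondary_droplet_limit = secondary_droplet_limit,
         side_product_onset = side_product_onset,
         core_diameter_mean = core_diameter_mean,
         core_diameter_sd = core_diameter_sd,
         shell_thickness_sd = shell_thickness_sd),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model>\n")
  cat(sprintf("  shell growth: %.4f nm/(uL/min), zero intercept\n", x$shell_slope))
  cat(sprintf("  transmission dip: centre %g uL/min, amplitude %g AU, width %g uL/min\n",
              x$response_center, x$response_amplitude, x$response_width))
  cat(sprintf("  baseline %g, trace noise sd %g, %g droplets/min\n",
              x$baseline_transmission, x$trace_noise_sd, x$droplet_frequency))
  invisible(x)
}

#' Gold-shell thickness at a given precursor flowrate
#'
#' Linear growth law with zero intercept: shell thickness is proportional to
#' the per-junction gold-precursor flowrate, with the slope anchored so the
#' characterized optimum (9.7 uL/min) yields a 3.5 nm shell under defaults.
#'
#' @param q_gold Gold-precursor flowrate, uL/min (scalar or vector).
#' @param cal A [calibration_model()].
#' @return Shell thickness in nm.
#' @examples
#' shell_thickness(9.7, calibration_model())  # 3.5 nm
#' @export
shell_thickness <- function(q_gold, cal = calibration_model()) {
  if (any(q_gold < 0)) stop("q_gold must be non-negative", call. = FALSE)
  cal$shell_slope * q_gold
}

#' Per-droplet optical transmission at 585 nm
#'
#' Beer-Lambert transmission of a droplet carrying core-shell particles grown
#' at gold flowrate `q_gold`. The added absorbance is a Gaussian in flowrate
#' centred on the calibrated optimum, so the noiseless response has exactly
#' one transmission minimum on the operating range:
#' \deqn{T(q) = T_0 \, 10^{-A \exp(-(q - q_c)^2 / (2 w^2))}}
#'
#' @param q_gold Gold-precursor flowrate, uL/min (scalar or vector), within
#'   `[0, q_max]`.
#' @param cal A [calibration_model()].
#' @param noise_sd Optional additive Gaussian noise sd (fraction of full
#'   scale); default 0 gives the deterministic response.
#' @param q_max Upper end of the valid flowrate range, uL/min.
#' @return Transmission as a fraction of full scale.
#' @export
droplet_transmission <- function(q_gold, cal = calibration_model(),
                                 noise_sd = 0, q_max = 30) {
  if (any(q_gold < 0) || any(q_gold > q_max))
    stop(sprintf("q_gold must lie within [0, %g]", q_max), call. = FALSE)
  absorbance <- cal$response_amplitude *
    exp(-(q_gold - cal$response_center)^2 / (2 * cal$response_width^2))
  t <- cal$baseline_transmission * 10^(-absorbance)
  if (noise_sd > 0) t <- t + stats::rnorm(length(t), 0, noise_sd)
  t
}
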