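#' Transmission trace container
#'
#' A photodetector time series: intensity as a fraction of full scale sampled
#' at a fixed rate. The oil carrier transmits near full scale; droplet
#' passages appear as rectangular dips to the droplet's transmission.
#'
#' @param intensities Numeric vector of intensity samples (fraction of full
#'   scale).
#' @param sampling_rate Sampling rate in Hz.
#' @param start_time Time of the first sample, minutes on the run clock.
#' @return An object of class `transmission_trace`.
#' @export
transmission_trace <- function(intensities, sampling_rate, start_time = 0) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive", call. = FALSE)
  if (!is.numeric(intensities)) stop("intensities must be numeric", call. = FALSE)
  structure(list(intensities = as.numeric(intensities),
                 sampling_rate = sampling_rate,
                 start_time = start_time),
            class = "transmission_trace")
}

#' @export
print.transmission_trace <- function(x, ...) {
  cat(sprintf(
    "<transmission_trace> %d samples @ %g Hz (%.2f min), range [%.3f, %.3f]\n",
    length(x$intensities), x$sampling_rate,
    length(x$intensities) / x$sampling_rate / 60,
    min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
length.transmission_trace <- function(x) length(x$intensities)

#' Synthesize a detector trace for a droplet train
#'
#' Renders the transmission signal the detector would record while the train
#' passes: a baseline at the carrier transmission, interrupted once per
#' droplet by a dip to that droplet's transmission ([droplet_transmission()]).
#' Each dip lasts the droplet's passage time (droplet length over local
#' linear velocity, equivalently droplet volume over total volumetric flow at
#' the detector) and sits centred in its generation period. Dip edges are
#' smoothed with a 3-sample linear ramp placed inside the dip, so the
#' inter-droplet gap retains full-scale baseline samples. Optional additive
#' Gaussian noise (`cal$trace_noise_sd`) is applied per sample.
#'
#' @param train A fully injected `droplet_train`.
#' @param q_gold Per-junction gold flowrate the train was injected at, uL/min.
#' @param cal A [calibration_model()].
#' @param flows A [flow_settings()]; with `q_gold`, sets the total flow at the
#'   detector and hence passage times.
#' @param sampling_rate Detector sampling rate, Hz (>= 10).
#' @param duration Trace duration, minutes (> 0).
#' @param seed Optional integer seed for the noise stream.
#' @param noise If `FALSE`, suppress noise regardless of the calibration.
#' @param start_time Run-clock time of the first sample, minutes.
#' @return A [transmission_trace()] with attributes `droplet_value` (the
#'   deterministic per-droplet transmission) and `n_droplets` (dips rendered).
#' @export
synth_trace <- function(train, q_gold, cal = calibration_model(),
                        flows = flow_settings(), sampling_rate = 50,
                        duration = 2, seed = NULL, noise = TRUE,
                        start_time = 0) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (sampling_rate < 10) stop("sampling_rate must be at least 10 Hz", call. = FALSE)
  n_samples <- round(duration * 60 * sampling_rate)
  total_flow <- dispersed_flow(flows) + flows$q_oil + 3 * q_gold
  if (total_flow <= 0) stop("stagnation: zero total flow at detector", call. = FALSE)

  value <- droplet_transmission(q_gold, cal)
  x <- rep(cal$baseline_transmission, n_samples)
  k <- min(nrow(train), floor(duration * cal$droplet_frequency))
  period <- sampling_rate * 60 / cal$droplet_frequency        # samples/droplet
  if (k > 0) {
    passage_min <- train$volume[1] / total_flow
    passage <- round(passage_min * 60 * sampling_rate)
    if (passage < 2)
      warning("droplet passage shorter than 2 samples: trace under-resolved",
              call. = FALSE)
    passage <- max(passage, 1L)
    ramp_w <- c(0.75, 0.5, 0.25)  # weight on baseline, entering the dip
    for (i in seq_len(k)) {
      a <- round((i - 1) * period + (period - passage) / 2) + 1L
      b <- a + passage - 1L
      a <- max(a, 1L); b <- min(b, n_samples)
      if (b < a) next
      x[a:b] <- value
      if (passage >= 7) {
        x[a:(a + 2L)] <- value + (cal$baseline_transmission - value) * ramp_w
        x[b:(b - 2L)] <- value + (cal$baseline_transmission - value) * ramp_w
      }
    }
  }
  if (noise && cal$trace_noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + stats::rnorm(n_samples, 0, cal$trace_noise_sd)
    x <- pmin(pmax(x, 0), 1 + 5 * cal$trace_noise_sd)
  }
  tr <- transmission_trace(x, sampling_rate, start_time)
  attr(tr, "droplet_value") <- value
  attr(tr, "n_droplets") <- k
  tr
}
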