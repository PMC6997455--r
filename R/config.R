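#' Default reactor configuration
#'
#' Complete configuration of the digital twin and its closed loop: reactor
#' geometry, flowrates, empirical calibration, detector settings and
#' optimizer settings. [read_config()] loads a YAML file with the same
#' nested structure and fills any omitted entry from these defaults.
#'
#' @return A nested list of class `dropletwin_config` with elements
#'   `geometry`, `flows`, `calibration`, `detector`, `optimizer`.
#' @export
default_config <- function() {
  structure(list(
    geometry = list(tubing_length = 190, inner_diameter = 0.51,
                    droplet_junction_pos = 15,
                    injection_junction_pos = c(100, 130, 160),
                    detector_pos = 190),
    flows = list(q_aqueous_1 = 10, q_aqueous_2 = 10, q_oil = 10,
                 q_gold_max = 30),
    calibration = list(shell_slope = 3.5 / 9.7, response_center = 9.7,
                       response_amplitude = 0.5, response_width = 5,
                       baseline_transmission = 0.95, trace_noise_sd = 0.01,
                       droplet_frequency = 60, secondary_droplet_limit = 30,
                       side_product_onset = 12, core_diameter_mean = 5.8,
                       core_diameter_sd = 1.4, shell_thickness_sd = 0.6),
    detector = list(sampling_rate = 50, window_min = 2),
    optimizer = list(guess = 5, step = 2, min_step = 0.1, bounds = c(1, 30),
                     max_iterations = 50, contraction = 0.5)),
    class = "dropletwin_config")
}

#' Read a reactor configuration from YAML
#'
#' @param path Path to a YAML file with any subset of the
#'   [default_config()] tables (`geometry`, `flows`, `calibration`,
#'   `detector`, `optimizer`); missing entries keep their defaults.
#' @return A `dropletwin_config` list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (tab in intersect(names(cfg), names(user))) {
    cfg[[tab]] <- utils::modifyList(cfg[[tab]], user[[tab]])
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    warning("ignoring unknown config tables: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  cfg
}

#' @export
print.dropletwin_config <- function(x, ...) {
  cat("<dropletwin_config>\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Build the twin's domain objects from a configuration
#'
#' @param config A `dropletwin_config`.
#' @param q_gold Gold flowrate to set on the returned [flow_settings()].
#' @return `config_geometry()`: a [reactor_geometry()];
#'   `config_flows()`: a [flow_settings()];
#'   `config_calibration()`: a [calibration_model()].
#' @export
config_geometry <- function(config) do.call(reactor_geometry, config$geometry)

#' @rdname config_geometry
#' @export
config_flows <- function(config, q_gold = 0)
  do.call(flow_settings, c(config$flows, list(q_gold = q_gold)))

#' @rdname config_geometry
#' @export
config_calibration <- function(config) do.call(calibration_model, config$calibration)
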