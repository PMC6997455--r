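#' Reactor geometry
#'
#' Describes the capillary droplet reactor as positions along a single piece
#' of tubing: the droplet-generating junction, three downstream reagent
#' injection junctions, and the optical detector at the outlet. Together with
#' the tubing bore these positions define the transit volumes that set
#' residence times under plug flow.
#'
#' @param tubing_length Total tubing length in cm.
#' @param inner_diameter Tubing bore in mm.
#' @param droplet_junction_pos Position of the droplet-generation junction, cm.
#' @param injection_junction_pos Positions of the three reagent-injection
#'   junctions, cm, strictly increasing and downstream of the droplet junction.
#' @param detector_pos Position of the transmission detector, cm; at or beyond
#'   the last injection junction and within the tubing.
#'
#' @return An object of class `reactor_geometry`.
#' @examples
#' geom <- reactor_geometry()
#' cross_section_ul_per_cm(geom)
#' @export
reactor_geometry <- function(tubing_length = 190,
                             inner_diameter = 0.51,
                             droplet_junction_pos = 15,
                             injection_junction_pos = c(100, 130, 160),
                             detector_pos = 190) {
  stopifnot(is.numeric(tubing_length), length(tubing_length) == 1L,
            is.numeric(inner_diameter), length(inner_diameter) == 1L,
            is.numeric(droplet_junction_pos), length(droplet_junction_pos) == 1L,
            is.numeric(injection_junction_pos), length(injection_junction_pos) == 3L,
            is.numeric(detector_pos), length(detector_pos) == 1L)
  if (inner_diameter <= 0)
    stop("inner_diameter must be positive (mm)", call. = FALSE)
  if (droplet_junction_pos <= 0 || droplet_junction_pos >= min(injection_junction_pos))
    stop("droplet junction must lie strictly between inlet and first injection junction",
         call. = FALSE)
  if (any(diff(injection_junction_pos) <= 0))
    stop("injection junction positions must be strictly increasing", call. = FALSE)
  if (detector_pos < max(injection_junction_pos) || detector_pos > tubing_length)
    stop("detector must lie at or beyond the last injection junction, within the tubing",
         call. = FALSE)
  structure(
    list(tubing_length = tubing_length,
         inner_diameter = inner_diameter,
         droplet_junction_pos = droplet_junction_pos,
         injection_junction_pos = injection_junction_pos,
         detector_pos = detector_pos),
    class = "reactor_geometry")
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat("<reactor_geometry>\n")
  cat(sprintf("  tubing: %g cm x %g mm ID (%.3f uL/cm)\n",
              x$tubing_length, x$inner_diameter, cross_section_ul_per_cm(x)))
  cat(sprintf("  droplet junction: %g cm; injections: %s cm; detector: %g cm\n",
              x$droplet_junction_pos,
              paste(x$injection_junction_pos, collapse = ", "),
              x$detector_pos))
  invisible(x)
}

#' Tubing hold-up per unit length
#'
#' Cross-sectional area of the tubing expressed as microlitres of hold-up per
#' centimetre, the conversion factor between tubing length and transit volume.
#'
#' @param geom A [reactor_geometry()].
#' @return Hold-up in uL/cm.
#' @export
cross_section_ul_per_cm <- function(geom) {
  r_cm <- (geom$inner_diameter / 10) / 2
  pi * r_cm^2 * 1000  # cm^3 -> uL
}

#' Flow settings
#'
#' Volumetric flowrates driving the reactor: the two aqueous dispersed-phase
#' streams (iron precursor and ammonia) that form droplets, the carrier oil,
#' and the gold-precursor injection rate shared by all three injection
#' junctions.
#'
#' @param q_aqueous_1,q_aqueous_2 Aqueous stream flowrates, uL/min.
#' @param q_oil Carrier (continuous phase) oil flowrate, uL/min.
#' @param q_gold Gold-precursor flowrate per injection junction, uL/min.
#' @param q_gold_max Configured ceiling on `q_gold`, uL/min.
#' @return An object of class `flow_settings`.
#' @export
flow_settings <- function(q_aqueous_1 = 10, q_aqueous_2 = 10,
                          q_oil = 10, q_gold = 0, q_gold_max = 30) {
  rates <- c(q_aqueous_1, q_aqueous_2, q_oil, q_gold)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all flowrates must be finite and non-negative", call. = FALSE)
  if (q_gold > q_gold_max)
    stop(sprintf("q_gold (%g) exceeds configured maximum (%g uL/min)",
                 q_gold, q_gold_max), call. = FALSE)
  structure(
    list(q_aqueous_1 = q_aqueous_1, q_aqueous_2 = q_aqueous_2,
         q_oil = q_oil, q_gold = q_gold, q_gold_max = q_gold_max),
    class = "flow_settings")
}

#' @export
print.flow_settings <- function(x, ...) {
  cat(sprintf(
    "<flow_settings> aq1 %g + aq2 %g + oil %g uL/min; gold %g uL/min/junction (max %g)\n",
    x$q_aqueous_1, x$q_aqueous_2, x$q_oil, x$q_gold, x$q_gold_max))
  invisible(x)
}

#' Dispersed-phase flowrate
#'
#' @param flows A [flow_settings()].
#' @return Sum of the aqueous stream flowrates, uL/min.
#' @export
dispersed_flow <- function(flows) flows$q_aqueous_1 + flows$q_aqueous_2

#' Piecewise total flow along the tubing
#'
#' The total volumetric flow is piecewise constant between junctions: it is
#' the dispersed plus oil flow from the droplet junction, and gains one
#' `q_gold` increment at each injection junction.
#'
#' @param geom A [reactor_geometry()].
#' @param flows A [flow_settings()].
#' @return A data.frame with columns `start`, `end` (cm) and `flow` (uL/min).
#' @export
flow_profile <- function(geom, flows) {
  base <- dispersed_flow(flows) + flows$q_oil
  starts <- c(0, geom$droplet_junction_pos, geom$injection_junction_pos)
  ends <- c(geom$droplet_junction_pos, geom$injection_junction_pos,
            geom$tubing_length)
  # only oil flows upstream of the droplet junction
  data.frame(start = starts, end = ends,
             flow = c(flows$q_oil, base + flows$q_gold * (0:3)))
}

#' Plug-flow transit time between two positions
#'
#' Time for a droplet to travel between two tubing positions under plug flow:
#' the hold-up volume of each traversed segment divided by the total
#' volumetric flow prevailing there, summed over segments. Additive over
#' adjacent intervals.
#'
#' @param geom A [reactor_geometry()].
#' @param flows A [flow_settings()].
#' @param from_pos,to_pos Positions in cm, `from_pos <= to_pos`, both at or
#'   downstream of the droplet junction and within the tubing.
#' @return Transit time in minutes.
#' @examples
#' geom <- reactor_geometry()
#' flows <- flow_settings()  # 30 uL/min total before the first injection
#' transit_time(geom, flows, 15, 100)  # ~5.79 min
#' @export
transit_time <- function(geom, flows, from_pos, to_pos) {
  if (from_pos > to_pos)
    stop("from_pos must not exceed to_pos", call. = FALSE)
  if (from_pos < 0 || to_pos > geom$tubing_length)
    stop("positions must lie within the tubing", call. = FALSE)
  prof <- flow_profile(geom, flows)
  ul_per_cm <- cross_section_ul_per_cm(geom)
  total <- 0
  for (i in seq_len(nrow(prof))) {
    lo <- max(from_pos, prof$start[i])
    hi <- min(to_pos, prof$end[i])
    if (hi <= lo) next
    if (prof$flow[i] <= 0)
      stop(sprintf("stagnation: zero flow in segment [%g, %g] cm",
                   prof$start[i], prof$end[i]), call. = FALSE)
    total <- total + (hi - lo) * ul_per_cm / prof$flow[i]
  }
  total
}
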