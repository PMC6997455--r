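#' Size-distribution statistics of a particle batch
#'
#' Sample means and standard deviations (n - 1 denominator) of core
#' diameter, shell thickness and total diameter.
#'
#' @param particles A `particle_table` from [sample_particles()] (columns
#'   `core_nm`, `shell_nm`, `total_nm`); must be non-empty.
#' @return A `size_summary` list: `core_mean`, `core_sd`, `shell_mean`,
#'   `shell_sd`, `total_mean`, `total_sd`, `n`.
#' @export
size_statistics <- function(particles) {
  if (!nrow(particles)) stop("empty particle table", call. = FALSE)
  sd1 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  structure(list(
    core_mean = mean(particles$core_nm), core_sd = sd1(particles$core_nm),
    shell_mean = mean(particles$shell_nm), shell_sd = sd1(particles$shell_nm),
    total_mean = mean(particles$total_nm), total_sd = sd1(particles$total_nm),
    n = nrow(particles)), class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf(
    "<size_summary> n = %d\n  core  %.2f +/- %.2f nm\n  shell %.2f +/- %.2f nm\n  total %.2f +/- %.2f nm\n",
    x$n, x$core_mean, x$core_sd, x$shell_mean, x$shell_sd,
    x$total_mean, x$total_sd))
  invisible(x)
}

#' Calibrate shell growth against flowrate
#'
#' Ordinary least squares fit of shell thickness on gold-precursor flowrate,
#' the software counterpart of the post-synthesis TEM calibration curve.
#'
#' @param flowrate Gold flowrates, uL/min (at least two distinct values).
#' @param thickness Matching shell thicknesses, nm.
#' @return A list: `slope` (nm per uL/min), `intercept` (nm), `r_squared`.
#' @export
fit_shell_vs_flowrate <- function(flowrate, thickness) {
  if (length(flowrate) != length(thickness))
    stop("flowrate and thickness must have equal length", call. = FALSE)
  if (length(unique(flowrate)) < 2)
    stop("degenerate fit: need at least two distinct flowrates", call. = FALSE)
  fit <- stats::lm(thickness ~ flowrate)
  tss <- sum((thickness - mean(thickness))^2)
  # computed directly: summary.lm() warns on exact calibration data
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Gold mass fraction of a core-shell sphere
#'
#' Geometric composition from the spherical core-shell model: shell mass
#' over total mass given the two bulk densities. This is a geometric
#' idealization (bulk densities, perfectly concentric full-density shell)
#' and is not expected to match elemental spectroscopy on real particles.
#'
#' @param core_diameter Core diameter, nm.
#' @param shell_thickness Shell thickness, nm; may be 0.
#' @param core_density,shell_density Bulk densities, g/cm^3 (defaults:
#'   magnetite 5.17, gold 19.3).
#' @return Mass fraction of the shell, in `[0, 1)`.
#' @examples
#' gold_mass_fraction(5.8, 3.5)  # ~0.973
#' @export
gold_mass_fraction <- function(core_diameter, shell_thickness,
                               core_density = 5.17, shell_density = 19.3) {
  if (any(core_diameter <= 0) || any(shell_thickness < 0) ||
      any(core_density <= 0) || any(shell_density <= 0))
    stop("sizes must be positive (shell may be zero) and densities positive",
         call. = FALSE)
  r <- core_diameter / 2
  R <- r + shell_thickness
  shell_mass <- shell_density * (R^3 - r^3)   # 4/3 pi cancels
  core_mass <- core_density * r^3
  shell_mass / (shell_mass + core_mass)
}

#' Fixed-width histogram of particle sizes
#'
#' Left-closed, right-open bins of width `bin_width`, anchored at the
#' integer floor of the smallest value and extending to the integer ceiling
#' of the largest, so counts always sum to the sample size.
#'
#' @param values Numeric vector of sizes, nm (non-empty).
#' @param bin_width Bin width, nm (> 0).
#' @return A data.frame with `bin_left`, `bin_right` and `count`.
#' @examples
#' size_histogram(c(1.0, 1.5, 2.0), 1)  # counts 2, 1
#' @export
size_histogram <- function(values, bin_width) {
  if (!length(values)) stop("empty values", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  lo <- floor(min(values))
  hi <- ceiling(max(values))
  breaks <- seq(lo, hi + bin_width, by = bin_width)
  idx <- findInterval(values, breaks)  # [breaks[i], breaks[i+1])
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  keep <- seq_len(max(idx))
  data.frame(bin_left = breaks[keep], bin_right = breaks[keep + 1L],
             count = counts[keep])
}
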