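#' Sample core-shell particle sizes
#'
#' Draws per-particle sizes from the calibrated distribution model: iron
#' oxide core diameters are Normal(5.8, 1.4^2) nm under defaults (the TEM
#' characterization at the optimum flowrate), gold-shell thicknesses are
#' Normal around the growth law [shell_thickness()] with sd 0.6 nm, and the
#' total diameter is computed exactly as core plus twice the shell. Both
#' normals are truncated at a small positive floor by resampling.
#'
#' @param n Number of particles (positive integer).
#' @param q_gold Gold-precursor flowrate the batch was synthesized at, uL/min.
#' @param cal A [calibration_model()].
#' @param seed Optional integer seed.
#' @param floor_nm Positive truncation floor, nm.
#' @return A `particle_table` data.frame with columns `core_nm`, `shell_nm`,
#'   `total_nm`.
#' @examples
#' p <- sample_particles(1000, 9.7, calibration_model(), seed = 1)
#' colMeans(p)  # core ~5.8, shell ~3.5, total ~12.8
#' @export
sample_particles <- function(n, q_gold, cal = calibration_model(),
                             seed = NULL, floor_nm = 0.1) {
  if (length(n) != 1L || n <= 0 || n != floor(n))
    stop("n must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  core <- rnorm_truncated(n, cal$core_diameter_mean, cal$core_diameter_sd, floor_nm)
  shell <- rnorm_truncated(n, shell_thickness(q_gold, cal), cal$shell_thickness_sd,
                           floor_nm)
  out <- data.frame(core_nm = core, shell_nm = shell,
                    total_nm = core + 2 * shell)
  class(out) <- c("particle_table", "data.frame")
  out
}

# Normal truncated below at `floor` by resampling the out-of-range draws.
rnorm_truncated <- function(n, mean, sd, floor) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < floor)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
  }
  x
}

#' @export
print.particle_table <- function(x, ...) {
  cat(sprintf(
    "<particle_table> %d particles: core %.2f nm, shell %.2f nm, total %.2f nm (means)\n",
    nrow(x), mean(x$core_nm), mean(x$shell_nm), mean(x$total_nm)))
  invisible(x)
}
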