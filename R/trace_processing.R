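#' Threshold separating droplet from carrier samples
#'
#' Midpoint of the 10th and 90th intensity percentiles. For a two-level
#' droplet/baseline signal this lands between the levels regardless of the
#' duty cycle, and is deterministic and explainable, which is why it is
#' preferred over histogram-shape methods here.
#'
#' @param trace A [transmission_trace()].
#' @return Threshold intensity (fraction of full scale).
#' @examples
#' tr <- transmission_trace(rep(c(0.4, 0.9), each = 50), 50)
#' estimate_threshold(tr)  # 0.65
#' @export
estimate_threshold <- function(trace) {
  x <- trace$intensities
  if (!length(x)) stop("empty trace", call. = FALSE)
  if (diff(range(x)) < 1e-9)
    stop("degenerate trace: constant intensity, no droplet/baseline contrast",
         call. = FALSE)
  q <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  mean(q)
}

#' Segment droplet passages out of a trace
#'
#' Finds maximal runs of consecutive samples strictly below the threshold;
#' runs shorter than `min_width` samples are discarded as noise spikes. The
#' per-segment mean intensity is computed after trimming `edge_trim` samples
#' from each end of the run (the edge-ramp width of the synthesized signal),
#' so transitional samples do not bias the droplet level; short runs keep at
#' least their central sample.
#'
#' @param trace A [transmission_trace()].
#' @param threshold Intensity threshold, normally from [estimate_threshold()].
#' @param min_width Minimum run length in samples.
#' @param edge_trim Samples trimmed from each run end before averaging.
#' @return A `droplet_segments` data.frame with `start_index`, `end_index`
#'   (inclusive sample indices), `n_samples` and `mean_intensity`; zero rows
#'   if nothing falls below threshold.
#' @export
segment_droplets <- function(trace, threshold, min_width = 3, edge_trim = 3) {
  below <- trace$intensities < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  starts <- starts[keep]; ends <- ends[keep]
  mean_intensity <- vapply(seq_along(starts), function(i) {
    a <- starts[i]; b <- ends[i]
    trim <- min(edge_trim, (b - a) %/% 2L)
    mean(trace$intensities[(a + trim):(b - trim)])
  }, numeric(1))
  out <- data.frame(start_index = starts, end_index = ends,
                    n_samples = ends - starts + 1L,
                    mean_intensity = mean_intensity)
  class(out) <- c("droplet_segments", "data.frame")
  out
}

#' Average droplet transmission over a collection window
#'
#' Unweighted mean of the per-segment mean intensities: the quantity fed to
#' the optimizer as its objective. Count and spread are reported alongside
#' for quality control and logging.
#'
#' @param segments A `droplet_segments` data.frame from [segment_droplets()].
#' @return A list with `mean`, `count` and `sd` (sd is 0 for a single
#'   segment).
#' @export
droplet_mean_transmission <- function(segments) {
  if (!nrow(segments))
    stop("no droplets detected in window", call. = FALSE)
  m <- segments$mean_intensity
  list(mean = mean(m), count = nrow(segments),
       sd = if (length(m) > 1) stats::sd(m) else 0)
}

#' Extract the windowed droplet average from a raw trace
#'
#' Convenience pipeline: threshold estimation, segmentation, averaging.
#'
#' @inheritParams segment_droplets
#' @return As [droplet_mean_transmission()], plus the `threshold` used.
#' @export
extract_droplet_signal <- function(trace, min_width = 3, edge_trim = 3) {
  thr <- estimate_threshold(trace)
  seg <- segment_droplets(trace, thr, min_width = min_width,
                          edge_trim = edge_trim)
  res <- droplet_mean_transmission(seg)
  res$threshold <- thr
  res
}
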