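#' Read and write the twin's tabular artefacts
#'
#' Plain CSV interchange for detector traces (`time_s`, `intensity`),
#' particle tables (`core_nm`, `shell_nm`, `total_nm`), droplet trains,
#' droplet segments (`start_s`, `end_s`, `mean_intensity`) and run logs.
#' Run logs can also be written as JSON lines, one evaluation per line.
#'
#' @param trace A [transmission_trace()].
#' @param path Output (or input) file path.
#' @return The writers return `path` invisibly; the readers return the
#'   rebuilt object.
#' @name dropletwin-io
NULL

#' @rdname dropletwin-io
#' @export
write_trace_csv <- function(trace, path) {
  t_s <- trace$start_time * 60 +
    (seq_along(trace$intensities) - 1) / trace$sampling_rate
  utils::write.csv(data.frame(time_s = t_s, intensity = trace$intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname dropletwin-io
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "intensity") %in% names(d)))
    stop("trace CSV needs columns time_s, intensity", call. = FALSE)
  rate <- if (nrow(d) > 1) 1 / stats::median(diff(d$time_s)) else 50
  transmission_trace(d$intensity, rate, start_time = d$time_s[1] / 60)
}

#' @rdname dropletwin-io
#' @param particles A `particle_table`.
#' @export
write_particles_csv <- function(particles, path) {
  utils::write.csv(as.data.frame(particles), path, row.names = FALSE)
  invisible(path)
}

#' @rdname dropletwin-io
#' @export
read_particles_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("core_nm", "shell_nm", "total_nm")
  if (!all(need %in% names(d)))
    stop("particle CSV needs columns core_nm, shell_nm, total_nm", call. = FALSE)
  d <- d[need]
  class(d) <- c("particle_table", "data.frame")
  d
}

#' @rdname dropletwin-io
#' @param train A `droplet_train`.
#' @export
write_droplets_csv <- function(train, path) {
  utils::write.csv(as.data.frame(train), path, row.names = FALSE)
  invisible(path)
}

#' @rdname dropletwin-io
#' @param segments A `droplet_segments` data.frame.
#' @param sampling_rate Sampling rate (Hz) used to convert indices to seconds.
#' @export
write_segments_csv <- function(segments, sampling_rate, path) {
  utils::write.csv(data.frame(
    start_s = (segments$start_index - 1) / sampling_rate,
    end_s = (segments$end_index - 1) / sampling_rate,
    mean_intensity = segments$mean_intensity), path, row.names = FALSE)
  invisible(path)
}

#' @rdname dropletwin-io
#' @param log A `run_log` data.frame from [run_closed_loop()].
#' @export
write_run_log_csv <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}

#' @rdname dropletwin-io
#' @export
write_run_log_jsonl <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(as.data.frame(log)[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
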