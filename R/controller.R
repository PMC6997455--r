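#' Run the closed self-optimization loop on the digital twin
#'
#' Reproduces the autonomous experiment in software. For each flowrate the
#' optimizer proposes, the controller (1) advances the simulated clock by the
#' plug-flow transit from the first injection junction to the detector plus
#' the collection window, (2) generates a droplet train for the window,
#' injects gold precursor at the three junctions, and synthesizes the
#' detector trace, (3) extracts the windowed droplet-mean transmission by
#' thresholding, and (4) feeds it to the optimizer — until the step size
#' contracts below its minimum or the iteration budget runs out. Every
#' evaluation is logged.
#'
#' A single root `seed` is split deterministically (via one `sample.int`
#' draw per potential evaluation, in evaluation order, with a second bank
#' reserved for retries) so identical seed and configuration give a
#' byte-identical run log. A window in which no droplet is detected is
#' retried once with its reserve sub-seed, then aborts with a diagnostic.
#'
#' @param config A [default_config()]-style `dropletwin_config`.
#' @param seed Integer root seed for all stochastic components.
#' @return A list: `par` (converged flowrate, uL/min), `value` (its mean
#'   droplet transmission), `iterations` (post-initialization evaluations),
#'   `converged`, `clock_min` (total simulated time), and `log`, a `run_log`
#'   data.frame with one row per evaluation.
#' @examples
#' \donttest{
#' res <- run_closed_loop(default_config(), seed = 1)
#' res$par  # ~9.7 uL/min
#' }
#' @export
run_closed_loop <- function(config = default_config(), seed = 1) {
  geom <- config_geometry(config)
  cal <- config_calibration(config)
  opt <- config$optimizer
  det <- config$detector
  window <- det$window_min

  set.seed(seed)
  n_bank <- opt$max_iterations + 2L
  subseeds <- sample.int(.Machine$integer.max - 1L, 2L * n_bank)

  st <- simplex_init(opt$guess, opt$step, opt$min_step, opt$bounds,
                     opt$contraction)
  clock <- 0
  log_rows <- vector("list", n_bank)
  eval_i <- 0L

  while (!st$converged && st$iteration_count < opt$max_iterations) {
    eval_i <- eval_i + 1L
    q <- st$current_point
    flows <- config_flows(config, q_gold = q)
    clock <- clock +
      transit_time(geom, flows, geom$injection_junction_pos[1],
                   geom$detector_pos) + window

    measure <- function(sub_seed) {
      train <- generate_droplets(flows, cal, window)
      train <- inject_all(train, q, cal)
      tr <- synth_trace(train, q, cal, flows,
                        sampling_rate = det$sampling_rate,
                        duration = window, seed = sub_seed)
      extract_droplet_signal(tr)
    }
    sig <- tryCatch(measure(subseeds[eval_i]), error = function(e) e)
    if (inherits(sig, "error")) {  # retry once on an empty window
      sig <- tryCatch(measure(subseeds[n_bank + eval_i]), error = function(e) e)
      if (inherits(sig, "error"))
        stop(sprintf(
          "closed loop aborted at evaluation %d (q = %g uL/min): %s",
          eval_i, q, conditionMessage(sig)), call. = FALSE)
    }

    st <- simplex_update(st, sig$mean)
    last <- st$history[nrow(st$history), ]
    log_rows[[eval_i]] <- data.frame(
      eval = eval_i, iteration = st$iteration_count, flowrate = q,
      droplet_count = sig$count, mean_transmission = sig$mean,
      sd_transmission = sig$sd, step = last$step, accepted = last$accepted,
      best_flowrate = st$best_point, clock_min = clock,
      seed_used = subseeds[eval_i], converged = st$converged)
  }

  log <- do.call(rbind, log_rows[seq_len(eval_i)])
  class(log) <- c("run_log", "data.frame")
  list(par = st$best_point, value = st$best_value,
       iterations = st$iteration_count, converged = st$converged,
       clock_min = clock, log = log)
}

#' @export
print.run_log <- function(x, ...) {
  if (all(c("best_flowrate", "converged") %in% names(x)) && nrow(x))
    cat(sprintf("<run_log> %d evaluations, final flowrate %.3g uL/min%s\n",
                nrow(x), x$best_flowrate[nrow(x)],
                if (isTRUE(x$converged[nrow(x)])) " (converged)" else ""))
  print.data.frame(x, ...)
  invisible(x)
}

#' Replicate the closed-loop experiment over seeds
#'
#' Runs [run_closed_loop()] once per seed and summarizes the dispersion of
#' the converged flowrates, the software analogue of repeating the physical
#' experiment to estimate setup accuracy.
#'
#' @param config A `dropletwin_config`.
#' @param seeds Integer vector of at least two root seeds.
#' @return A list: `runs` (per-seed data.frame with `seed`, `converged_q`,
#'   `iterations`, `converged`, `aborted`, `abort_reason`), and `mean`, `sd`
#'   of the converged flowrates over non-aborted runs.
#' @export
replicate_study <- function(config = default_config(), seeds) {
  if (length(seeds) < 2) stop("need at least 2 seeds", call. = FALSE)
  rows <- lapply(seeds, function(s) {
    res <- tryCatch(run_closed_loop(config, seed = s), error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(seed = s, converged_q = NA_real_, iterations = NA_integer_,
                 converged = FALSE, aborted = TRUE,
                 abort_reason = conditionMessage(res))
    } else {
      data.frame(seed = s, converged_q = res$par, iterations = res$iterations,
                 converged = res$converged, aborted = FALSE,
                 abort_reason = "")
    }
  })
  runs <- do.call(rbind, rows)
  ok <- runs$converged_q[!runs$aborted]
  list(runs = runs, mean = mean(ok), sd = stats::sd(ok))
}
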