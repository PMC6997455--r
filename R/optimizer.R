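#' One-dimensional step-contracting simplex search
#'
#' The reactor's self-optimization rule: evaluate two initial points, march
#' downhill with a fixed step in the direction of the better one, and once
#' the minimum has been passed (the first rejected proposal) contract the
#' step on every subsequent evaluation, reversing direction on each
#' rejection; terminate once the step falls below a minimum step size.
#' Contracting only after the first overshoot keeps the approach march fast
#' (its step is fixed by the initial guesses), while the geometric
#' contraction afterwards makes the number of refinement evaluations
#' essentially independent of measurement noise. Derivative-free and bounded
#' — every proposal is clamped to the operating range.
#'
#' `simplex_init()` builds the optimizer state; the two initial evaluation
#' points are `guess` and `guess + step` (clamped to bounds), and the march
#' direction is set toward the lower of the two once both are measured.
#' `simplex_update()` consumes one measured objective value and returns the
#' state carrying the next proposal in `$current_point`.
#'
#' @param guess First initial point, within `bounds` (uL/min in the reactor).
#' @param step Initial (maximum) step size; must exceed `min_step`.
#' @param min_step Convergence floor: the state is converged once the step
#'   contracts below this.
#' @param bounds Length-2 numeric, the closed operating range.
#' @param contraction Step multiplier (0 < c < 1) applied on every
#'   evaluation once the minimum has first been passed.
#' @return `simplex_init()`: an object of class `simplex_state` whose
#'   `$current_point` is the next point to measure.
#' @examples
#' st <- simplex_init(5, 2)
#' st$current_point            # 5, then 7 after the first update
#' @export
simplex_init <- function(guess, step, min_step = 0.1, bounds = c(1, 30),
                         contraction = 0.5) {
  if (length(bounds) != 2L || bounds[1] >= bounds[2])
    stop("bounds must be an ordered pair", call. = FALSE)
  if (guess < bounds[1] || guess > bounds[2])
    stop("initial guess outside bounds", call. = FALSE)
  if (min_step <= 0) stop("min_step must be positive", call. = FALSE)
  if (step <= min_step)
    stop("initial step must exceed min_step", call. = FALSE)
  if (contraction <= 0 || contraction >= 1)
    stop("contraction must lie in (0, 1)", call. = FALSE)
  p2 <- clamp(guess + step, bounds)
  structure(
    list(current_point = guess, best_point = NA_real_, best_value = Inf,
         step = step, direction = NA_integer_, min_step = min_step,
         bounds = bounds, contraction = contraction,
         init_points = c(guess, p2), phase = "init1",
         contracting = FALSE, iteration_count = 0L, converged = FALSE,
         history = data.frame(point = numeric(0), value = numeric(0),
                              step = numeric(0), accepted = logical(0),
                              phase = character(0))),
    class = "simplex_state")
}

clamp <- function(x, bounds) min(max(x, bounds[1]), bounds[2])

#' @rdname simplex_init
#' @param state A `simplex_state`.
#' @param measured_value Objective value measured at `state$current_point`;
#'   must be finite (a failed measurement should be retried by the caller,
#'   not fed to the optimizer).
#' @return `simplex_update()`: the updated `simplex_state`.
#' @export
simplex_update <- function(state, measured_value) {
  if (state$converged) stop("optimizer already converged", call. = FALSE)
  if (!is.finite(measured_value))
    stop("non-finite measurement: retry the measurement", call. = FALSE)
  pt <- state$current_point
  accepted <- FALSE
  if (state$phase == "init1") {
    state$best_point <- pt
    state$best_value <- measured_value
    accepted <- TRUE
    state$phase <- "init2"
    state$current_point <- state$init_points[2]
  } else if (state$phase == "init2") {
    if (measured_value < state$best_value) {
      state$best_point <- pt
      state$best_value <- measured_value
      accepted <- TRUE
      d <- sign(pt - state$init_points[1])
    } else {
      d <- sign(state$init_points[1] - pt)
    }
    state$direction <- if (d == 0) -1 else d
    state$phase <- "search"
    state$current_point <- clamp(state$best_point +
                                   state$direction * state$step, state$bounds)
  } else {
    state$iteration_count <- state$iteration_count + 1L
    if (measured_value < state$best_value) {  # ties count as not improved
      state$best_point <- pt
      state$best_value <- measured_value
      accepted <- TRUE
      if (state$contracting) state$step <- state$step * state$contraction
    } else {
      state$direction <- -state$direction
      state$step <- state$step * state$contraction
      state$contracting <- TRUE
    }
    if (state$step < state$min_step) state$converged <- TRUE
    state$current_point <- clamp(state$best_point +
                                   state$direction * state$step, state$bounds)
  }
  state$history <- rbind(state$history,
                         data.frame(point = pt, value = measured_value,
                                    step = state$step, accepted = accepted,
                                    phase = state$phase))
  state
}

#' @export
print.simplex_state <- function(x, ...) {
  cat(sprintf(
    "<simplex_state> phase %s, best %.4g (value %.4g), step %.4g, %d iterations%s\n",
    x$phase, x$best_point, x$best_value, x$step, x$iteration_count,
    if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Run the simplex search on an objective function
#'
#' Headless harness around [simplex_init()]/[simplex_update()]: repeatedly
#' evaluates `objective` at the proposed point and feeds the value back until
#' convergence or the iteration budget is exhausted. One iteration is one
#' objective evaluation after the two initial ones.
#'
#' @param objective A function of one numeric argument defined on `bounds`.
#' @inheritParams simplex_init
#' @param max_iterations Budget of post-initialization evaluations.
#' @return A list: `par` (converged point), `value`, `iterations`,
#'   `converged` (FALSE flags non-convergence at budget), `history`.
#' @examples
#' run_on_function(function(x) (x - 9.7)^2, guess = 5, step = 2)$par
#' @export
run_on_function <- function(objective, guess, step, min_step = 0.1,
                            bounds = c(1, 30), max_iterations = 100,
                            contraction = 0.5) {
  st <- simplex_init(guess, step, min_step, bounds, contraction)
  while (!st$converged && st$iteration_count < max_iterations) {
    st <- simplex_update(st, objective(st$current_point))
  }
  list(par = st$best_point, value = st$best_value,
       iterations = st$iteration_count, converged = st$converged,
       history = st$history)
}
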