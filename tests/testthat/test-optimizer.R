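test_that("initialization pairs the guess with guess + step, clamped", {
  st <- simplex_init(5, 2)
  expect_equal(st$init_points, c(5, 7))
  expect_equal(st$current_point, 5)
  expect_equal(simplex_init(29, 4, bounds = c(1, 30))$init_points, c(29, 30))
  expect_error(simplex_init(35, 2), "outside bounds")
  expect_error(simplex_init(5, 0.05, min_step = 0.1), "exceed min_step")
})

test_that("direction is set toward the lower of the two initial points", {
  st <- simplex_init(5, 2)
  st <- simplex_update(st, 0.60)   # f(5)
  expect_equal(st$current_point, 7)
  st <- simplex_update(st, 0.55)   # f(7) lower: march upward
  expect_equal(st$direction, 1)
  expect_equal(st$current_point, 9)

  st2 <- simplex_init(15, 3)
  st2 <- simplex_update(st2, 0.50)
  st2 <- simplex_update(st2, 0.58)  # f(18) higher: march downward
  expect_equal(st2$direction, -1)
  expect_equal(st2$current_point, 12)
})

test_that("acceptance keeps the step before the first overshoot", {
  # best 7 (0.60), current 9 measured 0.55: accept, next proposal 11
  st <- simplex_init(5, 2)
  st <- simplex_update(st, 0.62)
  st <- simplex_update(st, 0.60)
  st <- simplex_update(st, 0.55)
  expect_equal(st$best_point, 9)
  expect_equal(st$step, 2)
  expect_equal(st$current_point, 11)
})

test_that("rejection reverses and halves; refinement contracts every step", {
  # best 9 (0.55), current 11 measured 0.58, step 2: reject ->
  # direction -1, step 1, next proposal 8
  st <- simplex_init(5, 2)
  for (v in c(0.62, 0.60, 0.55)) st <- simplex_update(st, v)
  st <- simplex_update(st, 0.58)
  expect_false(st$history$accepted[nrow(st$history)])
  expect_equal(st$direction, -1)
  expect_equal(st$step, 1)
  expect_equal(st$current_point, 8)
  # once contracting, an accepted refinement halves the step too
  st <- simplex_update(st, 0.54)
  expect_true(st$history$accepted[nrow(st$history)])
  expect_equal(st$step, 0.5)
  expect_equal(st$current_point, 7.5)
})

test_that("convergence triggers when the step falls below the minimum", {
  st <- simplex_init(5, 0.15, min_step = 0.1)
  st <- simplex_update(st, 0.6)    # f(5)
  st <- simplex_update(st, 0.7)    # f(5.15): march downward from 5
  st <- simplex_update(st, 0.7)    # f(4.85) rejected: step 0.075 < 0.1
  expect_true(st$converged)
  expect_equal(st$step, 0.075)
  expect_equal(st$best_point, 5)
  expect_error(simplex_update(st, 0.5), "already converged")
  expect_error({s <- simplex_init(5, 2); simplex_update(s, NaN)}, "non-finite")
})

test_that("harness converges near the minimum of simple objectives", {
  r1 <- run_on_function(function(x) (x - 9.7)^2, 5, 2)
  expect_true(r1$converged)
  expect_lt(abs(r1$par - 9.7), 0.4)
  r2 <- run_on_function(function(x) abs(x - 15), 24, 4)
  expect_lt(abs(r2$par - 15), 0.4)
  # constant objective: ties never accepted, stays at the initial best
  r3 <- run_on_function(function(x) 1, 10, 2)
  expect_true(r3$converged)
  expect_equal(r3$par, 10)
  # budget exhaustion flags non-convergence
  r4 <- run_on_function(function(x) (x - 9.7)^2, 5, 2, max_iterations = 2)
  expect_false(r4$converged)
  expect_equal(r4$iterations, 2)
})

test_that("search matches a fine grid argmin on random unimodal quadratics", {
  set.seed(101)
  grid <- seq(1, 30, by = 0.01)
  worst <- 0
  for (i in 1:1000) {
    a <- runif(1, 0.1, 5)
    ctr <- runif(1, 2, 29)
    f <- function(x) a * (x - ctr)^2
    r <- run_on_function(f, runif(1, 1, 30), runif(1, 0.5, 5),
                         min_step = 0.1, max_iterations = 300)
    worst <- max(worst, abs(r$par - grid[which.min(f(grid))]))
  }
  expect_lte(worst, 4 * 0.1)
})

test_that("search trajectories satisfy the bookkeeping invariants", {
  set.seed(7)
  for (i in 1:50) {
    ctr <- runif(1, 2, 28)
    r <- run_on_function(function(x) (x - ctr)^2, runif(1, 1, 30),
                         runif(1, 0.5, 5), max_iterations = 300)
    h <- r$history
    expect_equal(nrow(h), r$iterations + 2)
    expect_true(all(h$point >= 1 & h$point <= 30))
    # step sequence non-increasing after the first rejection
    first_rej <- which(!h$accepted & h$phase == "search")[1]
    if (!is.na(first_rej))
      expect_true(all(diff(h$step[first_rej:nrow(h)]) <= 0))
    # monotone best value along the history
    expect_true(all(diff(cummin(h$value)) <= 0))
    best_so_far <- cummin(h$value)
    expect_equal(min(h$value), r$value)
  }
})
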