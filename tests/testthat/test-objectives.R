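# three equal voxels with doses 10/20/30 Gy: the hand-workable case used
# throughout (only the 30 Gy voxel exceeds a 20 Gy objective)
three_voxel <- function() {
  list(mask = toy_mask(1:3, 3), dose = c(10, 20, 30))
}

test_that("overdose penalty reproduces the hand-computed value", {
  tv <- three_voxel()
  obj <- objective("max_dose", tv$mask, dose_gy = 20, weight = 1)
  expect_equal(evaluate_objective(obj, tv$dose), ((30 - 20) / 20)^2 / 3,
               tolerance = 1e-12)
  # empty exceedance set
  expect_equal(evaluate_objective(obj, c(5, 10, 20)), 0)
  # uniform dose exactly at the objective
  u <- objective("uniform_dose", tv$mask, 20)
  expect_equal(evaluate_objective(u, rep(20, 3)), 0)
  # dvh_point shares the overdose form
  dv <- objective("dvh_point", tv$mask, 20, fractional_volume = 35)
  expect_equal(evaluate_objective(dv, tv$dose),
               evaluate_objective(obj, tv$dose))
})

test_that("each objective kind penalizes its own residual set", {
  m <- toy_mask(1:4, 4)
  dose <- c(5, 10, 15, 20)
  expect_equal(evaluate_objective(objective("min_dose", m, 12), dose),
               ((12 - 5)^2 + (12 - 10)^2) / 12^2 / 4, tolerance = 1e-12)
  expect_equal(evaluate_objective(objective("uniform_dose", m, 12), dose),
               sum(((dose - 12) / 12)^2) / 4, tolerance = 1e-12)
  expect_equal(evaluate_objective(objective("mean_dose", m, 10), dose),
               ((12.5 - 10) / 10)^2, tolerance = 1e-12)
  expect_equal(evaluate_objective(objective("mean_dose", m, 15), dose), 0)
  expect_error(objective("max_dose", m, dose_gy = 0), "> 0")
  expect_error(objective("dvh_point", m, 10), "fractional_volume")
})

test_that("weight scales the objective linearly", {
  set.seed(3)
  m <- toy_mask(1:20, 20)
  dose <- runif(20, 0, 40)
  for (kind in c("max_dose", "min_dose", "uniform_dose", "mean_dose")) {
    f1 <- evaluate_objective(objective(kind, m, 17), dose)
    f7 <- evaluate_objective(objective(kind, m, 17, weight = 7), dose)
    expect_equal(f7, 7 * f1, tolerance = 1e-12)
  }
})

test_that("gradients are exact against central finite differences", {
  tv <- three_voxel()
  obj <- objective("max_dose", tv$mask, 20)
  g <- objective_gradient(obj, tv$dose)
  expect_equal(g[3], 2 * 10 / 400 / 3, tolerance = 1e-12)
  expect_equal(g[1:2], c(0, 0))

  set.seed(4)
  kinds <- c("max_dose", "min_dose", "uniform_dose", "mean_dose",
             "dvh_point")
  h <- 1e-4
  for (rep in 1:100) {
    n <- 50
    kind <- kinds[(rep %% length(kinds)) + 1]
    dj <- runif(1, 5, 40)
    dose <- runif(n, 0, 2 * dj)
    # keep every voxel (and the mean) away from the penalty kink so the
    # quadratic is smooth across the difference stencil
    dose[abs(dose - dj) < 10 * h] <- dj + 11 * h
    if (kind == "mean_dose" && abs(mean(dose) - dj) < 10 * h) {
      dose <- dose + 20 * h
    }
    idx <- sort(sample(n, 30))
    m <- toy_mask(idx, n)
    obj <- objective(kind, m, dj, weight = runif(1, 0.1, 10),
                     fractional_volume = if (kind == "dvh_point") 50)
    g <- objective_gradient(obj, dose)
    probe <- sample(idx, 5)
    for (i in probe) {
      dp <- dose; dp[i] <- dp[i] + h
      dm <- dose; dm[i] <- dm[i] - h
      fd <- (evaluate_objective(obj, dp) - evaluate_objective(obj, dm)) /
        (2 * h)
      if (abs(fd) > 1e-12) {
        expect_equal(g[i], fd, tolerance = 1e-6)
      } else {
        expect_lt(abs(g[i]), 1e-10)
      }
    }
  }
})

test_that("composite objective is the plain sum with a per-objective breakdown", {
  tv <- three_voxel()
  obj <- objective("max_dose", tv$mask, 20)
  single <- composite_objective(list(obj), tv$dose)
  expect_equal(single$value, evaluate_objective(obj, tv$dose))
  doubled <- composite_objective(list(obj, obj), tv$dose)
  expect_equal(doubled$value, 2 * single$value)

  set.seed(5)
  n <- 40
  dose <- runif(n, 0, 50)
  objs <- list(
    objective("max_dose", toy_mask(1:15, n), 20),
    objective("min_dose", toy_mask(10:30, n), 30, weight = 3),
    objective("uniform_dose", toy_mask(20:40, n), 25, weight = 0.5)
  )
  total <- 0
  for (o in objs) total <- total + evaluate_objective(o, dose)
  comp <- composite_objective(objs, dose)
  expect_equal(comp$value, total, tolerance = 1e-12)
  expect_length(comp$breakdown, 3)
  gsum <- numeric(n)
  for (o in objs) gsum <- gsum + objective_gradient(o, dose, n)
  expect_equal(composite_gradient(objs, dose), gsum, tolerance = 1e-12)
})

test_that("solve_objective_dose inverts the overdose penalty", {
  tv <- three_voxel()
  obj <- objective("max_dose", tv$mask, 20)
  target <- ((30 - 20) / 20)^2 / 3
  sol <- solve_objective_dose(obj, tv$dose, target)
  expect_false(sol$floor)
  expect_equal(sol$dose_gy, 20, tolerance = 1e-3)

  # round-trip: evaluating at the root reproduces the target value
  set.seed(6)
  m <- toy_mask(1:60, 60)
  dose <- runif(60, 0, 40)
  obj <- objective("dvh_point", m, 10, fractional_volume = 35)
  for (target in c(0.5, 0.05, 0.005)) {
    sol <- solve_objective_dose(obj, dose, target)
    o2 <- obj; o2$dose_gy <- sol$dose_gy
    expect_equal(evaluate_objective(o2, dose), target,
                 tolerance = 1e-5)
  }
  # monotone: a larger target value forces a smaller objective dose
  roots <- vapply(c(0.01, 0.1, 1), function(tv2) {
    solve_objective_dose(obj, dose, tv2)$dose_gy
  }, numeric(1))
  expect_true(all(diff(roots) < 0))

  # fixed point: asking for the current value returns the current dose
  f_now <- evaluate_objective(obj, dose)
  sol <- solve_objective_dose(obj, dose, f_now)
  o2 <- obj; o2$dose_gy <- sol$dose_gy
  expect_equal(evaluate_objective(o2, dose), f_now, tolerance = 1e-5)

  # degenerate inputs: near-zero and all-zero structure dose
  cold <- solve_objective_dose(obj, rep(0.001, 60), 0.5)
  expect_true(cold$floor)
  expect_equal(cold$dose_gy, 0.01)
  zero <- solve_objective_dose(obj, rep(0, 60), 0.5)
  expect_true(zero$zero_dose)
  expect_error(solve_objective_dose(
    objective("min_dose", m, 10), dose, 0.5), "overdose")
})
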