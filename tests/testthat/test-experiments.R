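test_that("reconstruction splits hold out round-half-up fractions, keeping >= 1 point", {
  g <- generate_cohort(sim_config(n_children = 3, missing_prob = 0, seed = 1))
  ob <- child_obs(g$cohort, child_ids(g$cohort)[1])[1:10, ]
  s <- make_reconstruction_split(ob, 0.5, seed = 4)
  expect_equal(nrow(s$kept), 5)
  expect_equal(nrow(s$held_out), 5)
  expect_equal(nrow(rbind(s$kept, s$held_out)), 10)
  expect_length(intersect(s$kept$age_years, s$held_out$age_years), 0)

  s9 <- make_reconstruction_split(ob, 0.9, seed = 4)
  expect_equal(nrow(s9$kept), 1)
  expect_equal(nrow(s9$held_out), 9)

  # round-half-up: 0.25 * 10 = 2.5 -> 3 held out
  s25 <- make_reconstruction_split(ob, 0.25, seed = 4)
  expect_equal(nrow(s25$held_out), 3)

  expect_identical(make_reconstruction_split(ob, 0.5, seed = 7),
                   make_reconstruction_split(ob, 0.5, seed = 7))
})

test_that("forecast splits partition at the age threshold", {
  ob <- tibble::tibble(child_id = "X", sex = "male",
                       age_years = c(0, 1, 3, 10), bmi = c(13, 17, 16, 18))
  s <- make_forecast_split(ob, 2)
  expect_equal(s$history$age_years, c(0, 1))
  expect_equal(s$future$age_years, c(3, 10))
  s0 <- make_forecast_split(ob, 0)
  expect_equal(nrow(s0$history), 0)
  expect_equal(nrow(s0$future), 4)
  s99 <- make_forecast_split(ob, 99)
  expect_equal(nrow(s99$future), 0)
})

test_that("MSE matches hand arithmetic and an independent oracle", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 2), c(0, 0)), 2.5)
  set.seed(3)
  p <- rnorm(50)
  o <- rnorm(50)
  expect_equal(mse(p, o), sum((p - o)^2) / 50, tolerance = 1e-12)
  expect_error(mse(numeric(0), numeric(0)), "empty")
  expect_error(mse(1:2, 1:3), "mismatch")
})

test_that("WCIC95 covers its closed-form extremes", {
  # all points at the predictive mean of a single component -> 100
  expect_equal(wcic95(rep(5, 4), rep(1, 4), 1, rep(5, 4)), 100)
  # observed 3 sd away -> 0
  expect_equal(wcic95(rep(5, 4), rep(1, 4), 1, rep(8, 4)), 0)
  # two components, only the 0.3-weighted one covers
  m <- matrix(c(0, 10), 1)
  s <- matrix(c(1, 1), 1)
  w <- matrix(c(0.3, 0.7), 1)
  expect_equal(wcic95(m, s, w, 0.5), 30)
  expect_error(wcic95(m, s, w, c(1, 2)), "mismatch|missing")
})

test_that("a correctly specified mixture is calibrated at 50% missingness", {
  fit <- preset_model()
  test <- preset_split()$test
  rep <- run_experiment(test, methods = "gpmix",
                        conditions = list(experiment_condition(
                          "reconstruction", missing_fraction = 0.5,
                          seed = 101)),
                        model = fit)
  expect_gte(rep$wcic95, 90)
  expect_lte(rep$wcic95, 99)
})

test_that("with zero history the mixture model predicts but baselines error", {
  fit <- preset_model()
  jb <- preset_jb()
  test <- preset_split()$test
  cond <- experiment_condition("forecast", age_threshold = 0, seed = 1)
  rep <- run_experiment(test, methods = c("gpmix", "jb", "spline"),
                        conditions = list(cond), model = fit,
                        jb_weight = jb$weight, jb_height = jb$height)
  gp <- rep[rep$method == "gpmix", ]
  expect_equal(gp$n_runtime_errors, 0)
  expect_gt(gp$n_predicted_points, 0)
  for (m in c("jb", "spline")) {
    r <- rep[rep$method == m, ]
    expect_equal(r$n_children_evaluated, 0)
    expect_gt(r$n_runtime_errors, 0)
  }
})

test_that("spline runtime errors dominate at extreme missingness", {
  fit <- preset_model()
  test <- preset_split()$test
  rep <- run_experiment(test, methods = c("gpmix", "spline"),
                        conditions = list(experiment_condition(
                          "reconstruction", missing_fraction = 0.9,
                          seed = 11)),
                        model = fit)
  sp <- rep[rep$method == "spline", ]
  expect_gt(sp$n_runtime_errors, 0.5 * (sp$n_children_evaluated +
                                          sp$n_runtime_errors))
  expect_equal(rep[rep$method == "gpmix", ]$n_runtime_errors, 0)
})

test_that("the report has one row per method and condition and is order-invariant", {
  fit <- preset_model()
  test <- preset_split()$test
  conds <- list(
    experiment_condition("reconstruction", missing_fraction = 0.3, seed = 5),
    experiment_condition("forecast", age_threshold = 6, seed = 5))
  rep <- run_experiment(test, methods = c("gpmix", "spline"),
                        conditions = conds, model = fit)
  expect_equal(nrow(rep), 4)

  # permuting the children leaves the metrics unchanged
  rec <- test$records
  perm <- local({set.seed(2); sample(nrow(rec))})
  test2 <- growth_cohort(rec[perm, ], schedule = test$schedule, quiet = TRUE)
  rep2 <- run_experiment(test2, methods = c("gpmix", "spline"),
                         conditions = conds, model = fit)
  expect_equal(rep$mse, rep2$mse, tolerance = 1e-10)
  expect_equal(rep$n_predicted_points, rep2$n_predicted_points)
})

test_that("reconstruction error grows with the missing fraction for the mixture model", {
  fit <- preset_model()
  test <- preset_split()$test
  conds <- lapply(c(0.1, 0.5, 0.9), function(f) {
    experiment_condition("reconstruction", missing_fraction = f, seed = 21)
  })
  rep <- run_experiment(test, methods = "gpmix", conditions = conds,
                        model = fit)
  expect_lte(rep$mse[1], rep$mse[3])
})
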