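test_that("overweight thresholds are sex-specific with a working override", {
  expect_equal(overweight_threshold("female"), 22.0)
  expect_equal(overweight_threshold("male"), 22.8)
  expect_equal(overweight_threshold(c("male", "female")), c(22.8, 22.0))
  expect_equal(overweight_threshold("male", override = 25), 25)
  expect_equal(overweight_threshold("female",
                                    override = c(female = 21, male = 23)), 21)
  expect_error(overweight_threshold("robot"), "sex")
})

test_that("MC crossing probability counts exceedances", {
  draws <- matrix(c(rep(20, 96), rep(25, 4)), ncol = 1)
  colnames(draws) <- "10"
  attr(draws, "ages") <- 10
  expect_equal(crossing_probability_mc(draws, 22.8), 0.04)
  expect_equal(crossing_probability_mc(rep(10, 50), 22), 0)
  expect_error(crossing_probability_mc(numeric(0), 22), "zero")
})

test_that("path-wise crossing counts exceedance at any sampled age", {
  draws <- rbind(c(20, 23), c(21, 21.5), c(24, 20), c(19, 19))
  colnames(draws) <- c("6", "10")
  attr(draws, "ages") <- c(6, 10)
  expect_equal(crossing_probability_mc(draws, 22, age = 10), 0.25)
  expect_equal(crossing_probability_mc(draws, 22, pathwise = TRUE), 0.5)
})

test_that("analytic crossing probability matches symmetry, limits and Monte Carlo", {
  law1 <- gaussian_law(10, 22, matrix(1))
  p1 <- structure(list(target_ages = 10, laws = list(law1), weights = 1),
                  class = "gpm_prediction")
  expect_equal(crossing_probability_analytic(p1, 22, 10), 0.5)
  expect_equal(crossing_probability_analytic(p1, 1e6, 10), 0)
  expect_equal(crossing_probability_analytic(p1, -1e6, 10), 1)

  # two-component case vs large-sample Monte Carlo
  p2 <- structure(list(target_ages = 10,
                       laws = list(gaussian_law(10, 21, matrix(1.2)),
                                   gaussian_law(10, 24, matrix(0.8))),
                       weights = c(0.3, 0.7)),
                  class = "gpm_prediction")
  ana <- crossing_probability_analytic(p2, 22.8, 10)
  mc <- crossing_probability_mc(sample_trajectories(p2, 1e6, seed = 9), 22.8,
                                age = 10)
  expect_lt(abs(ana - mc), 3 * sqrt(ana * (1 - ana) / 1e6))
  # zero-variance component becomes an indicator on its mean
  p3 <- structure(list(target_ages = 10,
                       laws = list(gaussian_law(10, 25, matrix(0))),
                       weights = 1), class = "gpm_prediction")
  expect_equal(crossing_probability_analytic(p3, 22.8, 10), 1)
})

test_that("MC probability converges to the analytic tail at root-n rate", {
  p2 <- structure(list(target_ages = 10,
                       laws = list(gaussian_law(10, 21.5, matrix(1)),
                                   gaussian_law(10, 23.5, matrix(1.5))),
                       weights = c(0.6, 0.4)),
                  class = "gpm_prediction")
  ana <- crossing_probability_analytic(p2, 22.8, 10)
  errs <- vapply(c(1e3, 1e4, 1e5), function(n) {
    mc <- crossing_probability_mc(sample_trajectories(p2, n, seed = 31),
                                  22.8, age = 10)
    abs(mc - ana)
  }, numeric(1))
  bounds <- 4 * sqrt(ana * (1 - ana) / c(1e3, 1e4, 1e5))
  expect_true(all(errs <= bounds))
})

test_that("risk classification respects the cutoff with >= at the boundary", {
  expect_false(classify_risk(0.04, 0.05))
  expect_true(classify_risk(0.05, 0.05))
  expect_true(classify_risk(0.6, 0.5))
  expect_error(classify_risk(0.5, 0), "cutoff")
  expect_error(classify_risk(0.5, 1.2), "cutoff")
})

test_that("classification metrics reproduce hand-computed confusion arithmetic", {
  pred <- c(rep(TRUE, 3), rep(FALSE, 7))
  obs <- c(TRUE, TRUE, FALSE, TRUE, rep(FALSE, 6))
  r <- score_classification(pred, obs)
  expect_equal(r$tp, 2)
  expect_equal(r$fp, 1)
  expect_equal(r$tn, 6)
  expect_equal(r$fn, 1)
  expect_equal(r$sensitivity, 2 / 3)
  expect_equal(r$specificity, 6 / 7)
  expect_equal(r$ppv, 2 / 3)
  expect_equal(r$npv, 6 / 7)
  expect_equal(r$accuracy, 0.8)

  perfect <- score_classification(obs, obs)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$accuracy, 1)

  nopos <- score_classification(c(FALSE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(nopos$sensitivity))
  expect_equal(nopos$specificity, 1)
  expect_error(score_classification(TRUE, c(TRUE, FALSE)), "length")
})

test_that("raising the cutoff never raises sensitivity nor lowers specificity", {
  fit <- preset_model()
  test <- preset_split()$test
  out <- run_risk_pipeline(fit, test, age_thresholds = 4,
                           engine = "analytic", seed = 2)
  probs <- out$results$probability
  obs <- out$results$observed_positive
  cuts <- c(0.02, 0.05, 0.2, 0.5, 0.9)
  sens <- spec <- numeric(0)
  for (ct in cuts) {
    s <- score_classification(classify_risk(probs, ct), obs)
    sens <- c(sens, ifelse(is.na(s$sensitivity), 0, s$sensitivity))
    spec <- c(spec, s$specificity)
  }
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spec) >= -1e-12))
})

test_that("risk pipeline excludes children without a measurement at the target age", {
  fit <- preset_model()
  test <- preset_split()$test
  out <- run_risk_pipeline(fit, test, age_thresholds = c(2, 8),
                           engine = "analytic", seed = 3)
  n_eval <- length(unique(out$results$child_id))
  expect_equal(n_eval + out$n_excluded, n_children(test))
  expect_true(all(out$results$probability >= 0 &
                    out$results$probability <= 1))
  expect_equal(out$reports$n, rep(n_eval, 2))
})

test_that("analytic and Monte-Carlo risk probabilities agree child by child", {
  fit <- preset_model()
  test <- preset_split()$test
  sub <- growth_cohort(
    test$records[test$records$child_id %in% utils::head(child_ids(test), 25), ],
    schedule = test$schedule, quiet = TRUE)
  a <- run_risk_pipeline(fit, sub, age_thresholds = 4, engine = "analytic",
                         seed = 5)
  m <- run_risk_pipeline(fit, sub, age_thresholds = 4, engine = "mc",
                         n_samples = 1e5, seed = 5)
  expect_true(all(abs(a$results$probability - m$results$probability) < 0.01))
})
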