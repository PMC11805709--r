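test_that("K=1 fit reduces to the single-mean multi-task GP with a closed-form E-step", {
  # a well-spaced schedule keeps the mean-process kernel well-conditioned so
  # the plain-solve oracle and the Cholesky path agree to tight tolerance
  g <- generate_cohort(sim_config(n_children = 25, seed = 41,
                                  schedule = seq(0, 10, length.out = 8)))
  fit <- gpm_fit(g$cohort, K = 1, control = gpm_control(seed = 41,
                                                        max_iter = 1))
  expect_true(all(fit$memberships == 1))
  expect_equal(fit$mixture_weights, 1)

  # independent plain-solve oracle for the first E-step (initial
  # hyper-parameters gamma=(3,1), theta=(1,1.5), sigma2=0.1, tau=1)
  grid <- sort(unique(g$cohort$records$age_years))
  p <- length(grid)
  Cg <- se_kernel(grid, grid, kernel_params(3, 1))
  Kth <- se_kernel(grid, grid, kernel_params(1, 1.5))
  m0 <- mean(g$cohort$records$bmi)
  Prec <- solve(Cg + diag(3e-10, p))  # same starting jitter policy
  rhs <- drop(Prec %*% rep(m0, p))
  for (id in child_ids(g$cohort)) {
    ob <- child_obs(g$cohort, id)
    ix <- match(ob$age_years, grid)
    Psi_inv <- solve(Kth[ix, ix] + diag(0.1, length(ix)))
    Prec[ix, ix] <- Prec[ix, ix] + Psi_inv
    rhs[ix] <- rhs[ix] + drop(Psi_inv %*% ob$bmi)
  }
  C_or <- solve(Prec)
  m_or <- drop(C_or %*% rhs)
  expect_equal(fit$mean_hyperpost[[1]]$mean, m_or, tolerance = 1e-6)
  expect_equal(fit$mean_hyperpost[[1]]$cov, (C_or + t(C_or)) / 2,
               tolerance = 1e-5)
})

test_that("the ELBO trace is non-decreasing", {
  fit <- two_cluster_fit()
  expect_true(all(diff(fit$elbo_trace) > -1e-6))
  expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
})

test_that("well-separated clusters are recovered with high ARI and hyper-parameters within 25%", {
  skip_if_not_installed("mclust")
  g <- two_cluster_data()
  fit <- two_cluster_fit()
  hard <- max.col(fit$memberships, ties.method = "first")
  ari <- mclust::adjustedRandIndex(hard,
                                   g$truth$labels[rownames(fit$memberships)])
  expect_gt(ari, 0.9)
  cfg <- g$truth$config
  expect_lt(abs(fit$individual_kernel$variance -
                  cfg$individual_kernel$variance) /
              cfg$individual_kernel$variance, 0.25)
  expect_lt(abs(fit$individual_kernel$lengthscale -
                  cfg$individual_kernel$lengthscale) /
              cfg$individual_kernel$lengthscale, 0.25)
  expect_lt(abs(fit$noise_var - cfg$noise_sd^2) / cfg$noise_sd^2, 0.25)
})

test_that("training is exchangeable under permutation of children", {
  g <- generate_cohort(sim_config(n_children = 50, k_true = 2, seed = 43))
  rec <- g$cohort$records
  perm <- local({set.seed(1); sample(nrow(rec))})
  coh2 <- growth_cohort(rec[perm, ], schedule = g$cohort$schedule,
                        quiet = TRUE)
  ctrl <- gpm_control(seed = 43, max_iter = 5)
  f1 <- gpm_fit(g$cohort, K = 2, control = ctrl)
  f2 <- gpm_fit(coh2, K = 2, control = ctrl)
  # align clusters by mean level before comparing
  o1 <- order(sapply(f1$mean_hyperpost, function(l) mean(l$mean)))
  o2 <- order(sapply(f2$mean_hyperpost, function(l) mean(l$mean)))
  for (j in 1:2) {
    expect_equal(f1$mean_hyperpost[[o1[j]]]$mean,
                 f2$mean_hyperpost[[o2[j]]]$mean, tolerance = 1e-8)
  }
})

test_that("counting non-empty clusters follows argmax membership", {
  g <- generate_cohort(sim_config(n_children = 20, seed = 44))
  fit1 <- gpm_fit(g$cohort, K = 1, control = gpm_control(max_iter = 2))
  expect_equal(count_nonempty_clusters(fit1), 1)
  expect_equal(count_nonempty_clusters(fit1, min_members = 21), 0)
})

test_that("prediction with no observations returns the population mixture", {
  fit <- preset_model()
  pred <- predict(fit, target_ages = c(2, 6, 10))
  expect_equal(pred$weights, fit$mixture_weights)
  mm <- mixture_moments(pred)
  expect_true(all(mm$var > fit$noise_var))
  # population-level means lie in the plausible BMI band
  expect_true(all(mm$mean > 12 & mm$mean < 25))
})

test_that("conditioning on a full trajectory recovers the noise-free truth within noise SD", {
  fit <- preset_model()
  s <- preset_split()
  truth <- s$truth
  sched <- truth$config$schedule
  ids <- utils::head(child_ids(s$train), 40)
  errs <- unlist(lapply(ids, function(id) {
    ob <- child_obs(s$train, id)
    pred <- predict(fit, ob$age_years, ob$bmi, target_ages = ob$age_years)
    mm <- mixture_moments(pred)
    ix <- match(ob$age_years, sched)
    latent <- truth$cluster_means[truth$labels[id], ix] +
      truth$deviations[id, ix]
    mm$mean - latent
  }))
  # the posterior mean recovers the latent curve below the measurement-noise
  # level, and essentially all pointwise errors sit inside the noise band
  expect_lte(sqrt(mean(errs^2)), truth$config$noise_sd)
  expect_gte(mean(abs(errs) <= 1.96 * truth$config$noise_sd), 0.95)
})

test_that("longer observation histories narrow the predictive law at age 10", {
  fit <- preset_model()
  s <- preset_split()
  ids <- child_ids(s$test)
  v <- t(vapply(ids, function(id) {
    ob <- child_obs(s$test, id)
    vapply(c(2, 6, 8), function(thr) {
      h <- ob[ob$age_years < thr, ]
      mixture_moments(predict(fit, h$age_years, h$bmi, 10))$var
    }, numeric(1))
  }, numeric(3)))
  # nested information: histories to age 8 narrow the age-10 law relative to
  # infancy-only histories for >= 90% of children, and the typical child
  # narrows already by age 6 (early memberships can be overconfident for a
  # minority, so the 6 y comparison is asserted on the median)
  expect_gte(mean(v[, 3] <= v[, 1] + 1e-9), 0.9)
  expect_lt(median(v[, 2] / v[, 1]), 1)
})

test_that("prediction is invariant to relabeling the clusters", {
  fit <- preset_model()
  perm <- c(3, 1, 4, 5, 2)
  fit2 <- fit
  fit2$mean_kernels <- fit$mean_kernels[perm]
  fit2$mean_hyperpost <- fit$mean_hyperpost[perm]
  fit2$mixture_weights <- fit$mixture_weights[perm]
  fit2$memberships <- fit$memberships[, perm]
  fit2$empty <- fit$empty[perm]
  fit2$suffstats <- list(S = fit$suffstats$S[perm], b = fit$suffstats$b[perm])
  ob <- child_obs(preset_split()$test, child_ids(preset_split()$test)[1])
  p1 <- predict(fit, ob$age_years, ob$bmi, c(4, 10))
  p2 <- predict(fit2, ob$age_years, ob$bmi, c(4, 10))
  expect_equal(mixture_moments(p1), mixture_moments(p2), tolerance = 1e-9)
})

test_that("prediction at off-grid ages uses the augmented-grid hyper-posterior", {
  fit <- preset_model()
  ob <- child_obs(preset_split()$test, child_ids(preset_split()$test)[2])
  tgt <- c(3.33, 7.77)  # not on the training grid
  pred <- predict(fit, ob$age_years, ob$bmi, tgt)
  mm <- mixture_moments(pred)
  expect_true(all(is.finite(mm$mean)))
  # consistency with neighbouring on-grid predictions
  on_grid <- mixture_moments(predict(fit, ob$age_years, ob$bmi, c(3, 3.5)))
  expect_lt(abs(mm$mean[1] - mean(on_grid$mean)), 0.5)
})

test_that("trajectory sampling is reproducible and honours degenerate laws", {
  fit <- preset_model()
  pred <- predict(fit, target_ages = c(2, 10))
  s1 <- sample_trajectories(pred, 100, seed = 5)
  s2 <- sample_trajectories(pred, 100, seed = 5)
  expect_identical(s1, s2)

  degen <- structure(list(target_ages = 10,
                          laws = list(gaussian_law(10, 20, matrix(0))),
                          weights = 1), class = "gpm_prediction")
  sd0 <- sample_trajectories(degen, 50, seed = 1)
  expect_true(all(sd0 == 20))
})

test_that("sample moments converge to the mixture moments", {
  fit <- preset_model()
  pred <- predict(fit, target_ages = c(2, 6, 10))
  draws <- sample_trajectories(pred, 1e5, seed = 77)
  mm <- mixture_moments(pred)
  se <- sqrt(mm$var / 1e5)
  expect_true(all(abs(colMeans(draws) - mm$mean) <= 4 * se))
})

test_that("model serialization round-trips through JSON", {
  fit <- two_cluster_fit()
  path <- tempfile(fileext = ".json")
  write_gpm_model(fit, path)
  back <- read_gpm_model(path)
  ob <- child_obs(two_cluster_data()$cohort,
                  child_ids(two_cluster_data()$cohort)[3])
  p1 <- predict(fit, ob$age_years, ob$bmi, c(5, 10))
  p2 <- predict(back, ob$age_years, ob$bmi, c(5, 10))
  expect_equal(p1$weights, p2$weights, tolerance = 1e-12)
  expect_equal(mixture_moments(p1), mixture_moments(p2), tolerance = 1e-12)
  expect_error(suppressWarnings(read_gpm_model(tempfile())), ".")
})
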