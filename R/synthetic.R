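#' Default 20-visit schedule
#'
#' A fixed schedule of 20 nominal visit ages spanning birth to 10 years,
#' dense in infancy (8 visits before age 2, where BMI changes fastest) and
#' annual from age 5. This is a plausible pediatric follow-up schedule, not a
#' claim about any particular cohort.
#'
#' @return Numeric vector of 20 strictly increasing ages, first 0, last 10.
#' @export
default_schedule <- function() {
  c(0, 0.125, 0.25, 0.5, 0.75, 1, 1.25, 1.5,
    2, 2.5, 3, 3.5, 4, 4.5,
    5, 6, 7, 8, 9, 10)
}

#' Default cluster mean-curve parameters
#'
#' Parameters of the built-in family of cluster mean BMI curves
#' `f(t) = a + b t - exp(c - d t) + h exp(-(t - t_peak)^2 / (2 w^2))`:
#' a Jenss-Bayley-shaped backbone plus a Gaussian bump producing the infant
#' BMI peak near 9 months. The 5-cluster preset emulates the qualitative
#' structure of observed childhood BMI clusters: a shared infancy peak with
#' varying intensity, then divergent trajectories, the upper cluster growing
#' towards ~26 kg/m^2 at age 10 y. Rows are ordered by the curve value at
#' age 10 (descending: cluster 1 is the upper pattern). For `k < 5`, `k`
#' maximally spread rows of the preset are returned, giving well-separated
#' clusters.
#'
#' @param k Number of clusters, between 1 and 5.
#' @return A tibble with columns `a, b, c, d, h, t_peak, w`, one row per
#'   cluster.
#' @export
default_cluster_params <- function(k = 5) {
  stopifnot(k >= 1, k <= 5)
  preset <- tibble::tibble(
    a = c(16.2, 15.4, 14.8, 14.3, 13.6),
    b = c(1.03, 0.72, 0.44, 0.18, 0.00),
    c = log(4),
    d = 2.5,
    h = c(4.2, 3.1, 2.1, 1.3, 0.5),
    t_peak = c(0.62, 0.69, 0.76, 0.83, 0.90),
    w = c(0.30, 0.32, 0.35, 0.38, 0.42)
  )
  preset[unique(round(seq(1, 5, length.out = k))), , drop = FALSE]
}

#' Cluster mean BMI curves
#'
#' Evaluates the parametric family of [default_cluster_params()] on an age
#' grid. Each curve is smooth, has a local maximum (the infant BMI peak) at
#' an age in roughly `[0.5, 1.25]` y, and curves are returned ordered by
#' their value at the last grid age (descending).
#'
#' @param params A data frame of curve parameters (`a, b, c, d, h, t_peak, w`),
#'   one row per cluster; see [default_cluster_params()].
#' @param grid Numeric vector of ages within `[0, 10]`.
#' @return Matrix with one row per cluster, one column per grid age.
#' @export
generate_cluster_means <- function(params = default_cluster_params(), grid) {
  stopifnot(all(grid >= 0), all(grid <= 10))
  params <- as.data.frame(params)
  curves <- t(apply(params, 1, function(p) {
    p["a"] + p["b"] * grid - exp(p["c"] - p["d"] * grid) +
      p["h"] * exp(-(grid - p["t_peak"])^2 / (2 * p["w"]^2))
  }))
  if (length(grid) == 1L) curves <- matrix(curves, ncol = 1L)
  if (!all(is.finite(curves))) {
    stop("curve parameters produce non-finite values", call. = FALSE)
  }
  curves[order(curves[, ncol(curves)], decreasing = TRUE), , drop = FALSE]
}

#' Age of the infant BMI peak of a curve
#'
#' Brute-force argmax of a mean curve restricted to infancy (ages up to
#' `upper`), the operational definition of the infant BMI peak. The global
#' argmax is not used because upper trajectories keep rising to age 10.
#'
#' @param par One row of curve parameters (list or one-row data frame).
#' @param upper Upper end of the infancy window in years.
#' @param step Grid spacing for the brute-force search.
#' @return The age (years) of the within-window maximum.
#' @export
infant_peak_age <- function(par, upper = 2.5, step = 1e-3) {
  g <- seq(0, upper, by = step)
  y <- generate_cluster_means(as.data.frame(par), g)
  g[which.max(y[1, ])]
}

#' Synthetic cohort configuration
#'
#' Bundles the generator's parameters. Defaults define the package's
#' standard simulated study conditions: 300 children in 5 latent clusters
#' with mixture weights (0.12, 0.18, 0.25, 0.25, 0.20), per-child smooth GP
#' deviations with an SE kernel (variance 1 (kg/m^2)^2, lengthscale 2 y),
#' i.i.d. measurement noise of SD 0.4 kg/m^2, the 20-visit
#' [default_schedule()] with 20% of visits missing at random, and an even
#' sex ratio.
#'
#' @param n_children Number of children.
#' @param k_true Number of latent clusters (1-5 with the built-in preset).
#' @param mixture_weights Probability vector of length `k_true`.
#' @param cluster_curve_params Curve parameter table; see
#'   [default_cluster_params()].
#' @param individual_kernel [kernel_params()] of the per-child deviation GP.
#' @param noise_sd Measurement noise SD, kg/m^2.
#' @param schedule Visit ages (years).
#' @param missing_prob Per-visit i.i.d. missingness probability in `[0, 1)`.
#' @param sex_ratio Probability that a child is male.
#' @param emit_wh If `TRUE`, also emit consistent `weight_kg` / `height_cm`
#'   columns (height from a fixed monotone growth template with small
#'   child-level random effects; weight back-computed so that
#'   `bmi = weight / (height/100)^2` holds exactly), so weight/height
#'   pathways are testable.
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_children = 300, k_true = 5,
                       mixture_weights = NULL,
                       cluster_curve_params = default_cluster_params(k_true),
                       individual_kernel = kernel_params(1.0, 2.0),
                       noise_sd = 0.4,
                       schedule = default_schedule(),
                       missing_prob = 0.2,
                       sex_ratio = 0.5,
                       emit_wh = FALSE,
                       seed = 1) {
  if (is.null(mixture_weights)) {
    mixture_weights <- if (k_true == 5) c(0.12, 0.18, 0.25, 0.25, 0.20)
    else rep(1 / k_true, k_true)
  }
  stopifnot(n_children >= 1, k_true >= 1,
            length(mixture_weights) == k_true,
            abs(sum(mixture_weights) - 1) < 1e-8,
            noise_sd > 0, missing_prob >= 0, missing_prob < 1,
            nrow(cluster_curve_params) == k_true)
  structure(list(n_children = n_children, k_true = k_true,
                 mixture_weights = mixture_weights,
                 cluster_curve_params = cluster_curve_params,
                 individual_kernel = individual_kernel,
                 noise_sd = noise_sd, schedule = schedule,
                 missing_prob = missing_prob, sex_ratio = sex_ratio,
                 emit_wh = emit_wh, seed = seed),
            class = "sim_config")
}

# Fixed monotone height growth template (cm): Jenss-Bayley-shaped, ~50 cm at
# birth, ~135 cm at age 10, first-year velocity ~25 cm/y.
height_template <- function(t) 65.4 + 7 * t - exp(2.733 - 1.2 * t)

#' Generate a synthetic growth cohort
#'
#' Draws, per child: a latent cluster from the mixture weights; a smooth
#' deviation curve from `GP(0, individual_kernel)` on the schedule; i.i.d.
#' Gaussian measurement noise; and an i.i.d. per-visit missingness mask
#' (redrawn until at least one visit remains). Observed BMI is
#' cluster mean + deviation + noise. Fully reproducible given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (a [growth_cohort()]) and `truth`
#'   (per-child latent labels and deviation curves, the cluster mean curves
#'   on the schedule and on a dense grid, and the config).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$schedule) == 0L) stop("empty schedule", call. = FALSE)
  sched <- config$schedule
  p <- length(sched)
  means <- generate_cluster_means(config$cluster_curve_params, sched)
  dense <- seq(0, 10, by = 0.05)
  means_dense <- generate_cluster_means(config$cluster_curve_params, dense)
  Kdev <- se_kernel(sched, sched, config$individual_kernel)
  R <- chol_jitter(Kdev)

  local_seed(config$seed, {
    n <- config$n_children
    labels <- integer(n)
    devs <- matrix(0, n, p)
    rows <- vector("list", n)
    ids <- sprintf("C%04d", seq_len(n))
    for (i in seq_len(n)) {
      k <- sample.int(config$k_true, 1, prob = config$mixture_weights)
      sex <- if (stats::runif(1) < config$sex_ratio) "male" else "female"
      dev <- drop(crossprod(R, stats::rnorm(p)))
      bmi <- means[k, ] + dev + stats::rnorm(p, 0, config$noise_sd)
      repeat {
        keep <- stats::runif(p) >= config$missing_prob
        if (any(keep)) break
      }
      df <- tibble::tibble(child_id = ids[i], sex = sex,
                           age_years = sched[keep], bmi = bmi[keep])
      if (config$emit_wh) {
        ha <- stats::rnorm(1, 0, 1.5)
        hb <- stats::rnorm(1, 0, 0.3)
        height <- height_template(sched[keep]) + ha + hb * sched[keep] +
          stats::rnorm(sum(keep), 0, 0.3)
        df$weight_kg <- df$bmi * (height / 100)^2
        df$height_cm <- height
      }
      labels[i] <- k
      devs[i, ] <- dev
      rows[[i]] <- df
    }
    records <- do.call(rbind, rows)
    cohort <- growth_cohort(records, schedule = sched, quiet = TRUE)
    truth <- list(labels = stats::setNames(labels, ids),
                  deviations = `rownames<-`(devs, ids),
                  cluster_means = means,
                  dense_grid = dense,
                  cluster_means_dense = means_dense,
                  config = config)
    list(cohort = cohort, truth = truth)
  })
}

#' Simulate a cohort directly from a Jenss-Bayley mixed model
#'
#' Draws per-child parameters `(a, b, c)` around the fixed effects (with `d`
#' fixed at the population value), evaluates the Jenss-Bayley curve on a
#' schedule and adds i.i.d. residual noise. Used for parameter-recovery
#' checks of the mixed-model fitter.
#'
#' @param n Number of children.
#' @param fixed Named vector `c(a, b, c, d)` of fixed effects.
#' @param re_sd Named vector `c(a, b, c)` of random-effect SDs.
#' @param resid_sd Residual SD in trait units.
#' @param schedule Observation ages.
#' @param seed Integer seed.
#' @return A tibble with columns `child_id, age_years, value` and an
#'   attribute `truth` holding the generating parameters.
#' @export
simulate_jb_cohort <- function(n = 150,
                               fixed = c(a = 65.4, b = 7, c = 2.733, d = 1.2),
                               re_sd = c(a = 2, b = 0.4, c = 0.1),
                               resid_sd = 0.5,
                               schedule = default_schedule(),
                               seed = 1) {
  local_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      a <- fixed["a"] + stats::rnorm(1, 0, re_sd["a"])
      b <- fixed["b"] + stats::rnorm(1, 0, re_sd["b"])
      cc <- fixed["c"] + stats::rnorm(1, 0, re_sd["c"])
      y <- jenss_bayley_curve(schedule, a = a, b = b, c = cc, d = fixed["d"]) +
        stats::rnorm(length(schedule), 0, resid_sd)
      tibble::tibble(child_id = sprintf("J%04d", i), age_years = schedule,
                     value = y)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(fixed = fixed, re_sd = re_sd,
                               resid_sd = resid_sd)
    out
  })
}
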