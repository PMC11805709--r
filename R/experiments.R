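#' Experimental condition
#'
#' One cell of the evaluation design: either missing-data reconstruction at
#' a given missing fraction, or forecasting beyond an age threshold.
#'
#' @param kind `"reconstruction"` or `"forecast"`.
#' @param missing_fraction Fraction of each child's points held out
#'   (reconstruction only), in `(0, 1)`.
#' @param age_threshold Forecast history cutoff in years (forecast only).
#' @param seed Integer seed governing the random hold-out draws.
#' @return A list of class `experiment_condition`.
#' @export
experiment_condition <- function(kind = c("reconstruction", "forecast"),
                                 missing_fraction = NULL,
                                 age_threshold = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "reconstruction") {
    stopifnot(is.numeric(missing_fraction), missing_fraction > 0,
              missing_fraction < 1)
    age_threshold <- NA_real_
  } else {
    stopifnot(is.numeric(age_threshold))
    missing_fraction <- NA_real_
  }
  structure(list(kind = kind, missing_fraction = missing_fraction,
                 age_threshold = age_threshold, seed = seed),
            class = "experiment_condition")
}

#' Random hold-out split of one child's observations
#'
#' Holds out `round(fraction * n)` points (round half up) uniformly at
#' random; at least one point is always kept so that every method receives
#' an input.
#'
#' @param obs A tibble of one child's records (rows sorted by age).
#' @param missing_fraction Fraction to hold out.
#' @param seed Integer seed.
#' @return List with tibbles `kept` and `held_out`.
#' @export
make_reconstruction_split <- function(obs, missing_fraction, seed) {
  n <- nrow(obs)
  stopifnot(n >= 1)
  n_hold <- floor(missing_fraction * n + 0.5)
  n_hold <- min(n_hold, n - 1L)
  if (n_hold <= 0) return(list(kept = obs, held_out = obs[0, ]))
  idx <- local_seed(seed, sample.int(n, n_hold))
  list(kept = obs[-idx, , drop = FALSE], held_out = obs[idx, , drop = FALSE])
}

#' Age-threshold split of one child's observations
#'
#' History is every point strictly before the threshold; the future is
#' every point at or after it. Deterministic.
#'
#' @param obs A tibble of one child's records.
#' @param age_threshold Threshold in years.
#' @return List with tibbles `history` and `future`.
#' @export
make_forecast_split <- function(obs, age_threshold) {
  before <- obs$age_years < age_threshold
  list(history = obs[before, , drop = FALSE],
       future = obs[!before, , drop = FALSE])
}

#' Mean squared error
#'
#' Pooled over all supplied points.
#'
#' @param predicted,observed Equal-length numeric vectors, length `>= 1`.
#' @return The mean of squared differences.
#' @export
mse <- function(predicted, observed) {
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (length(predicted) != length(observed)) {
    stop("length mismatch", call. = FALSE)
  }
  mean((predicted - observed)^2)
}

#' Weighted 95% credible-interval coverage
#'
#' For each held-out point, each mixture component contributes its
#' membership weight if the observation falls inside that component's
#' central 95% interval `mean +/- 1.96 sd`; WCIC95 is 100 times the average
#' over points of these weighted indicator sums. With a single component it
#' reduces to plain 95%-interval coverage.
#'
#' @param means,sds Matrices (points x components) of per-point per-cluster
#'   predictive means and SDs (vectors are treated as single-component).
#' @param weights Matrix (points x components) of membership weights, or a
#'   single probability vector recycled across points.
#' @param observed Observed values, one per point.
#' @return Coverage percentage in `[0, 100]`.
#' @export
wcic95 <- function(means, sds, weights, observed) {
  if (is.null(dim(means))) means <- matrix(means, ncol = 1)
  if (is.null(dim(sds))) sds <- matrix(sds, ncol = 1)
  n <- nrow(means)
  K <- ncol(means)
  if (is.null(dim(weights))) {
    weights <- matrix(weights, n, K, byrow = TRUE)
  }
  if (length(observed) != n || !all(dim(sds) == c(n, K)) ||
      !all(dim(weights) == c(n, K))) {
    stop("missing or mismatched predictions for the observed points",
         call. = FALSE)
  }
  inside <- abs(observed - means) <= 1.96 * sds
  100 * mean(rowSums(weights * inside))
}

# Per-point per-cluster predictive summaries from a mixture prediction.
prediction_points <- function(pred) {
  mu <- sapply(pred$laws, `[[`, "mean")
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  sd <- sapply(pred$laws, function(l) sqrt(pmax(diag(l$cov), 0)))
  if (is.null(dim(sd))) sd <- matrix(sd, nrow = 1)
  list(means = mu, sds = sd,
       weights = matrix(pred$weights, nrow(mu), ncol(mu), byrow = TRUE))
}

#' Run the evaluation designs over a test cohort
#'
#' Applies each requested method to each condition. Per child, the
#' condition's split is drawn once and shared across methods. Children that
#' a method cannot handle (splines need >= 4 kept points, Jenss-Bayley
#' >= 2) are counted as runtime errors for that method, not silently
#' dropped; children whose target set is empty are skipped for all methods.
#' MSE is pooled over all predicted points; WCIC95 is reported for the
#' mixture model (the baselines carry no calibrated predictive law).
#'
#' @param test A [growth_cohort()]; for the Jenss-Bayley method its records
#'   need `weight_kg` and `height_cm` columns.
#' @param methods Subset of `c("gpmix", "jb", "spline")`.
#' @param conditions List of [experiment_condition()]s.
#' @param model A fitted [gpm_fit()] model (for method `"gpmix"`).
#' @param jb_weight,jb_height [fit_jb_mixed()] population fits of weight and
#'   height on the training cohort (for method `"jb"`).
#' @return A tibble, one row per method x condition: pooled `mse`, `wcic95`
#'   (NA for baselines), `n_predicted_points`, `n_runtime_errors`,
#'   `n_children_evaluated`, `n_children_skipped`.
#' @export
run_experiment <- function(test, methods = c("gpmix", "jb", "spline"),
                           conditions, model = NULL,
                           jb_weight = NULL, jb_height = NULL) {
  stopifnot(inherits(test, "growth_cohort"))
  methods <- match.arg(methods, several.ok = TRUE)
  if ("gpmix" %in% methods) stopifnot(inherits(model, "gpm_model"))
  if ("jb" %in% methods) {
    stopifnot(inherits(jb_weight, "jb_population"),
              inherits(jb_height, "jb_population"))
  }
  ids <- child_ids(test)
  out <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    stopifnot(inherits(cond, "experiment_condition"))
    acc <- lapply(methods, function(m) {
      list(pred = numeric(0), obs = numeric(0),
           means = NULL, sds = NULL, wts = NULL,
           errors = 0L, evaluated = 0L, skipped = 0L)
    })
    names(acc) <- methods
    for (j in seq_along(ids)) {
      ob <- child_obs(test, ids[j])
      sp <- if (cond$kind == "reconstruction") {
        s <- make_reconstruction_split(ob, cond$missing_fraction,
                                       seed = cond$seed * 10000L + j)
        list(input = s$kept, target = s$held_out)
      } else {
        s <- make_forecast_split(ob, cond$age_threshold)
        list(input = s$history, target = s$future)
      }
      if (nrow(sp$target) == 0L) {
        for (m in methods) acc[[m]]$skipped <- acc[[m]]$skipped + 1L
        next
      }
      tgt_age <- sp$target$age_years
      tgt_bmi <- sp$target$bmi
      for (m in methods) {
        res <- tryCatch(
          predict_one(m, sp$input, tgt_age, model, jb_weight, jb_height),
          error = function(e) NULL)
        if (is.null(res)) {
          acc[[m]]$errors <- acc[[m]]$errors + 1L
          next
        }
        acc[[m]]$evaluated <- acc[[m]]$evaluated + 1L
        acc[[m]]$pred <- c(acc[[m]]$pred, res$mean)
        acc[[m]]$obs <- c(acc[[m]]$obs, tgt_bmi)
        if (!is.null(res$points)) {
          acc[[m]]$means <- rbind(acc[[m]]$means, res$points$means)
          acc[[m]]$sds <- rbind(acc[[m]]$sds, res$points$sds)
          acc[[m]]$wts <- rbind(acc[[m]]$wts, res$points$weights)
        }
      }
    }
    for (m in methods) {
      a <- acc[[m]]
      out[[length(out) + 1L]] <- tibble::tibble(
        method = m, kind = cond$kind,
        missing_fraction = cond$missing_fraction,
        age_threshold = cond$age_threshold, seed = cond$seed,
        mse = if (length(a$pred) > 0) mse(a$pred, a$obs) else NA_real_,
        wcic95 = if (!is.null(a$means)) {
          wcic95(a$means, a$sds, a$wts, a$obs)
        } else NA_real_,
        n_predicted_points = length(a$pred),
        n_runtime_errors = a$errors,
        n_children_evaluated = a$evaluated,
        n_children_skipped = a$skipped)
    }
  }
  do.call(rbind, out)
}

predict_one <- function(method, input, target_ages, model,
                        jb_weight, jb_height) {
  if (method == "gpmix") {
    pred <- predict(model, obs_ages = input$age_years, obs_bmi = input$bmi,
                    target_ages = target_ages)
    mm <- mixture_moments(pred)
    list(mean = mm$mean, points = prediction_points(pred))
  } else if (method == "spline") {
    fit <- fit_cubic_spline(input$age_years, input$bmi)
    list(mean = predict(fit, target_ages), points = NULL)
  } else {
    if (!all(c("weight_kg", "height_cm") %in% names(input))) {
      stop("Jenss-Bayley needs weight and height columns", call. = FALSE)
    }
    okw <- is.finite(input$weight_kg)
    okh <- is.finite(input$height_cm)
    if (sum(okw) < 2 || sum(okh) < 2) {
      stop("Jenss-Bayley needs at least 2 observations per child",
           call. = FALSE)
    }
    pw <- jb_eb_params(jb_weight, input$age_years[okw], input$weight_kg[okw])
    ph <- jb_eb_params(jb_height, input$age_years[okh], input$height_cm[okh])
    w <- jenss_bayley_curve(target_ages, pw["a"], pw["b"], pw["c"], pw["d"])
    h <- jenss_bayley_curve(target_ages, ph["a"], ph["b"], ph["c"], ph["d"])
    if (any(h <= 0)) stop("non-positive composed height", call. = FALSE)
    list(mean = w / (h / 100)^2, points = NULL)
  }
}
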