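#' Sex-specific overweight/obesity BMI threshold at age 10
#'
#' Default cutoffs are the sex-specific 90th percentiles of the reference
#' population underlying the modeled cohort: 22.0 kg/m^2 for girls and
#' 22.8 kg/m^2 for boys. Both can be overridden.
#'
#' @param sex `"female"` or `"male"`.
#' @param override `NULL`, a single number applied to both sexes, or a named
#'   list/vector with entries `female` and `male`.
#' @return The threshold in kg/m^2.
#' @examples
#' overweight_threshold("female")  # 22.0
#' overweight_threshold("male")    # 22.8
#' @export
overweight_threshold <- function(sex, override = NULL) {
  sex <- map_sex(sex)
  if (any(is.na(sex))) stop("unknown sex", call. = FALSE)
  if (!is.null(override)) {
    if (length(override) == 1L && is.null(names(override))) {
      return(rep(as.numeric(override), length(sex)))
    }
    return(as.numeric(unlist(override)[sex]))
  }
  unname(c(female = 22.0, male = 22.8)[sex])
}

#' Monte-Carlo threshold-crossing probability
#'
#' Fraction of sampled trajectories whose value at the target age exceeds
#' the threshold.
#'
#' @param samples A matrix from [sample_trajectories()] (or a numeric vector
#'   of draws at a single age).
#' @param threshold BMI threshold in kg/m^2.
#' @param age Target age; required when `samples` covers several ages and
#'   `pathwise = FALSE`.
#' @param pathwise If `TRUE`, a trajectory counts as crossing when it
#'   exceeds the threshold at *any* sampled age (default: pointwise at
#'   `age` only).
#' @return Probability in `[0, 1]`.
#' @export
crossing_probability_mc <- function(samples, threshold, age = NULL,
                                    pathwise = FALSE) {
  if (is.matrix(samples) && pathwise) {
    if (nrow(samples) == 0L) stop("zero samples", call. = FALSE)
    return(mean(apply(samples > threshold, 1, any)))
  }
  if (is.matrix(samples)) {
    ages <- attr(samples, "ages")
    if (is.null(ages)) ages <- as.numeric(colnames(samples))
    col <- if (ncol(samples) == 1L && is.null(age)) 1L
    else which(abs(ages - age) < 1e-9)
    if (length(col) != 1L) stop("target age not in the sampled ages",
                                call. = FALSE)
    samples <- samples[, col]
  }
  if (length(samples) == 0L) stop("zero samples", call. = FALSE)
  mean(samples > threshold)
}

#' Analytic threshold-crossing probability
#'
#' Closed-form tail probability of the Gaussian-mixture predictive law at
#' one age: `sum_k tau_k (1 - Phi((threshold - m_k) / s_k))`, with a
#' point-mass indicator where `s_k = 0`. The exact counterpart of
#' [crossing_probability_mc()].
#'
#' @param pred A [predict.gpm_model()] result.
#' @param threshold BMI threshold in kg/m^2.
#' @param age Target age; must be one of the prediction's target ages.
#' @return Probability in `[0, 1]`.
#' @export
crossing_probability_analytic <- function(pred, threshold, age) {
  stopifnot(inherits(pred, "gpm_prediction"))
  j <- which(abs(pred$target_ages - age) < 1e-9)
  if (length(j) != 1L) stop("target age not in the prediction grid",
                            call. = FALSE)
  tails <- vapply(pred$laws, function(l) {
    s <- sqrt(max(diag(l$cov)[j], 0))
    if (s == 0) as.numeric(l$mean[j] > threshold)
    else 1 - stats::pnorm((threshold - l$mean[j]) / s)
  }, numeric(1))
  sum(pred$weights * tails)
}

#' Classify a crossing probability against a decision cutoff
#'
#' Positive when `probability >= cutoff` (boundary counts as positive).
#'
#' @param probability Probability in `[0, 1]`.
#' @param cutoff Decision cutoff in `(0, 1]`; default 5%.
#' @return Logical.
#' @export
classify_risk <- function(probability, cutoff = 0.05) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff > 1) {
    stop("`cutoff` must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(all(probability >= 0), all(probability <= 1))
  probability >= cutoff
}

#' Confusion-matrix metrics for risk classification
#'
#' @param predicted,observed Equal-length logical vectors of predicted and
#'   observed positive status.
#' @return A list of class `classification_report`: counts `tp, fp, tn, fn`
#'   and `sensitivity, specificity, accuracy, ppv, npv` (a ratio with a zero
#'   denominator is reported as `NA`, not 0).
#' @export
score_classification <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) == 0L) {
    stop("`predicted` and `observed` must have equal positive length",
         call. = FALSE)
  }
  predicted <- as.logical(predicted)
  observed <- as.logical(observed)
  tp <- sum(predicted & observed)
  fp <- sum(predicted & !observed)
  tn <- sum(!predicted & !observed)
  fn <- sum(!predicted & observed)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 accuracy = (tp + tn) / length(predicted),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("TP %d FP %d TN %d FN %d | sens %.3f spec %.3f acc %.3f ppv %.3f npv %.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity,
              x$accuracy, x$ppv, x$npv))
  invisible(x)
}

#' Prospective overweight/obesity risk pipeline
#'
#' For each child with a measured BMI near the target age and each history
#' threshold: keep the observations before the threshold, predict at the
#' target age, convert the mixture predictive law into a crossing
#' probability (Monte-Carlo trajectory sampling by default; the closed-form
#' mixture tail as a fast mode), classify against the decision cutoff, and
#' score against the observed status (measured BMI vs the sex-specific
#' threshold). Children without a measurement within `age_tol` of the
#' target age are excluded and counted.
#'
#' @param model A fitted [gpm_fit()] model.
#' @param test A [growth_cohort()].
#' @param age_thresholds History cutoffs in years.
#' @param target_age Age at which overweight status is assessed.
#' @param n_samples Monte-Carlo draws per child.
#' @param cutoff Decision cutoff on the probability.
#' @param seed Integer seed for the sampling.
#' @param age_tol Matching tolerance (years) for "measured at the target
#'   age".
#' @param engine `"mc"` (trajectory sampling) or `"analytic"`.
#' @param threshold_override Passed to [overweight_threshold()].
#' @return A list with `results` (per child x threshold tibble of
#'   probabilities and classifications), `reports` (per-threshold tibble of
#'   confusion metrics) and `n_excluded`.
#' @export
run_risk_pipeline <- function(model, test, age_thresholds = c(2, 4, 6, 8),
                              target_age = 10, n_samples = 100000,
                              cutoff = 0.05, seed = 1, age_tol = 0.25,
                              engine = c("mc", "analytic"),
                              threshold_override = NULL) {
  stopifnot(inherits(model, "gpm_model"), inherits(test, "growth_cohort"))
  engine <- match.arg(engine)
  ids <- child_ids(test)
  rows <- list()
  excluded <- 0L
  for (j in seq_along(ids)) {
    ob <- child_obs(test, ids[j])
    near <- which(abs(ob$age_years - target_age) <= age_tol)
    if (length(near) == 0L) {
      excluded <- excluded + 1L
      next
    }
    near <- near[which.min(abs(ob$age_years[near] - target_age))]
    sex <- ob$sex[1]
    thr <- overweight_threshold(sex, threshold_override)
    status <- ob$bmi[near] > thr
    for (h in age_thresholds) {
      hist <- ob[ob$age_years < h, , drop = FALSE]
      pred <- predict(model, obs_ages = hist$age_years, obs_bmi = hist$bmi,
                      target_ages = target_age)
      prob <- if (engine == "mc") {
        draws <- sample_trajectories(pred, n_samples,
                                     seed = seed + 7919L * j + round(h))
        crossing_probability_mc(draws, thr, age = target_age)
      } else {
        crossing_probability_analytic(pred, thr, age = target_age)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        child_id = ids[j], sex = sex, age_threshold = h,
        target_age = target_age, threshold_bmi = thr,
        n_history = nrow(hist), probability = prob,
        classified_positive = classify_risk(prob, cutoff),
        observed_positive = status)
    }
  }
  results <- do.call(rbind, rows)
  reports <- do.call(rbind, lapply(age_thresholds, function(h) {
    r <- results[results$age_threshold == h, ]
    s <- score_classification(r$classified_positive, r$observed_positive)
    tibble::tibble(age_threshold = h, n = nrow(r),
                   tp = s$tp, fp = s$fp, tn = s$tn, fn = s$fn,
                   sensitivity = s$sensitivity, specificity = s$specificity,
                   accuracy = s$accuracy, ppv = s$ppv, npv = s$npv)
  }))
  list(results = results, reports = reports, n_excluded = excluded)
}
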