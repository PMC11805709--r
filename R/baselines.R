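#' Jenss-Bayley growth curve
#'
#' The four-parameter early-childhood growth function
#' `f(t) = a + b t - exp(c - d t)`: a linear part plus a decaying
#' exponential capturing the rapid infancy phase. The sign convention is
#' `- exp(c - d t)` with `d > 0` (equivalently `+ exp(c' + d' t)` with
#' `d' < 0`).
#'
#' @param t Ages in years.
#' @param a Intercept of the linear part (trait units).
#' @param b Slope of the linear part per year.
#' @param c Log-scale of the exponential term.
#' @param d Decay rate per year, `> 0`.
#' @return Trait values at `t`.
#' @examples
#' jenss_bayley_curve(0:3, a = 10, b = 1, c = 0, d = 1)
#' @export
jenss_bayley_curve <- function(t, a, b, c, d) {
  stopifnot(d > 0)
  e <- exp(c - d * t)
  if (!all(is.finite(e))) stop("overflow in exp(c - d t)", call. = FALSE)
  a + b * t - e
}

#' Fit the hierarchical Jenss-Bayley mixed-effects model
#'
#' Fits `y = a_i + b_i t - exp(c_i - d t) + noise` to a cohort trait by
#' nonlinear mixed-effects estimation (Lindstrom-Bates iterative
#' linearization via [nlme::nlme()]), with child-level random effects on
#' `(a, b, c)` and `d` fixed at the population level (d is weakly identified
#' per child with sparse infancy data). Children with fewer than 2
#' observations are excluded and counted. If the general positive-definite
#' random-effect covariance does not converge, a diagonal covariance is
#' tried; persistent failure returns a flagged result rather than an error.
#'
#' @param cohort A [growth_cohort()], or a data frame with columns
#'   `child_id`, `age_years` and the trait column.
#' @param trait `"weight"`, `"height"`, `"bmi"`, or `"value"` (the column
#'   `weight_kg`, `height_cm`, `bmi` or `value` respectively).
#' @param start Optional named starting values `c(a, b, c, d)`; otherwise a
#'   pooled heuristic is used (linear fit on later ages, log-linear fit of
#'   early residuals).
#' @return An object of class `jb_population`: fixed effects, random-effect
#'   covariance over `(a, b, c)`, residual SD, per-child empirical-Bayes
#'   parameters, exclusion count and convergence flag.
#' @export
fit_jb_mixed <- function(cohort, trait = c("weight", "height", "bmi", "value"),
                         start = NULL) {
  trait <- match.arg(trait)
  col <- switch(trait, weight = "weight_kg", height = "height_cm",
                bmi = "bmi", value = "value")
  df <- if (inherits(cohort, "growth_cohort")) cohort$records else
    tibble::as_tibble(cohort)
  if (!(col %in% names(df))) {
    stop("trait column not present: ", col, call. = FALSE)
  }
  df <- df[is.finite(df[[col]]), c("child_id", "age_years", col)]
  names(df) <- c("id", "t", "y")
  cnt <- table(df$id)
  excluded <- sum(cnt < 2)
  df <- df[df$id %in% names(cnt)[cnt >= 2], , drop = FALSE]
  if (length(unique(df$id)) < 3) {
    stop("need at least 3 children with >= 2 observations", call. = FALSE)
  }

  if (is.null(start)) start <- jb_start_values(df$t, df$y)
  df$id <- factor(df$id)

  fit <- NULL
  flag <- "converged"
  for (random in list(nlme::pdSymm(a + b + c ~ 1),
                      nlme::pdDiag(a + b + c ~ 1))) {
    fit <- tryCatch(
      suppressWarnings(
        nlme::nlme(y ~ a + b * t - exp(c - d * t),
                   fixed = a + b + c + d ~ 1,
                   random = random,
                   groups = ~id,
                   data = df,
                   start = start,
                   control = nlme::nlmeControl(maxIter = 100, msMaxIter = 150,
                                               returnObject = TRUE))),
      error = function(e) NULL)
    if (!is.null(fit)) break
    flag <- "pdSymm failed; diagonal random effects"
  }
  if (is.null(fit)) {
    stop("Jenss-Bayley mixed model failed to converge for trait ", trait,
         call. = FALSE)
  }

  fe <- nlme::fixef(fit)
  re_cov <- nlme::pdMatrix(fit$modelStruct$reStruct)[[1]] * fit$sigma^2
  dimnames(re_cov) <- list(c("a", "b", "c"), c("a", "b", "c"))
  resid_sd <- fit$sigma
  co <- stats::coef(fit)  # per-child (a, b, c, d); d equals the fixed effect
  eb <- tibble::tibble(child_id = rownames(co), a = co$a, b = co$b,
                       c = co$c, d = co$d)
  # diagnostic only: count fitted children whose curve is not monotone
  # increasing on [0, 10] (expected for weight/height, not enforced)
  tt <- seq(0, 10, by = 0.1)
  nonmono <- sum(vapply(seq_len(nrow(eb)), function(i) {
    any(diff(jenss_bayley_curve(tt, eb$a[i], eb$b[i], eb$c[i],
                                eb$d[i])) < 0)
  }, logical(1)))

  structure(list(trait = trait, fixed = fe, re_cov = re_cov,
                 resid_sd = resid_sd, eb_params = eb,
                 n_excluded = excluded, flag = flag,
                 n_nonmonotone = nonmono),
            class = "jb_population")
}

#' @export
print.jb_population <- function(x, ...) {
  cat(sprintf("Jenss-Bayley mixed model (%s): a=%.3f b=%.3f c=%.3f d=%.3f\n",
              x$trait, x$fixed["a"], x$fixed["b"], x$fixed["c"], x$fixed["d"]))
  cat(sprintf("  residual SD %.3f; %d child(ren) excluded (<2 obs); %s\n",
              x$resid_sd, x$n_excluded, x$flag))
  invisible(x)
}

# Pooled starting values: linear part from ages >= 3 (where the exponential
# has died out), exponential part from a log-linear fit of early residuals.
jb_start_values <- function(t, y) {
  late <- t >= 3
  if (sum(late) < 2) late <- t >= stats::median(t)
  lf <- stats::lm(y ~ t, subset = late)
  a0 <- unname(stats::coef(lf)[1])
  b0 <- unname(stats::coef(lf)[2])
  r <- a0 + b0 * t - y
  early <- t < 2 & r > 1e-3
  if (sum(early) >= 2) {
    ef <- stats::lm(log(r[early]) ~ t[early])
    c0 <- unname(stats::coef(ef)[1])
    d0 <- max(0.2, -unname(stats::coef(ef)[2]))
  } else {
    c0 <- 0
    d0 <- 1
  }
  c(a = a0, b = b0, c = c0, d = d0)
}

#' Empirical-Bayes Jenss-Bayley parameters for a new child
#'
#' Posterior-mode child-level parameters `(a, b, c)` given fitted population
#' parameters and the child's observations, by penalized Gauss-Newton
#' (ridge penalty from the random-effect covariance); `d` stays at the
#' population value. Needs at least 2 observations.
#'
#' @param pop A [fit_jb_mixed()] result.
#' @param t,y The child's ages and trait values.
#' @param max_iter,tol Gauss-Newton iteration controls.
#' @return Named vector `c(a, b, c, d)`.
#' @export
jb_eb_params <- function(pop, t, y, max_iter = 50, tol = 1e-8) {
  stopifnot(inherits(pop, "jb_population"))
  if (length(t) < 2) {
    stop("Jenss-Bayley needs at least 2 observations per child", call. = FALSE)
  }
  fe <- pop$fixed
  D_inv <- pd_inverse(pop$re_cov)
  s2 <- pop$resid_sd^2
  # penalized objective; Inf on numerical overflow so such steps are rejected
  pen <- function(u) {
    e <- exp(fe["c"] + u[3] - fe["d"] * t)
    r <- y - (fe["a"] + u[1] + (fe["b"] + u[2]) * t - e)
    val <- sum(r^2) / s2 + drop(t(u) %*% D_inv %*% u)
    if (!is.finite(val)) Inf else val
  }
  u <- c(0, 0, 0)
  f_cur <- pen(u)
  for (it in seq_len(max_iter)) {
    e <- exp(fe["c"] + u[3] - fe["d"] * t)
    r <- y - (fe["a"] + u[1] + (fe["b"] + u[2]) * t - e)
    J <- cbind(1, t, -e)
    H <- crossprod(J) / s2 + D_inv
    g <- drop(crossprod(J, r)) / s2 - drop(D_inv %*% u)
    step <- tryCatch(solve(H, g), error = function(e2) NULL)
    if (is.null(step)) break
    # step-halving: Gauss-Newton on an exponential model can overshoot badly
    lam <- 1
    repeat {
      f_new <- pen(u + lam * step)
      if (f_new <= f_cur + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (lam < 1e-6) break
    u <- u + lam * step
    moved <- lam * sqrt(sum(step^2))
    f_cur <- pen(u)
    if (moved < tol) break
  }
  c(a = unname(fe["a"] + u[1]), b = unname(fe["b"] + u[2]),
    c = unname(fe["c"] + u[3]), d = unname(fe["d"]))
}

#' Jenss-Bayley BMI trajectory composed from weight and height fits
#'
#' Evaluates a child's empirical-Bayes weight and height curves and composes
#' `BMI(t) = weight(t) / (height(t)/100)^2`.
#'
#' @param weight_model,height_model [fit_jb_mixed()] results for weight (kg)
#'   and height (cm).
#' @param child_id A child present in both models' `eb_params`.
#' @param t Ages at which to evaluate.
#' @return BMI values at `t`.
#' @export
jb_bmi_trajectory <- function(weight_model, height_model, child_id, t) {
  pw <- jb_child_params(weight_model, child_id)
  ph <- jb_child_params(height_model, child_id)
  w <- jenss_bayley_curve(t, pw["a"], pw["b"], pw["c"], pw["d"])
  h <- jenss_bayley_curve(t, ph["a"], ph["b"], ph["c"], ph["d"])
  if (any(h <= 0)) stop("non-positive height on the requested ages",
                        call. = FALSE)
  w / (h / 100)^2
}

jb_child_params <- function(pop, child_id) {
  row <- pop$eb_params[pop$eb_params$child_id == child_id, ]
  if (nrow(row) == 0) stop("child not in fitted model: ", child_id,
                           call. = FALSE)
  c(a = row$a, b = row$b, c = row$c, d = row$d)
}

#' Per-child cubic smoothing spline
#'
#' Fits a cubic smoothing spline to one child's points only
#' ([stats::smooth.spline()]; smoothing chosen by generalized
#' cross-validation unless `spar` is given). Requires at least 4 distinct
#' observed ages. Evaluation outside the observed range uses the natural
#' spline's linear extrapolation.
#'
#' @param ages,bmi The child's observed ages and BMI values.
#' @param spar Optional fixed smoothing parameter passed to
#'   [stats::smooth.spline()].
#' @return An object of class `bmi_spline` with a `predict` method.
#' @export
fit_cubic_spline <- function(ages, bmi, spar = NULL) {
  stopifnot(length(ages) == length(bmi))
  if (length(unique(ages)) < 4) {
    stop("insufficient points: cubic spline fitting requires at least 4 ",
         "distinct observed time points", call. = FALSE)
  }
  fit <- if (is.null(spar)) stats::smooth.spline(ages, bmi)
  else stats::smooth.spline(ages, bmi, spar = spar)
  structure(list(fit = fit, range = range(ages)), class = "bmi_spline")
}

#' @export
predict.bmi_spline <- function(object, newage, ...) {
  stats::predict(object$fit, x = newage)$y
}

#' @export
print.bmi_spline <- function(x, ...) {
  cat(sprintf("Cubic smoothing spline on %d points, ages %.2f-%.2f y\n",
              length(x$fit$x), x$range[1], x$range[2]))
  invisible(x)
}
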