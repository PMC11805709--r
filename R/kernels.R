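#' Squared-exponential kernel parameters
#'
#' Container for the two hyper-parameters of a squared-exponential (SE)
#' covariance function: the signal variance (in squared units of the modeled
#' trait, here (kg/m^2)^2) and the lengthscale (in years). Both must be
#' strictly positive; optimization routines work on the log scale.
#'
#' @param variance Signal variance, strictly positive.
#' @param lengthscale Correlation lengthscale in years, strictly positive.
#' @return An object of class `kernel_params`.
#' @examples
#' kernel_params(variance = 1, lengthscale = 2)
#' @export
kernel_params <- function(variance, lengthscale) {
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance <= 0) {
    stop("`variance` must be a single strictly positive number", call. = FALSE)
  }
  if (!is.numeric(lengthscale) || length(lengthscale) != 1L ||
      !is.finite(lengthscale) || lengthscale <= 0) {
    stop("`lengthscale` must be a single strictly positive number", call. = FALSE)
  }
  structure(list(variance = variance, lengthscale = lengthscale),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("SE kernel: variance = %.4g, lengthscale = %.4g y\n",
              x$variance, x$lengthscale))
  invisible(x)
}

#' Squared-exponential covariance matrix
#'
#' Computes `K[i, j] = variance * exp(-(t1[i] - t2[j])^2 / (2 * lengthscale^2))`.
#'
#' @param t1,t2 Numeric vectors of ages (years).
#' @param params A [kernel_params()] object.
#' @return A `length(t1)` by `length(t2)` covariance matrix.
#' @examples
#' se_kernel(0:2, 0:2, kernel_params(1, 1))
#' @export
se_kernel <- function(t1, t2, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (!all(is.finite(t1)) || !all(is.finite(t2))) {
    stop("ages must be finite", call. = FALSE)
  }
  d <- outer(t1, t2, "-")
  params$variance * exp(-d^2 / (2 * params$lengthscale^2))
}

# Cholesky with escalating jitter. SE kernels on near-duplicate ages are
# ill-conditioned; start at 1e-10 * max(diag) and escalate x10 up to
# 1e-4 * max(diag) before failing.
chol_jitter <- function(S, jitter0 = 1e-10, jitter_max = 1e-4) {
  scale <- max(diag(S), .Machine$double.eps)
  jit <- jitter0 * scale
  cap <- jitter_max * scale
  repeat {
    L <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- jit * 10
    if (jit > cap) {
      stop("covariance matrix is not positive definite even after jitter ",
           "escalation; the conditioning set is likely degenerate",
           call. = FALSE)
    }
  }
}

# Symmetric PD inverse through the jittered Cholesky.
pd_inverse <- function(S) {
  L <- chol_jitter(S)
  chol2inv(L)
}

#' Multivariate Gaussian log-density
#'
#' Log density of `y` under N(mean, cov), evaluated through a jittered
#' Cholesky factorization.
#'
#' @param y Numeric vector of observed values.
#' @param mean Mean vector, same length as `y`.
#' @param cov Covariance matrix (PSD up to jitter).
#' @return The log density in nats.
#' @examples
#' gaussian_loglik(c(0, 0), c(0, 0), diag(2))  # -log(2*pi)
#' @export
gaussian_loglik <- function(y, mean, cov) {
  n <- length(y)
  if (length(mean) != n || !all(dim(cov) == c(n, n))) {
    stop("dimension mismatch between `y`, `mean` and `cov`", call. = FALSE)
  }
  L <- chol_jitter(cov)
  r <- backsolve(L, y - mean, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(r^2)
}

#' Gaussian predictive law on an age grid
#'
#' A mean vector and covariance matrix over a common age grid; the basic
#' currency of all predictions in the package.
#'
#' @param ages Numeric vector of ages (years).
#' @param mean Mean vector (kg/m^2), same length as `ages`.
#' @param cov Covariance matrix ((kg/m^2)^2), symmetric PSD up to jitter.
#' @return An object of class `gaussian_law`.
#' @export
gaussian_law <- function(ages, mean, cov) {
  n <- length(ages)
  stopifnot(length(mean) == n, all(dim(cov) == c(n, n)))
  cov <- (cov + t(cov)) / 2
  structure(list(ages = ages, mean = as.numeric(mean), cov = cov),
            class = "gaussian_law")
}

#' @export
print.gaussian_law <- function(x, ...) {
  cat(sprintf("Gaussian law on %d ages in [%.3g, %.3g] y\n",
              length(x$ages), min(x$ages), max(x$ages)))
  invisible(x)
}

#' Gaussian process conditional (posterior) law
#'
#' Standard GP regression: conditions a GP prior on noisy observations and
#' returns the posterior law of the latent function at `target_t`. The prior
#' is either an SE kernel prior (`prior_params`, with constant `prior_mean`)
#' or an explicit mean vector / covariance matrix over `c(obs_t, target_t)`
#' (`prior_mean`, `prior_cov`), which is how the mixture model conditions on
#' its non-stationary cluster-level priors. With zero observations the prior
#' law at `target_t` is returned.
#'
#' @param obs_t,obs_y Observed ages and values (equal length; may be empty).
#' @param target_t Ages at which the posterior is requested.
#' @param prior_params A [kernel_params()] prior covariance (ignored when
#'   `prior_cov` is supplied).
#' @param prior_mean Constant, or vector over `c(obs_t, target_t)`.
#' @param prior_cov Optional explicit prior covariance over `c(obs_t, target_t)`.
#' @param noise_var Observation noise variance, `>= 0`.
#' @return A [gaussian_law()] at `target_t` (latent function, noise-free; add
#'   `noise_var` to the diagonal for a predictive law of observations).
#' @examples
#' gp_conditional(c(1, 2), c(15, 16), seq(0, 3, 0.5),
#'                prior_params = kernel_params(1, 1), prior_mean = 15,
#'                noise_var = 0.1)
#' @export
gp_conditional <- function(obs_t, obs_y, target_t,
                           prior_params = NULL, prior_mean = 0,
                           prior_cov = NULL, noise_var = 0) {
  n <- length(obs_t)
  m <- length(target_t)
  if (length(obs_y) != n) stop("`obs_t` and `obs_y` lengths differ", call. = FALSE)
  if (noise_var < 0) stop("`noise_var` must be >= 0", call. = FALSE)

  all_t <- c(obs_t, target_t)
  if (is.null(prior_cov)) {
    stopifnot(inherits(prior_params, "kernel_params"))
    prior_cov <- se_kernel(all_t, all_t, prior_params)
  } else {
    stopifnot(all(dim(prior_cov) == c(n + m, n + m)))
  }
  mu <- if (length(prior_mean) == 1L) rep(prior_mean, n + m) else prior_mean
  stopifnot(length(mu) == n + m)

  oi <- seq_len(n)
  ti <- n + seq_len(m)
  if (n == 0L) {
    return(gaussian_law(target_t, mu[ti], prior_cov[ti, ti, drop = FALSE]))
  }
  Koo <- prior_cov[oi, oi, drop = FALSE] + diag(noise_var, n)
  Kot <- prior_cov[oi, ti, drop = FALSE]
  L <- chol_jitter(Koo)
  alpha <- backsolve(L, backsolve(L, obs_y - mu[oi], transpose = TRUE))
  V <- backsolve(L, Kot, transpose = TRUE)
  post_mean <- mu[ti] + drop(crossprod(Kot, alpha))
  post_cov <- prior_cov[ti, ti, drop = FALSE] - crossprod(V)
  gaussian_law(target_t, post_mean, post_cov)
}
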