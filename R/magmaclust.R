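#' Control settings for the mixture fit
#'
#' @param max_iter Maximum number of VEM iterations.
#' @param tol Convergence threshold on the change of the evidence lower
#'   bound (ELBO) between iterations, in nats.
#' @param seed Integer seed for the k-means initialization.
#' @param kmeans_nstart Number of seeded k-means restarts for the
#'   membership initialization.
#' @param optim_maxit Iteration cap for each Nelder-Mead hyper-parameter
#'   update inside the M-step.
#' @param empty_tol Total responsibility below which a cluster is frozen and
#'   flagged empty (its hyper-parameters stop being re-optimized).
#' @param n_init Number of VEM restarts from different k-means seeds
#'   (mixture likelihoods are multimodal; restart selection by ELBO is the
#'   standard remedy).
#' @param init_iter Burn-in iterations per restart when `n_init > 1`.
#' @param n_keep Number of best-ELBO restarts continued to convergence after
#'   the burn-in; the final model is the one with the best converged ELBO.
#' @param common_mean_kernel If `TRUE` (default), the mean-process SE kernel
#'   hyper-parameters are shared across clusters and estimated jointly; with
#'   `FALSE` each cluster optimizes its own. Sharing regularizes sparsely
#'   populated components, which otherwise inflate their own kernel variance
#'   to absorb a handful of outlying children.
#' @return A list of class `gpm_control`.
#' @export
gpm_control <- function(max_iter = 100, tol = 1e-3, seed = 1,
                        kmeans_nstart = 5, optim_maxit = 60,
                        empty_tol = 1e-8, n_init = 1, init_iter = 40,
                        n_keep = 2, common_mean_kernel = TRUE) {
  structure(list(max_iter = max_iter, tol = tol, seed = seed,
                 kmeans_nstart = kmeans_nstart, optim_maxit = optim_maxit,
                 empty_tol = empty_tol, n_init = n_init,
                 init_iter = init_iter, n_keep = n_keep,
                 common_mean_kernel = common_mean_kernel),
            class = "gpm_control")
}

# Internal: per-child observation index/value lists against a common grid.
# `lin` holds the linear indices of the [idx, idx] submatrix of a p x p
# matrix and `dpos` the diagonal positions within that submatrix, so hot
# loops can extract Psi_i with a single vector subset.
child_blocks <- function(cohort, grid) {
  ids <- child_ids(cohort)
  p <- length(grid)
  lapply(ids, function(id) {
    ob <- child_obs(cohort, id)
    idx <- match(ob$age_years, grid)
    ni <- length(idx)
    lin <- as.vector(outer(idx, (idx - 1) * p, "+"))
    list(id = id, idx = idx, y = ob$bmi, n = ni, lin = lin,
         dpos = seq(1, ni * ni, by = ni + 1))
  })
}

# Per-child Psi_i = K_theta[idx, idx] + sigma2 I factorizations. Psi is
# well-conditioned for any meaningful sigma2, so a plain Cholesky is used
# with the jittered version as a rare fallback.
psi_inverses <- function(blocks, Kth, sigma2) {
  lapply(blocks, function(b) {
    Psi <- matrix(Kth[b$lin], b$n)
    Psi[b$dpos] <- Psi[b$dpos] + sigma2
    L <- tryCatch(chol(Psi), error = function(e) chol_jitter(Psi))
    list(inv = chol2inv(L), logdet = 2 * sum(log(diag(L))))
  })
}

log_norm_rows <- function(logw) {
  mx <- apply(logw, 1, max)
  w <- exp(logw - mx)
  w / rowSums(w)
}

#' Fit the multi-task Gaussian process mixture
#'
#' Fits the package's core model to a training cohort: observed trajectories
#' are `y_i = mu_{Z_i} + f_i + noise`, where the K cluster mean processes
#' `mu_k ~ GP(m0, SE(gamma_k))` are shared across children, the individual
#' deviations `f_i ~ GP(0, SE(theta))` use a common kernel, and the noise is
#' i.i.d. `N(0, sigma^2)`. Training alternates closed-form variational
#' updates of the mean-process hyper-posteriors `(m_k, C_k)` on the pooled
#' age grid and of the membership probabilities `tau`, with gradient-free
#' M-step updates of `(gamma_k, theta, sigma^2)` on the log scale and
#' `pi_k = mean_i tau_ik`, until the ELBO change falls below `control$tol`.
#'
#' Memberships are initialized by seeded k-means on per-child summary
#' features (mean BMI and BMI-vs-age slope); the prior mean of every mean
#' process is the training grand-mean BMI. A cluster whose total
#' responsibility falls below `control$empty_tol` is frozen and flagged
#' empty rather than deleted.
#'
#' @param train A [growth_cohort()]; every child needs at least one record.
#' @param K Number of mixture components, `>= 1`.
#' @param control A [gpm_control()].
#' @return An object of class `gpm_model` with elements `K`, `grid`,
#'   `mean_kernels`, `individual_kernel`, `noise_var`, `prior_mean`,
#'   `mixture_weights`, `mean_hyperpost` (list of [gaussian_law()]s),
#'   `memberships` (children x K matrix), `elbo_trace`, `empty` (logical),
#'   and cached training sufficient statistics used by [predict.gpm_model()].
#' @export
gpm_fit <- function(train, K, control = gpm_control()) {
  stopifnot(inherits(train, "growth_cohort"), K >= 1)
  grid <- sort(unique(train$records$age_years))
  p <- length(grid)
  blocks <- child_blocks(train, grid)
  n <- length(blocks)
  ids <- vapply(blocks, `[[`, "", "id")
  m0 <- mean(train$records$bmi)
  m0_vec <- rep(m0, p)

  new_state <- function(init_seed) {
    ctrl <- control
    ctrl$seed <- init_seed
    list(tau = init_memberships(train, K, ctrl),
         pi_k = rep(1 / K, K),
         gammas = replicate(K, kernel_params(3.0, 1.0), simplify = FALSE),
         theta = kernel_params(1.0, 1.5),
         sigma2 = 0.1,
         frozen = rep(FALSE, K),
         m_hat = vector("list", K), C_hat = vector("list", K),
         elbo_trace = numeric(0), converged = FALSE)
  }

  if (control$n_init > 1L) {
    burns <- lapply(seq_len(control$n_init), function(r) {
      vem_steps(new_state(control$seed + r - 1L), blocks, grid, m0_vec,
                control, control$init_iter)
    })
    elbos <- vapply(burns, function(s) utils::tail(s$elbo_trace, 1),
                    numeric(1))
    keep <- utils::head(order(elbos, decreasing = TRUE),
                        max(1L, control$n_keep))
    finals <- lapply(burns[keep], function(s) {
      vem_steps(s, blocks, grid, m0_vec, control,
                control$max_iter - control$init_iter)
    })
    best <- which.max(vapply(finals, function(s) {
      utils::tail(s$elbo_trace, 1)
    }, numeric(1)))
    state <- finals[[best]]
  } else {
    state <- vem_steps(new_state(control$seed), blocks, grid, m0_vec,
                       control, control$max_iter)
  }

  # Cache sufficient statistics of the training data for prediction-time
  # hyper-posterior recomputation on augmented grids.
  Kth <- se_kernel(grid, grid, state$theta)
  psis <- psi_inverses(blocks, Kth, state$sigma2)
  S_k <- vector("list", K)
  b_k <- vector("list", K)
  for (k in seq_len(K)) {
    S <- matrix(0, p, p)
    bb <- numeric(p)
    for (i in seq_len(n)) {
      w <- state$tau[i, k]
      if (w <= 0) next
      ix <- blocks[[i]]$idx
      S[ix, ix] <- S[ix, ix] + w * psis[[i]]$inv
      bb[ix] <- bb[ix] + w * drop(psis[[i]]$inv %*% blocks[[i]]$y)
    }
    S_k[[k]] <- S
    b_k[[k]] <- bb
  }

  tau <- state$tau
  rownames(tau) <- ids
  structure(list(K = K, grid = grid,
                 mean_kernels = state$gammas,
                 individual_kernel = state$theta,
                 noise_var = state$sigma2, prior_mean = m0,
                 mixture_weights = state$pi_k,
                 mean_hyperpost = lapply(seq_len(K), function(k) {
                   gaussian_law(grid, state$m_hat[[k]], state$C_hat[[k]])
                 }),
                 memberships = tau, elbo_trace = state$elbo_trace,
                 empty = state$frozen,
                 suffstats = list(S = S_k, b = b_k),
                 n_children = n),
            class = "gpm_model")
}

# One or more full VEM cycles (E-mu, E-Z, M, ELBO) applied to a state.
vem_steps <- function(state, blocks, grid, m0_vec, control, n_iter) {
  if (n_iter <= 0 || state$converged) return(state)
  K <- length(state$pi_k)
  n <- length(blocks)
  p <- length(grid)
  elbo_prev <- if (length(state$elbo_trace) > 0) {
    utils::tail(state$elbo_trace, 1)
  } else -Inf

  for (iter in seq_len(n_iter)) {
    Kth <- se_kernel(grid, grid, state$theta)
    psis <- psi_inverses(blocks, Kth, state$sigma2)

    # Per-child information scattered into grid coordinates (cluster-free).
    a <- lapply(seq_len(n), function(i) {
      drop(psis[[i]]$inv %*% blocks[[i]]$y)
    })

    # (E-mu) hyper-posterior of each mean process on the grid.
    for (k in seq_len(K)) {
      Cg_inv <- pd_inverse(se_kernel(grid, grid, state$gammas[[k]]))
      S <- matrix(0, p, p)
      bb <- numeric(p)
      for (i in seq_len(n)) {
        w <- state$tau[i, k]
        if (w <= 0) next
        ix <- blocks[[i]]$idx
        S[ix, ix] <- S[ix, ix] + w * psis[[i]]$inv
        bb[ix] <- bb[ix] + w * a[[i]]
      }
      state$C_hat[[k]] <- pd_inverse(Cg_inv + S)
      state$m_hat[[k]] <- drop(state$C_hat[[k]] %*%
                                 (Cg_inv %*% m0_vec + bb))
    }

    # (E-Z) membership probabilities.
    logw <- matrix(0, n, K)
    for (k in seq_len(K)) {
      for (i in seq_len(n)) {
        b <- blocks[[i]]
        r <- b$y - state$m_hat[[k]][b$idx]
        q <- drop(crossprod(r, psis[[i]]$inv %*% r))
        tr <- sum(psis[[i]]$inv * state$C_hat[[k]][b$idx, b$idx])
        logw[i, k] <- log(max(state$pi_k[k], 1e-300)) -
          0.5 * (b$n * log(2 * pi) + psis[[i]]$logdet + q + tr)
      }
    }
    state$tau <- log_norm_rows(logw)

    # (M) mixture weights, then hyper-parameters on the log scale.
    state$pi_k <- colMeans(state$tau)
    state$frozen <- state$frozen | (colSums(state$tau) < control$empty_tol)

    if (isTRUE(control$common_mean_kernel)) {
      live <- which(!state$frozen)
      g_new <- optimize_gamma_common(state$gammas[[live[1]]],
                                     state$m_hat[live], state$C_hat[live],
                                     m0_vec, grid, control$optim_maxit)
      for (k in seq_len(K)) state$gammas[[k]] <- g_new
    } else {
      for (k in seq_len(K)) {
        if (state$frozen[k]) next
        state$gammas[[k]] <- optimize_gamma(state$gammas[[k]],
                                            state$m_hat[[k]],
                                            state$C_hat[[k]], m0_vec, grid,
                                            control$optim_maxit)
      }
    }
    upd <- optimize_theta_sigma(state$theta, state$sigma2, blocks, state$tau,
                                state$m_hat, state$C_hat, grid,
                                control$optim_maxit)
    state$theta <- upd$theta
    state$sigma2 <- upd$sigma2

    elbo <- gpm_elbo(blocks, state$tau, state$pi_k, state$m_hat, state$C_hat,
                     state$gammas, state$theta, state$sigma2, grid, m0_vec)
    state$elbo_trace <- c(state$elbo_trace, elbo)
    if (is.finite(elbo_prev) && abs(elbo - elbo_prev) < control$tol) {
      state$converged <- TRUE
      break
    }
    elbo_prev <- elbo
  }
  state
}

init_memberships <- function(train, K, control) {
  ids <- child_ids(train)
  # Features: BMI linearly interpolated at anchor ages (constant beyond the
  # observed range), capturing both infancy peak intensity and later level.
  anchors <- c(0.25, 0.75, 1.5, 3, 5, 7, 10)
  feats <- t(vapply(ids, function(id) {
    ob <- child_obs(train, id)
    if (nrow(ob) == 1L) rep(ob$bmi, length(anchors))
    else stats::approx(ob$age_years, ob$bmi, xout = anchors, rule = 2)$y
  }, numeric(length(anchors))))
  feats <- scale(feats)
  feats[!is.finite(feats)] <- 0
  n <- length(ids)
  assign_k <- if (K == 1L || n <= K) {
    rep_len(seq_len(K), n)
  } else {
    local_seed(control$seed,
               stats::kmeans(feats, centers = K,
                             nstart = control$kmeans_nstart)$cluster)
  }
  tau <- matrix(0.1 / max(K - 1, 1), n, K)
  tau[cbind(seq_len(n), assign_k)] <- if (K == 1L) 1 else 0.9
  tau / rowSums(tau)
}

# Joint update of a mean-process kernel shared by several clusters: the sum
# of the per-cluster expected-lower-bound terms under one (variance,
# lengthscale) pair.
optimize_gamma_common <- function(gamma, m_hats, C_hats, m0_vec, grid,
                                  maxit) {
  p <- length(grid)
  d2 <- outer(grid, grid, "-")^2
  C_sum <- Reduce(`+`, C_hats)
  nk <- length(m_hats)
  obj <- function(lp) {
    v <- exp(lp[1])
    Cg <- v * exp(-d2 / (2 * exp(2 * lp[2])))
    diag(Cg) <- diag(Cg) + 1e-10 * v
    L <- tryCatch(chol(Cg), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    quad <- sum(vapply(m_hats, function(m) {
      sum(backsolve(L, m - m0_vec, transpose = TRUE)^2)
    }, numeric(1)))
    ll <- -nk * sum(log(diag(L))) - 0.5 * quad -
      0.5 * sum(chol2inv(L) * C_sum)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- log(c(gamma$variance, gamma$lengthscale))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  if (fit$value <= obj(start)) {
    kernel_params(exp(fit$par[1]), exp(fit$par[2]))
  } else gamma
}

optimize_gamma <- function(gamma, m_hat, C_hat, m0_vec, grid, maxit) {
  p <- length(grid)
  d2 <- outer(grid, grid, "-")^2
  obj <- function(lp) {
    v <- exp(lp[1])
    Cg <- v * exp(-d2 / (2 * exp(2 * lp[2])))
    diag(Cg) <- diag(Cg) + 1e-10 * v
    L <- tryCatch(chol(Cg), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    r <- backsolve(L, m_hat - m0_vec, transpose = TRUE)
    ll <- -sum(log(diag(L))) - 0.5 * sum(r^2) -
      0.5 * sum(chol2inv(L) * C_hat)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  start <- log(c(gamma$variance, gamma$lengthscale))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  if (fit$value <= obj(start)) {
    kernel_params(exp(fit$par[1]), exp(fit$par[2]))
  } else gamma
}

optimize_theta_sigma <- function(theta, sigma2, blocks, tau, m_hat, C_hat,
                                 grid, maxit) {
  n <- length(blocks)
  K <- ncol(tau)
  # W_i = sum_k tau_ik [ (y - m_k)(y - m_k)' + C_k[idx, idx] ] does not
  # depend on (theta, sigma2); precompute once.
  W <- vector("list", n)
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    Wi <- matrix(0, b$n, b$n)
    for (k in seq_len(K)) {
      w <- tau[i, k]
      if (w <= 0) next
      r <- b$y - m_hat[[k]][b$idx]
      Wi <- Wi + w * (tcrossprod(r) + C_hat[[k]][b$idx, b$idx])
    }
    W[[i]] <- Wi
  }
  d2 <- outer(grid, grid, "-")^2
  obj <- function(lp) {
    v <- exp(lp[1])
    s2 <- exp(lp[3])
    Kth <- v * exp(-d2 / (2 * exp(2 * lp[2])))
    total <- 0
    for (i in seq_len(n)) {
      b <- blocks[[i]]
      Psi <- matrix(Kth[b$lin], b$n)
      Psi[b$dpos] <- Psi[b$dpos] + s2
      L <- tryCatch(chol(Psi), error = function(e) NULL)
      if (is.null(L)) return(1e10)
      total <- total - sum(log(diag(L))) - 0.5 * sum(chol2inv(L) * W[[i]])
    }
    if (!is.finite(total)) return(1e10)
    -total
  }
  start <- log(c(theta$variance, theta$lengthscale, sigma2))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit))
  if (fit$value <= obj(start)) {
    list(theta = kernel_params(exp(fit$par[1]), exp(fit$par[2])),
         sigma2 = exp(fit$par[3]))
  } else list(theta = theta, sigma2 = sigma2)
}

gpm_elbo <- function(blocks, tau, pi_k, m_hat, C_hat, gammas, theta, sigma2,
                     grid, m0_vec) {
  n <- length(blocks)
  K <- length(pi_k)
  Kth <- se_kernel(grid, grid, theta)
  psis <- psi_inverses(blocks, Kth, sigma2)
  total <- 0
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    for (k in seq_len(K)) {
      w <- tau[i, k]
      if (w <= 0) next
      r <- b$y - m_hat[[k]][b$idx]
      q <- drop(crossprod(r, psis[[i]]$inv %*% r))
      tr <- sum(psis[[i]]$inv * C_hat[[k]][b$idx, b$idx])
      total <- total + w * (log(max(pi_k[k], 1e-300)) -
                              0.5 * (b$n * log(2 * pi) + psis[[i]]$logdet +
                                       q + tr) - log(w))
    }
  }
  for (k in seq_len(K)) {
    Cg <- se_kernel(grid, grid, gammas[[k]])
    Cg_inv <- pd_inverse(Cg)
    total <- total + gaussian_loglik(m_hat[[k]], m0_vec, Cg) -
      0.5 * sum(Cg_inv * C_hat[[k]])
    Lc <- chol_jitter(C_hat[[k]])
    total <- total + 0.5 * (length(grid) * (1 + log(2 * pi)) +
                              2 * sum(log(diag(Lc))))
  }
  total
}

#' @export
print.gpm_model <- function(x, ...) {
  cat(sprintf(paste0("Multi-task GP mixture: K = %d (%d non-empty), ",
                     "%d children, grid of %d ages\n"),
              x$K, count_nonempty_clusters(x), x$n_children, length(x$grid)))
  cat(sprintf("  noise SD = %.3f kg/m^2; individual kernel: var %.3f, ls %.2f y\n",
              sqrt(x$noise_var), x$individual_kernel$variance,
              x$individual_kernel$lengthscale))
  cat(sprintf("  ELBO: %.2f after %d iterations\n",
              utils::tail(x$elbo_trace, 1), length(x$elbo_trace)))
  invisible(x)
}

#' Number of non-empty clusters
#'
#' Counts clusters that at least `min_members` children are assigned to by
#' argmax membership (ties broken toward the lower cluster index).
#'
#' @param model A fitted [gpm_fit()] model.
#' @param min_members Minimum argmax-membership size for a cluster to count.
#' @return Integer count.
#' @export
count_nonempty_clusters <- function(model, min_members = 2) {
  stopifnot(inherits(model, "gpm_model"))
  hard <- max.col(model$memberships, ties.method = "first")
  sizes <- tabulate(hard, nbins = model$K)
  sum(sizes >= min_members)
}

# Recompute the per-cluster mean-process hyper-posterior on an augmented
# grid from the cached training sufficient statistics (exact: training
# contributions live only on training-grid coordinates).
hyperpost_on_grid <- function(model, aug) {
  p <- length(aug)
  pos <- match(model$grid, aug)
  m0_vec <- rep(model$prior_mean, p)
  lapply(seq_len(model$K), function(k) {
    Cg <- se_kernel(aug, aug, model$mean_kernels[[k]])
    Cg_inv <- pd_inverse(Cg)
    S <- matrix(0, p, p)
    S[pos, pos] <- model$suffstats$S[[k]]
    bb <- numeric(p)
    bb[pos] <- model$suffstats$b[[k]]
    C <- pd_inverse(Cg_inv + S)
    m <- drop(C %*% (Cg_inv %*% m0_vec + bb))
    gaussian_law(aug, m, C)
  })
}

#' Mixture predictive law for one child
#'
#' For each cluster, recomputes the mean-process hyper-posterior on the
#' union of the training grid, the child's observed ages and the target
#' ages; forms the child-level prior
#' `N(m_k, C_k + K_theta + sigma^2 I)` on that grid; and conditions on the
#' child's observations. Membership weights come from the variational
#' E-step formula applied to the observations; with no observations the
#' learned mixture weights are returned (a population-level prediction).
#' The returned per-cluster laws are predictive laws of *observations*
#' (noise variance included on the diagonal).
#'
#' @param object A fitted [gpm_fit()] model.
#' @param obs_ages,obs_bmi The child's observed ages and BMI values (may be
#'   empty vectors).
#' @param target_ages Ages at which to predict.
#' @param ... Unused.
#' @return An object of class `gpm_prediction`: list with `target_ages`,
#'   `laws` (per-cluster [gaussian_law()]s), `weights`, and the
#'   conditioning observations.
#' @export
predict.gpm_model <- function(object, obs_ages = numeric(0),
                              obs_bmi = numeric(0), target_ages, ...) {
  model <- object
  stopifnot(length(obs_ages) == length(obs_bmi), length(target_ages) >= 1)
  aug <- sort(unique(c(model$grid, obs_ages, target_ages)))
  hyper <- if (identical(aug, model$grid)) model$mean_hyperpost
  else hyperpost_on_grid(model, aug)
  Kth <- se_kernel(aug, aug, model$individual_kernel)
  io <- match(obs_ages, aug)
  it <- match(target_ages, aug)
  s2 <- model$noise_var
  n_obs <- length(io)

  laws <- vector("list", model$K)
  logw <- numeric(model$K)
  for (k in seq_len(model$K)) {
    prior_cov <- hyper[[k]]$cov + Kth
    sel <- c(io, it)
    law <- gp_conditional(obs_t = obs_ages, obs_y = obs_bmi,
                          target_t = target_ages,
                          prior_mean = hyper[[k]]$mean[sel],
                          prior_cov = prior_cov[sel, sel, drop = FALSE],
                          noise_var = s2)
    law$cov <- law$cov + diag(s2, length(target_ages))
    laws[[k]] <- law
    if (n_obs > 0) {
      Psi <- Kth[io, io, drop = FALSE] + diag(s2, n_obs)
      L <- chol_jitter(Psi)
      Pinv <- chol2inv(L)
      r <- obs_bmi - hyper[[k]]$mean[io]
      logw[k] <- log(max(model$mixture_weights[k], 1e-300)) -
        0.5 * (n_obs * log(2 * pi) + 2 * sum(log(diag(L))) +
                 drop(crossprod(r, Pinv %*% r)) +
                 sum(Pinv * hyper[[k]]$cov[io, io]))
    }
  }
  weights <- if (n_obs > 0) drop(log_norm_rows(matrix(logw, 1)))
  else model$mixture_weights
  structure(list(target_ages = target_ages, laws = laws, weights = weights,
                 obs_ages = obs_ages, obs_bmi = obs_bmi),
            class = "gpm_prediction")
}

#' @export
print.gpm_prediction <- function(x, ...) {
  cat(sprintf("Mixture prediction at %d ages; top cluster weight %.3f\n",
              length(x$target_ages), max(x$weights)))
  invisible(x)
}

#' Mixture predictive mean and variance
#'
#' Pointwise moments of the Gaussian-mixture predictive law.
#'
#' @param pred A [predict.gpm_model()] result.
#' @return A tibble with columns `age`, `mean`, `var`.
#' @export
mixture_moments <- function(pred) {
  stopifnot(inherits(pred, "gpm_prediction"))
  mu <- sapply(pred$laws, `[[`, "mean")
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  v <- sapply(pred$laws, function(l) diag(l$cov))
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  w <- pred$weights
  m <- drop(mu %*% w)
  second <- drop((v + mu^2) %*% w)
  tibble::tibble(age = pred$target_ages, mean = m, var = second - m^2)
}

#' Sample trajectories from a mixture prediction
#'
#' Each draw samples a cluster from the membership weights, then a
#' multivariate normal path from that cluster's predictive law.
#' Reproducible given `seed`.
#'
#' @param pred A [predict.gpm_model()] result.
#' @param n_samples Number of draws, `>= 1`.
#' @param seed Integer seed.
#' @return A `n_samples` x `length(target_ages)` matrix of trajectories,
#'   with the target ages as column names.
#' @export
sample_trajectories <- function(pred, n_samples, seed) {
  stopifnot(inherits(pred, "gpm_prediction"), n_samples >= 1)
  m <- length(pred$target_ages)
  K <- length(pred$laws)
  local_seed(seed, {
    ks <- sample.int(K, n_samples, replace = TRUE, prob = pred$weights)
    out <- matrix(0, n_samples, m)
    for (k in seq_len(K)) {
      rows <- which(ks == k)
      if (length(rows) == 0) next
      law <- pred$laws[[k]]
      if (max(abs(law$cov)) < 1e-14) {
        out[rows, ] <- matrix(law$mean, length(rows), m, byrow = TRUE)
      } else {
        R <- chol_jitter(law$cov)
        Z <- matrix(stats::rnorm(length(rows) * m), length(rows), m)
        out[rows, ] <- Z %*% R +
          matrix(law$mean, length(rows), m, byrow = TRUE)
      }
    }
    colnames(out) <- format(pred$target_ages)
    attr(out, "ages") <- pred$target_ages
    out
  })
}

#' Serialize a fitted model to a portable JSON file
#'
#' Writes every learned quantity (grid, hyper-parameters, hyper-posteriors,
#' memberships, cached sufficient statistics) as plain arrays under a
#' versioned format tag; [read_gpm_model()] restores a working model.
#'
#' @param model A `gpm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gpm_model <- function(model, path) {
  stopifnot(inherits(model, "gpm_model"))
  obj <- list(
    format = "gpgrowth-model-v1",
    K = model$K, grid = model$grid,
    mean_kernels = lapply(model$mean_kernels, unclass),
    individual_kernel = unclass(model$individual_kernel),
    noise_var = model$noise_var, prior_mean = model$prior_mean,
    mixture_weights = model$mixture_weights,
    hyperpost_mean = lapply(model$mean_hyperpost, `[[`, "mean"),
    hyperpost_cov = lapply(model$mean_hyperpost, `[[`, "cov"),
    memberships = model$memberships,
    member_ids = rownames(model$memberships),
    elbo_trace = model$elbo_trace, empty = model$empty,
    suff_S = model$suffstats$S, suff_b = model$suffstats$b,
    n_children = model$n_children)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a model written by [write_gpm_model()]
#'
#' @param path Path to the JSON file.
#' @return A `gpm_model`.
#' @export
read_gpm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "gpgrowth-model-v1")) {
    stop("unrecognized model format tag: ", obj$format, call. = FALSE)
  }
  vec <- function(x) as.numeric(unlist(x, use.names = FALSE))
  mat <- function(x) do.call(rbind, lapply(x, vec))  # rows as written
  grid <- vec(obj$grid)
  K <- obj$K
  tau <- mat(obj$memberships)
  rownames(tau) <- unlist(obj$member_ids)
  structure(list(
    K = K, grid = grid,
    mean_kernels = lapply(obj$mean_kernels, function(k) {
      kernel_params(k$variance, k$lengthscale)
    }),
    individual_kernel = kernel_params(obj$individual_kernel$variance,
                                      obj$individual_kernel$lengthscale),
    noise_var = obj$noise_var, prior_mean = obj$prior_mean,
    mixture_weights = vec(obj$mixture_weights),
    mean_hyperpost = lapply(seq_len(K), function(k) {
      gaussian_law(grid, vec(obj$hyperpost_mean[[k]]),
                   mat(obj$hyperpost_cov[[k]]))
    }),
    memberships = tau, elbo_trace = vec(obj$elbo_trace),
    empty = as.logical(unlist(obj$empty)),
    suffstats = list(S = lapply(obj$suff_S, mat),
                     b = lapply(obj$suff_b, vec)),
    n_children = obj$n_children), class = "gpm_model")
}
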