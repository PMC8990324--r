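#' Moment-based initial parameters for the EM algorithm
#'
#' `alpha` starts at the feature mean, `beta` at 1, `sigma_omega2` at the
#' feature variance, `sigma_eps2` at 0.005, and the (fixed) link offset
#' `gamma` at the logit of the empirical spike rate, clipped away from 0 and
#' 1 by `1/K`. The spike-rate anchor pins the unidentified offset between
#' `gamma` and the state level at `x = 0`.
#'
#' @param features A data frame with columns `n` and `z`, at least 10 bins.
#' @return A [valence_params()] object.
#' @export
init_valence_params <- function(features) {
  K <- nrow(features)
  if (K < 10) abort("need at least 10 bins to initialize the EM")
  vz <- max(var(features$z), 1e-6)
  pbar <- max(min(mean(features$n), 1 - 1 / K), 1 / K)
  valence_params(
    alpha = mean(features$z), beta = 1,
    sigma_eps2 = 0.005, sigma_omega2 = vz,
    gamma = qlogis(pbar), x0 = 0
  )
}

#' M-step of the EM algorithm
#'
#' Closed-form parameter updates from the smoothed moments: `x0` is set to
#' the smoothed first-bin state; `(alpha, beta)` solve the 2x2 normal
#' equations of the continuous channel; `sigma_omega2` follows from the
#' expected continuous residual; `sigma_eps2` averages the expected squared
#' state increments `W[k] - 2 W_cross[k] + W[k-1]`. The link offset `gamma`
#' is not re-estimated (it anchors the state level). Variances are floored
#' at `1e-8`.
#'
#' The `k = 1` increment needs moments of the initial state. When `prev`
#' (the previous iteration's parameters) is supplied, the boundary uses
#' `x0_prev` with variance `sigma_eps2_prev`; otherwise the initial state is
#' identified with the smoothed first bin and the boundary term vanishes.
#'
#' @param smoothed A tibble from [mixed_smoother()].
#' @param features The matching feature data frame (column `z` is used).
#' @param gamma Link offset carried through unchanged.
#' @param prev Optional [valence_params()] from the previous iteration.
#' @return A [valence_params()] object.
#' @export
em_mstep <- function(smoothed, features, gamma = 0, prev = NULL) {
  K <- nrow(smoothed)
  z <- features$z
  x <- smoothed$x_sm
  W <- smoothed$W
  Sx <- sum(x); SW <- sum(W); Sz <- sum(z); Sxz <- sum(x * z)
  M <- matrix(c(K, Sx, Sx, SW), 2, 2)
  if (abs(det(M)) < 1e-12 * max(1, K * SW)) {
    warn("near-singular normal equations (constant smoothed state); adding ridge")
    M <- M + diag(1e-8, 2)
  }
  ab <- solve(M, c(Sz, Sxz))
  alpha <- ab[1]; beta <- ab[2]
  sw2 <- (sum(z^2) + K * alpha^2 + beta^2 * SW - 2 * alpha * Sz -
            2 * beta * Sxz + 2 * alpha * beta * Sx) / K
  x0 <- x[1]
  incr <- W[-1] - 2 * smoothed$W_cross[-1] + W[-K]
  if (is.null(prev)) {
    boundary <- 0 # x0 := x_sm[1]; initial moments mirror bin 1 exactly
  } else {
    # W_0 = sigma_eps2_prev + x0_prev^2, cross moment from the lag-one recursion
    boundary <- prev$sigma_eps2 - smoothed$v_sm[1] + (x[1] - prev$x0)^2
  }
  se2 <- (sum(incr) + boundary) / K
  valence_params(
    alpha = alpha, beta = beta,
    sigma_eps2 = max(se2, 1e-8), sigma_omega2 = max(sw2, 1e-8),
    gamma = gamma, x0 = x0
  )
}

#' Fit the valence state-space model by expectation-maximization
#'
#' Alternates the E-step (mixed filter, fixed-interval smoother, covariance
#' moments) with the closed-form M-step until the largest relative parameter
#' change among `(alpha, beta, sigma_eps2, sigma_omega2)` falls below `tol`,
#' or `max_iters` is reached. The link offset `gamma` is fixed at its
#' initial (spike-rate) value throughout.
#'
#' @param features A data frame with columns `n` and `z` (at least 10 bins).
#' @param init Optional [valence_params()] starting point; defaults to
#'   [init_valence_params()].
#' @param tol Convergence tolerance on `max |dtheta| / (|theta| + 1e-12)`.
#' @param max_iters Maximum EM iterations.
#' The model has two exact invariances of the continuous channel and the
#' state prior: an affine remap of the state `x -> (x - d) / c` with
#' `(alpha, beta, sigma_eps2, x0) -> (alpha + beta d, c beta,
#' sigma_eps2 / c^2, (x0 - d) / c)`. Only the Bernoulli channel identifies
#' the state's level and scale, and plain EM moves along these ridge
#' directions extremely slowly. Each iteration therefore ends with a
#' closed-form re-anchoring (`scale_anchor`): a logistic regression of `n`
#' on the smoothed state gives the affine remap that maximizes the binary
#' likelihood along the ridge, leaving the rest of the fit untouched. The
#' anchor is skipped when the binary channel is disabled (the ridge is then
#' unidentified and the classical EM ascent applies verbatim).
#'
#' @param v0 Initial predicted variance for the filter (default: the current
#'   `sigma_eps2` at each iteration).
#' @param use_binary Set `FALSE` to fit the linear-Gaussian sub-model only.
#' @param scale_anchor Re-anchor the state scale on the binary channel each
#'   iteration (default `TRUE`; ignored when `use_binary = FALSE`).
#' @return An object of class `valence_em` with elements `params`,
#'   `trajectory` (tibble `k, n, z, x_filt, v_filt, x_sm, v_sm, ci_lo,
#'   ci_hi`), `n_iters`, `converged`, and `param_history` (one row per
#'   iteration).
#' @examples
#' sim <- simulate_session(valence_params(), n_trials = 4, seed = 1)
#' fit <- fit_valence_model(sim, max_iters = 25)
#' tidy(fit)
#' @export
fit_valence_model <- function(features, init = NULL, tol = 1e-6,
                              max_iters = 500, v0 = NULL, use_binary = TRUE,
                              scale_anchor = TRUE) {
  params <- if (is.null(init)) init_valence_params(features) else init
  gamma <- params$gamma
  hist <- vector("list", max_iters)
  converged <- FALSE
  post <- NULL
  sm <- NULL
  iter <- 0
  nn <- features$n
  anchor <- use_binary && scale_anchor && var(nn) > 0
  for (i in seq_len(max_iters)) {
    iter <- i
    post <- mixed_filter(features, params, v0 = v0, use_binary = use_binary)
    sm <- mixed_smoother(post)
    new <- em_mstep(sm, features, gamma = gamma, prev = params)
    if (anchor) {
      gf <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(1, sm$x_sm), nn,
                                        family = stats::binomial())),
        error = function(e) NULL
      )
      ab <- if (is.null(gf)) c(NA, NA) else gf$coefficients
      if (all(is.finite(ab)) && ab[2] > 0) {
        # n ~ Bern(plogis(a + b x_sm)) and the model wants plogis(gamma + x'),
        # so remap x' = (x - d) / c with c = 1/b, d = (gamma - a) * c
        c_star <- min(max(1 / ab[2], 0.2), 5)
        d_star <- (gamma - ab[1]) * c_star
        sdx <- sd(sm$x_sm) + 1e-6
        d_star <- min(max(d_star, -10 * sdx), 10 * sdx)
        b0 <- new$beta
        new$alpha <- new$alpha + b0 * d_star
        new$beta <- b0 * c_star
        new$sigma_eps2 <- max(new$sigma_eps2 / c_star^2, 1e-8)
        new$x0 <- (new$x0 - d_star) / c_star
      }
    }
    hist[[i]] <- tibble(
      iter = i, alpha = new$alpha, beta = new$beta,
      sigma_eps2 = new$sigma_eps2, sigma_omega2 = new$sigma_omega2,
      gamma = gamma, x0 = new$x0
    )
    delta <- max(
      abs(new$alpha - params$alpha) / (abs(params$alpha) + 1e-12),
      abs(new$beta - params$beta) / (abs(params$beta) + 1e-12),
      abs(new$sigma_eps2 - params$sigma_eps2) / (abs(params$sigma_eps2) + 1e-12),
      abs(new$sigma_omega2 - params$sigma_omega2) / (abs(params$sigma_omega2) + 1e-12)
    )
    params <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # E-step at the final parameters so the trajectory matches `params`
  post <- mixed_filter(features, params, v0 = v0, use_binary = use_binary)
  sm <- mixed_smoother(post)
  trajectory <- tibble(
    k = post$k, n = post$n, z = post$z,
    x_filt = post$x_filt, v_filt = post$v_filt,
    x_sm = sm$x_sm, v_sm = sm$v_sm,
    ci_lo = sm$x_sm - 1.96 * sqrt(sm$v_sm),
    ci_hi = sm$x_sm + 1.96 * sqrt(sm$v_sm)
  )
  structure(
    list(params = params, trajectory = trajectory, n_iters = iter,
         converged = converged,
         param_history = dplyr::bind_rows(hist[seq_len(iter)])),
    class = "valence_em"
  )
}

#' @export
print.valence_em <- function(x, ...) {
  cat(sprintf("<valence_em> %d bins, %d iteration(s), %s\n",
              nrow(x$trajectory), x$n_iters,
              if (x$converged) "converged" else "NOT converged"))
  print(x$params)
  invisible(x)
}

#' Tidy the parameter estimates of a fitted valence model
#'
#' @param x A `valence_em` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy valence_em
#' @export
tidy.valence_em <- function(x, ...) {
  p <- x$params
  tibble(
    term = c("alpha", "beta", "sigma_eps2", "sigma_omega2", "gamma", "x0"),
    estimate = c(p$alpha, p$beta, p$sigma_eps2, p$sigma_omega2, p$gamma, p$x0)
  )
}

#' One-row summary of a fitted valence model
#'
#' @param x A `valence_em` object.
#' @param ... Unused.
#' @return A tibble with `n_bins`, `n_iters`, `converged` and the
#'   Gaussian-channel log-likelihood at the final parameters.
#' @method glance valence_em
#' @export
glance.valence_em <- function(x, ...) {
  tibble(
    n_bins = nrow(x$trajectory),
    n_iters = x$n_iters,
    converged = x$converged,
    loglik_gauss = gaussian_loglik(x$trajectory, x$params)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
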