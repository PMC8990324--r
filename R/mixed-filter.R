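#' One predict + update step of the Kalman-based mixed filter
#'
#' The prediction follows the random-walk state (`x_pred = x_prev`,
#' `v_pred = v_prev + sigma_eps2`). The update fuses the continuous Gaussian
#' channel and the Bernoulli channel: with gain
#' `C = v_pred / (beta^2 v_pred + sigma_omega2)`, the filtered mean solves the
#' implicit equation
#' `x = x_pred + C * (beta * (z - alpha - beta * x_pred) +
#'  sigma_omega2 * (n - plogis(gamma + x)))`,
#' which is scalar and monotone, so its root is unique; it is found by
#' Newton--Raphson started at `x_pred` with a bisection fallback on the
#' bracketing interval. The filtered variance is
#' `1 / (1 / v_pred + p (1 - p) + beta^2 / sigma_omega2)` at the solution.
#'
#' @param prev Either `NULL` (start of the sequence: the prior
#'   `(x0, v0)` is used for the first prediction) or the list returned by a
#'   previous call, carrying `x_filt` and `v_filt`.
#' @param n Binary observation (0/1); ignored when `use_binary = FALSE`.
#' @param z Continuous observation; ignored when `use_continuous = FALSE`.
#' @param params A [valence_params()] object.
#' @param v0 Initial predicted variance used when `prev` is `NULL`
#'   (default `params$sigma_eps2`).
#' @param use_binary,use_continuous Enable/disable the two observation
#'   channels (both `TRUE` by default). With `use_binary = FALSE` the update
#'   is the exact linear-Gaussian Kalman update; with `use_continuous =
#'   FALSE` it is the pure point-process filter
#'   `x = x_pred + v_pred * (n - p(x))`.
#' @param tol,max_iter Newton tolerance and iteration cap.
#' @return A list with `x_pred`, `v_pred`, `x_filt`, `v_filt`, `gain`.
#' @export
mixed_filter_step <- function(prev, n, z, params, v0 = NULL,
                              use_binary = TRUE, use_continuous = TRUE,
                              tol = 1e-10, max_iter = 50) {
  if (is.null(prev)) {
    x_pred <- params$x0
    v_pred <- if (is.null(v0)) params$sigma_eps2 else v0
  } else {
    x_pred <- prev$x_filt
    v_pred <- prev$v_filt + params$sigma_eps2
  }
  out <- filter_core_safely(n, z, params, x_pred, v_pred,
                            use_binary, use_continuous, tol, max_iter)
  list(x_pred = x_pred, v_pred = v_pred,
       x_filt = out$x_filt[1], v_filt = out$v_filt[1], gain = out$gain[1])
}

filter_core_safely <- function(n, z, params, x0, v0, use_binary,
                               use_continuous, tol, max_iter) {
  tryCatch(
    mixed_filter_core(as.numeric(n), as.numeric(z), params$alpha, params$beta,
                      params$gamma, params$sigma_eps2, params$sigma_omega2,
                      x0, v0, use_binary, use_continuous, tol, max_iter),
    error = function(e) {
      abort(conditionMessage(e), class = "valenceloop_solver_error", parent = e)
    }
  )
}

#' Run the mixed filter over a feature sequence
#'
#' Applies [mixed_filter_step()] recursively from the prior `(x0, v0)`.
#' Results are identical to streaming the observations one bin at a time.
#'
#' @param features A data frame with columns `n` and `z` (e.g. from
#'   [extract_features()] or [simulate_valence()]).
#' @inheritParams mixed_filter_step
#' @return A tibble with columns
#'   `k, n, z, x_pred, v_pred, x_filt, v_filt, gain`.
#' @examples
#' sim <- simulate_valence(valence_params(), K = 50, seed = 1)
#' post <- mixed_filter(sim, valence_params())
#' @export
mixed_filter <- function(features, params, v0 = NULL,
                         use_binary = TRUE, use_continuous = TRUE,
                         tol = 1e-10, max_iter = 50) {
  nn <- features$n
  zz <- features$z
  K <- length(zz)
  if (K == 0) {
    return(tibble(k = integer(), n = integer(), z = numeric(),
                  x_pred = numeric(), v_pred = numeric(), x_filt = numeric(),
                  v_filt = numeric(), gain = numeric()))
  }
  v0 <- if (is.null(v0)) params$sigma_eps2 else v0
  out <- filter_core_safely(nn, zz, params, params$x0, v0,
                            use_binary, use_continuous, tol, max_iter)
  tibble(k = seq_len(K), n = nn, z = zz, x_pred = out$x_pred,
         v_pred = out$v_pred, x_filt = out$x_filt, v_filt = out$v_filt,
         gain = out$gain)
}

#' Fixed-interval smoother and state-space covariance moments
#'
#' Backward pass over a filtered posterior: with
#' `A[k] = v_filt[k] / v_pred[k+1]`, the smoothed mean and variance are
#' `x_sm[k] = x_filt[k] + A[k] (x_sm[k+1] - x_pred[k+1])` and
#' `v_sm[k] = v_filt[k] + A[k]^2 (v_sm[k+1] - v_pred[k+1])`, initialized at
#' the last filtered estimate. Also returns the lag-one smoothed
#' cross-covariance `cov_cross[k] = A[k-1] * v_sm[k]` and the second moments
#' `W[k] = v_sm[k] + x_sm[k]^2`,
#' `W_cross[k] = cov_cross[k] + x_sm[k-1] * x_sm[k]` consumed by the EM
#' M-step.
#'
#' @param posterior A tibble from [mixed_filter()].
#' @return A tibble with columns
#'   `k, x_sm, v_sm, A, cov_cross, W, W_cross` (`A[K]`, `cov_cross[1]` and
#'   `W_cross[1]` are `NA`).
#' @export
mixed_smoother <- function(posterior) {
  K <- nrow(posterior)
  if (K == 0) abort("cannot smooth an empty posterior")
  x_filt <- posterior$x_filt; v_filt <- posterior$v_filt
  x_pred <- posterior$x_pred; v_pred <- posterior$v_pred
  x_sm <- numeric(K); v_sm <- numeric(K); A <- rep(NA_real_, K)
  x_sm[K] <- x_filt[K]
  v_sm[K] <- v_filt[K]
  if (K > 1) {
    for (k in (K - 1):1) {
      A[k] <- v_filt[k] / v_pred[k + 1]
      x_sm[k] <- x_filt[k] + A[k] * (x_sm[k + 1] - x_pred[k + 1])
      v_sm[k] <- v_filt[k] + A[k]^2 * (v_sm[k + 1] - v_pred[k + 1])
    }
  }
  cov_cross <- c(NA_real_, A[seq_len(K - 1)] * v_sm[-1])
  W <- v_sm + x_sm^2
  W_cross <- c(NA_real_, cov_cross[-1] + x_sm[seq_len(K - 1)] * x_sm[-1])
  tibble(k = posterior$k, x_sm = x_sm, v_sm = v_sm, A = A,
         cov_cross = cov_cross, W = W, W_cross = W_cross)
}

#' Gaussian-channel log-likelihood of a feature sequence
#'
#' One-step prediction-error decomposition of the continuous channel with the
#' binary channel disabled:
#' `sum(dnorm(z, alpha + beta * x_pred, sqrt(beta^2 v_pred + sigma_omega2)))`.
#' Exact for the linear-Gaussian sub-model; used to verify the EM ascent
#' property in that sub-model.
#'
#' @inheritParams mixed_filter
#' @return A single log-likelihood value.
#' @export
gaussian_loglik <- function(features, params, v0 = NULL) {
  post <- mixed_filter(features, params, v0 = v0, use_binary = FALSE)
  mu <- params$alpha + params$beta * post$x_pred
  s2 <- params$beta^2 * post$v_pred + params$sigma_omega2
  sum(stats::dnorm(features$z, mu, sqrt(s2), log = TRUE))
}
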