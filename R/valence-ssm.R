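#' State-space parameters of the valence model
#'
#' Bundles the parameter set of the latent-valence state-space model: the
#' state is a first-order random walk `x[k+1] = x[k] + eps[k] + s[k] + u[k]`
#' with process noise `eps ~ N(0, sigma_eps2)`, observed through a continuous
#' channel `z[k] = alpha + beta * x[k] + omega[k]`,
#' `omega ~ N(0, sigma_omega2)`, and a binary channel
#' `n[k] ~ Bernoulli(plogis(gamma + x[k]))`.
#'
#' @param alpha Baseline of the continuous feature.
#' @param beta Gain of the continuous feature on the state.
#' @param sigma_eps2 Process-noise variance (> 0).
#' @param sigma_omega2 Continuous observation-noise variance (> 0).
#' @param gamma Offset of the binary sigmoidal link.
#' @param x0 Initial state.
#' @return An object of class `valence_params`.
#' @examples
#' valence_params(alpha = 0.3, beta = 0.5)
#' @export
valence_params <- function(alpha = 0.3, beta = 0.5, sigma_eps2 = 0.005,
                           sigma_omega2 = 0.01, gamma = -1, x0 = 0) {
  p <- list(alpha = alpha, beta = beta, sigma_eps2 = sigma_eps2,
            sigma_omega2 = sigma_omega2, gamma = gamma, x0 = x0)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                  logical(1)))) {
    abort("all valence parameters must be finite scalars")
  }
  if (sigma_eps2 <= 0 || sigma_omega2 <= 0) {
    abort("sigma_eps2 and sigma_omega2 must be positive")
  }
  structure(p, class = "valence_params")
}

#' @export
print.valence_params <- function(x, ...) {
  cat("<valence_params>\n")
  cat(sprintf("  alpha = %.6g, beta = %.6g, gamma = %.6g, x0 = %.6g\n",
              x$alpha, x$beta, x$gamma, x$x0))
  cat(sprintf("  sigma_eps2 = %.6g, sigma_omega2 = %.6g\n",
              x$sigma_eps2, x$sigma_omega2))
  invisible(x)
}

#' Spike probability of the binary observation channel
#'
#' `p = plogis(gamma + x)`: strictly in (0, 1) and monotone increasing in the
#' state.
#'
#' @param x State value(s).
#' @param gamma Link offset.
#' @return Spike probabilities, same length as `x`.
#' @export
spike_prob <- function(x, gamma) {
  plogis(gamma + x)
}

#' Advance the latent state one step
#'
#' `x[k+1] = x[k] + eps + s + u` with `eps ~ N(0, sigma_eps2)`.
#'
#' @param x Current state (vectorized).
#' @param params A [valence_params()] object.
#' @param s Environmental stimulus input (default 0).
#' @param u Control input (default 0).
#' @param seed Optional seed for the process-noise draw.
#' @return The next state value(s).
#' @export
step_state <- function(x, params, s = 0, u = 0, seed = NULL) {
  eps <- run_seeded(seed, function() rnorm(length(x), 0, sqrt(params$sigma_eps2)))
  x + eps + s + u
}

#' Draw the binary and continuous observations for a state value
#'
#' @inheritParams step_state
#' @return A tibble with columns `p` (spike probability), `n` (binary draw)
#'   and `z` (continuous draw).
#' @export
emit_observations <- function(x, params, seed = NULL) {
  run_seeded(seed, function() {
    p <- spike_prob(x, params$gamma)
    n <- as.integer(runif(length(x)) < p)
    z <- params$alpha + params$beta * x + rnorm(length(x), 0, sqrt(params$sigma_omega2))
    tibble(p = p, n = n, z = z)
  })
}

#' Simulate a latent valence trajectory with its observations
#'
#' Simulates `K` steps of the state equation driven by optional stimulus and
#' control sequences, emitting both observation channels at every bin. One
#' state step corresponds to one 0.5 s feature bin.
#'
#' @param params A [valence_params()] object.
#' @param K Number of bins to simulate.
#' @param s Stimulus sequence (scalar or length `K`); `s[k]` acts on the
#'   transition from bin `k` to `k + 1`.
#' @param u Control sequence (scalar or length `K`), same convention.
#' @param seed Optional integer seed.
#' @return A tibble with columns `k, x, s, u, p, n, z`.
#' @examples
#' sim <- simulate_valence(valence_params(), K = 100, seed = 1)
#' @export
simulate_valence <- function(params, K, s = 0, u = 0, seed = NULL) {
  stopifnot(K >= 1)
  s <- rep_len(s, K)
  u <- rep_len(u, K)
  run_seeded(seed, function() {
    eps <- rnorm(K, 0, sqrt(params$sigma_eps2))
    ub <- runif(K)
    omega <- rnorm(K, 0, sqrt(params$sigma_omega2))
    x <- numeric(K)
    x[1] <- params$x0
    for (k in seq_len(K - 1)) {
      x[k + 1] <- x[k] + eps[k] + s[k] + u[k]
    }
    p <- spike_prob(x, params$gamma)
    tibble(
      k = seq_len(K), x = x, s = s, u = u, p = p,
      n = as.integer(ub < p),
      z = params$alpha + params$beta * x + omega
    )
  })
}
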