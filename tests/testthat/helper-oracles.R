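# Independent oracles used across the suite. Each is written from the
# defining formulas, separately from the package implementation it checks.

# Textbook scalar linear-Gaussian Kalman filter + RTS smoother for
# z = alpha + beta * x + noise on a random-walk state.
kalman_rts_ref <- function(z, alpha, beta, se2, sw2, x0, v0) {
  K <- length(z)
  xp <- vp <- xf <- vf <- numeric(K)
  for (k in seq_len(K)) {
    if (k == 1) {
      xp[k] <- x0
      vp[k] <- v0
    } else {
      xp[k] <- xf[k - 1]
      vp[k] <- vf[k - 1] + se2
    }
    Kg <- vp[k] * beta / (beta^2 * vp[k] + sw2)
    xf[k] <- xp[k] + Kg * (z[k] - alpha - beta * xp[k])
    vf[k] <- (1 - Kg * beta) * vp[k]
  }
  xs <- vs <- numeric(K)
  xs[K] <- xf[K]
  vs[K] <- vf[K]
  if (K > 1) {
    for (k in (K - 1):1) {
      A <- vf[k] / vp[k + 1]
      xs[k] <- xf[k] + A * (xs[k + 1] - xp[k + 1])
      vs[k] <- vf[k] + A^2 * (vs[k + 1] - vp[k + 1])
    }
  }
  list(x_pred = xp, v_pred = vp, x_filt = xf, v_filt = vf,
       x_sm = xs, v_sm = vs)
}

# Grid-search maximizer of the exact one-step posterior density
# N(x; x_pred, v_pred) * p^n (1-p)^(1-n) * N(z; alpha + beta x, sw2).
grid_posterior_mode <- function(x_pred, v_pred, n, z, alpha, beta, gamma, sw2,
                                n_grid = 400001) {
  half <- 6 * sqrt(v_pred) + 2
  g <- seq(x_pred - half, x_pred + half, length.out = n_grid)
  p <- plogis(gamma + g)
  lp <- -(g - x_pred)^2 / (2 * v_pred) + n * log(p) + (1 - n) * log1p(-p) -
    (z - alpha - beta * g)^2 / (2 * sw2)
  g[which.max(lp)]
}

# Piecewise-linear membership evaluation via interpolation knots, independent
# of the package's segment arithmetic.
mf_oracle <- function(mf, v) {
  bp <- mf$bp
  knots_x <- c(bp[1] - 1e6, bp[1], bp[2], bp[3], bp[4], bp[4] + 1e6)
  knots_y <- c(0, 0, 1, 1, 0, 0)
  # collapse duplicated knots (saturating edges), keeping the plateau value
  ux <- sort(unique(knots_x))
  uy <- vapply(ux, function(x0) max(knots_y[knots_x == x0]), numeric(1))
  stats::approx(ux, uy, xout = v, rule = 2)$y
}

# Midpoint-rule centroid of an aggregate membership function given as a
# callable, over [-u_max, u_max].
riemann_centroid <- function(f, u_max, n_points = 1e6) {
  h <- 2 * u_max / n_points
  u <- -u_max + (seq_len(n_points) - 0.5) * h
  mu <- f(u)
  den <- sum(mu) * h
  if (den <= 0) return(0)
  sum(mu * u) * h / den
}

# Aggregated Mamdani membership of a controller at smoothed input v,
# computed directly from the rule definitions (max of clipped output MFs).
mamdani_oracle_fn <- function(controller, degrees) {
  function(u) {
    mu <- numeric(length(u))
    for (lab in names(controller$rules)) {
      g <- degrees[[lab]]
      if (is.null(g) || g <= 0) next
      out_mf <- controller$output_mfs[[controller$rules[[lab]]]]
      mu <- pmax(mu, pmin(g, mf_oracle(out_mf, u)))
    }
    mu
  }
}

# A calibrated controller with simple symmetric input MFs for unit tests.
test_controller <- function(mode = "inhibitory", u_max = 0.1, ...) {
  ctrl <- fuzzy_controller(mode, u_max = u_max, ...)
  ctrl$input_mfs <- list(
    LowValence = membership_fn("trapezoid", c(-3, -2, -0.5, 0.5),
                               label = "LowValence"),
    HighValence = membership_fn("trapezoid", c(-0.5, 0.5, 2, 3),
                                label = "HighValence")
  )
  ctrl$universe_in <- c(-2, 2)
  ctrl
}

# Small synthetic recording shared by front-end tests (kept short for speed).
short_recording <- function(seed = 7, trials = 4, duration_s = 10) {
  generate_recording(synthetic_spec(
    trial_plan = tibble::tibble(
      label = rep(c("LV", "HV"), length.out = trials),
      duration_s = duration_s
    ),
    seed = seed
  ))
}
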