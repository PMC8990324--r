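#' Piecewise-linear membership function
#'
#' @param shape `"trapezoid"` (4 breakpoints `a <= b <= c <= d`: 0 below
#'   `a`, rising to 1 at `b`, plateau to `c`, falling to 0 at `d`) or
#'   `"triangle"` (3 breakpoints, a zero-width plateau).
#' @param breakpoints Non-decreasing numeric vector of length 4 or 3.
#' @param label Optional name.
#' @return An object of class `membership_fn`.
#' @export
membership_fn <- function(shape = c("trapezoid", "triangle"), breakpoints,
                          label = NULL) {
  shape <- match.arg(shape)
  need <- if (shape == "triangle") 3L else 4L
  if (length(breakpoints) != need) {
    abort(sprintf("%s needs %d breakpoints", shape, need))
  }
  if (is.unsorted(breakpoints)) abort("breakpoints must be non-decreasing")
  bp <- if (shape == "triangle") {
    c(breakpoints[1], breakpoints[2], breakpoints[2], breakpoints[3])
  } else {
    breakpoints
  }
  structure(list(shape = shape, bp = bp, label = label), class = "membership_fn")
}

#' Evaluate a membership function
#'
#' @param mf A [membership_fn()].
#' @param v Numeric values.
#' @return Membership degrees in \[0, 1\].
#' @export
mf_eval <- function(mf, v) {
  bp <- mf$bp
  out <- numeric(length(v))
  out[v >= bp[2] & v <= bp[3]] <- 1
  if (bp[2] > bp[1]) {
    i <- v > bp[1] & v < bp[2]
    out[i] <- (v[i] - bp[1]) / (bp[2] - bp[1])
  }
  if (bp[4] > bp[3]) {
    i <- v > bp[3] & v < bp[4]
    out[i] <- (bp[4] - v[i]) / (bp[4] - bp[3])
  }
  out
}

#' Construct a Mamdani fuzzy valence controller
#'
#' The controller maps a (10-s moving-average smoothed) state estimate to a
#' control effort `u` in `[-u_max, u_max]`. Input membership functions
#' (`LowValence`, `HighValence`) are subject-specific and are normally set
#' from an open-loop run via [calibrate_controller()]. Output membership
#' functions are `Inhibition` (trapezoid saturating at `-u_max`), `Neutral`
#' (triangle centred at 0) and `Excitation` (mirror of Inhibition). The rule
#' base depends on the mode: inhibitory -- LowValence => Neutral,
#' HighValence => Inhibition; excitatory -- LowValence => Excitation,
#' HighValence => Neutral. During the warm-up period the controller is
#' suspended and outputs 0.
#'
#' @param mode `"inhibitory"` or `"excitatory"`.
#' @param u_max Control-authority bound in state units per bin (default 0.1).
#' @param smoothing_window_s Moving-average window applied to the filtered
#'   state before fuzzification (default 10 s).
#' @param warmup_s Initial period with the controller suspended (default 60 s).
#' @param bin_len_s Bin length in seconds (default 0.5).
#' @param n_grid Number of points discretizing the output universe
#'   (default 2001).
#' @param input_mfs Optional named list with `LowValence` and `HighValence`
#'   [membership_fn()]s (usually set by calibration).
#' @param universe_in Optional length-2 input universe; inputs are clamped to
#'   it before fuzzification.
#' @return An object of class `fuzzy_controller`.
#' @export
fuzzy_controller <- function(mode = c("inhibitory", "excitatory"), u_max = 0.1,
                             smoothing_window_s = 10, warmup_s = 60,
                             bin_len_s = 0.5, n_grid = 2001,
                             input_mfs = NULL, universe_in = NULL) {
  mode <- match.arg(mode)
  if (u_max <= 0) abort("u_max must be positive")
  output_mfs <- list(
    Inhibition = membership_fn("trapezoid",
                               c(-u_max, -u_max, -0.6 * u_max, -0.2 * u_max),
                               label = "Inhibition"),
    Neutral = membership_fn("triangle", c(-0.2 * u_max, 0, 0.2 * u_max),
                            label = "Neutral"),
    Excitation = membership_fn("trapezoid",
                               c(0.2 * u_max, 0.6 * u_max, u_max, u_max),
                               label = "Excitation")
  )
  rules <- if (mode == "inhibitory") {
    list(LowValence = "Neutral", HighValence = "Inhibition")
  } else {
    list(LowValence = "Excitation", HighValence = "Neutral")
  }
  structure(
    list(mode = mode, u_max = u_max,
         smoothing_window_s = smoothing_window_s, warmup_s = warmup_s,
         bin_len_s = bin_len_s,
         u_grid = u_max * seq(-1, 1, length.out = n_grid),
         input_mfs = input_mfs, output_mfs = output_mfs, rules = rules,
         universe_in = universe_in),
    class = "fuzzy_controller"
  )
}

#' @export
print.fuzzy_controller <- function(x, ...) {
  cat(sprintf("<fuzzy_controller> mode=%s, u_max=%g, window=%gs, warmup=%gs, %s\n",
              x$mode, x$u_max, x$smoothing_window_s, x$warmup_s,
              if (is.null(x$input_mfs)) "uncalibrated" else "calibrated"))
  invisible(x)
}

#' Calibrate the input membership functions from an open-loop run
#'
#' Because the controller regulates the estimated valence directly (no
#' reference subtraction), its input membership functions are anchored on
#' the subject's own open-loop response: the input universe spans the 1st to
#' 99th percentile of the open-loop filtered state, and the LowValence /
#' HighValence functions cross at the midpoint between the LV-period and
#' HV-period medians. The rise/fall of each function is confined to the
#' central half between the two medians, leaving a dead band around each
#' class level so the controller is exactly silent when the state sits at
#' its own class median (this prevents control chatter inside the target
#' class).
#'
#' @param controller A [fuzzy_controller()].
#' @param open_loop_state Either a `scenario_result` from [run_scenario()]
#'   (its post-warm-up trajectory is used) or a data frame with columns
#'   `x_filt` and `label` (`"LV"`/`"HV"`).
#' @param deadband Fraction of the inter-median distance kept flat on each
#'   side (default 0.25).
#' @return The controller with `input_mfs` and `universe_in` set.
#' @export
calibrate_controller <- function(controller, open_loop_state, deadband = 0.25) {
  d <- if (inherits(open_loop_state, "scenario_result")) {
    tr <- open_loop_state$trajectory
    tr[tr$t_s >= open_loop_state$warmup_s, c("x_filt", "label")]
  } else {
    open_loop_state
  }
  stopifnot(all(c("x_filt", "label") %in% names(d)))
  m_lv <- median(d$x_filt[d$label == "LV"])
  m_hv <- median(d$x_filt[d$label == "HV"])
  if (!is.finite(m_lv) || !is.finite(m_hv) || m_lv >= m_hv) {
    abort(paste("degenerate calibration: LV-period median is not below the",
                "HV-period median; this subject shows no usable LV/HV",
                "contrast and should be excluded"),
          class = "valenceloop_calibration_error")
  }
  lo <- min(quantile(d$x_filt, 0.01), m_lv)
  hi <- max(quantile(d$x_filt, 0.99), m_hv)
  D <- m_hv - m_lv
  fall_lo <- m_lv + deadband * D
  fall_hi <- m_hv - deadband * D
  controller$input_mfs <- list(
    LowValence = membership_fn("trapezoid", c(lo - 1, lo, fall_lo, fall_hi),
                               label = "LowValence"),
    HighValence = membership_fn("trapezoid", c(fall_lo, fall_hi, hi, hi + 1),
                                label = "HighValence")
  )
  controller$universe_in <- c(lo, hi)
  controller
}

#' Smooth the filtered-state history for the controller input
#'
#' Mean of the most recent `window` bins (all available bins when the
#' history is shorter than the window).
#'
#' @param history Numeric vector of filtered state estimates (oldest first).
#' @param window_bins Window length in bins.
#' @return A single smoothed value.
#' @export
smooth_input <- function(history, window_bins = 20) {
  if (length(history) == 0) abort("empty state history")
  mean(tail(history, window_bins))
}

#' Fuzzify a crisp input value
#'
#' @param v Crisp input (clamped to the controller universe when set).
#' @param controller A calibrated [fuzzy_controller()].
#' @return Named numeric vector of membership degrees.
#' @export
fuzzify <- function(v, controller) {
  if (is.null(controller$input_mfs)) {
    abort("controller is not calibrated; run calibrate_controller() first",
          class = "valenceloop_calibration_error")
  }
  if (!is.null(controller$universe_in)) {
    v <- min(max(v, controller$universe_in[1]), controller$universe_in[2])
  }
  vapply(controller$input_mfs, mf_eval, numeric(1), v = v)
}

#' Mamdani inference: clipped, max-aggregated output membership
#'
#' Each rule's output membership function is clipped (min) at the rule's
#' input degree; the aggregate is the pointwise max over rules, evaluated on
#' the discretized output universe.
#'
#' The returned grid is the controller's uniform output grid augmented with
#' the exact breakpoints and clip-crossing points of the active rules, so
#' that the subsequent trapezoidal centroid is exact for the piecewise-linear
#' aggregate (the output membership functions have non-overlapping supports).
#'
#' @param degrees Named degrees from [fuzzify()].
#' @param controller A [fuzzy_controller()].
#' @return A tibble with columns `u` (grid) and `mu` (aggregated membership).
#' @export
fuzzy_infer <- function(degrees, controller) {
  grid <- controller$u_grid
  u_max <- controller$u_max
  kinks <- numeric(0)
  for (input_label in names(controller$rules)) {
    g <- degrees[[input_label]]
    if (is.null(g) || g <= 0) next
    bp <- controller$output_mfs[[controller$rules[[input_label]]]]$bp
    kk <- bp
    if (g < 1) {
      # where the rising/falling edges cross the clip height
      if (bp[2] > bp[1]) kk <- c(kk, bp[1] + g * (bp[2] - bp[1]))
      if (bp[4] > bp[3]) kk <- c(kk, bp[4] - g * (bp[4] - bp[3]))
    }
    kinks <- c(kinks, kk)
  }
  kinks <- kinks[kinks > -u_max & kinks < u_max]
  if (length(kinks)) grid <- sort(unique(c(grid, kinks)))
  mu <- numeric(length(grid))
  for (input_label in names(controller$rules)) {
    g <- degrees[[input_label]]
    if (is.null(g) || g <= 0) next
    out_mf <- controller$output_mfs[[controller$rules[[input_label]]]]
    mu <- pmax(mu, pmin(g, mf_eval(out_mf, grid)))
  }
  tibble(u = grid, mu = mu)
}

#' Centroid defuzzification
#'
#' `u = integral(mu * u) / integral(mu)` by trapezoidal quadrature on the
#' output grid; a zero-area aggregate (no active rule) defuzzifies to 0.
#'
#' @param aggregate A tibble with columns `u` and `mu` (from
#'   [fuzzy_infer()]).
#' @return The crisp control value.
#' @export
defuzzify_centroid <- function(aggregate) {
  den <- pracma::trapz(aggregate$u, aggregate$mu)
  if (den <= 0) return(0)
  pracma::trapz(aggregate$u, aggregate$mu * aggregate$u) / den
}

#' One control step
#'
#' Returns 0 during the warm-up period; otherwise smooths the filtered-state
#' history, fuzzifies, runs Mamdani inference and defuzzifies. The output is
#' clamped to the mode's sign (inhibitory <= 0, excitatory >= 0) and to
#' `[-u_max, u_max]`; magnitudes below `1e-9 * u_max` are snapped to exactly
#' zero (the symmetric Neutral centroid is an analytic zero).
#'
#' @param controller A calibrated [fuzzy_controller()].
#' @param x_filt_history Filtered state estimates up to the current bin.
#' @param t_s Elapsed session time in seconds.
#' @return The control effort `u`.
#' @export
control_step <- function(controller, x_filt_history, t_s) {
  if (t_s < controller$warmup_s) return(0)
  wb <- max(1L, as.integer(round(controller$smoothing_window_s / controller$bin_len_s)))
  v <- smooth_input(x_filt_history, wb)
  u <- defuzzify_centroid(fuzzy_infer(fuzzify(v, controller), controller))
  if (controller$mode == "inhibitory") u <- min(u, 0) else u <- max(u, 0)
  u <- max(min(u, controller$u_max), -controller$u_max)
  if (abs(u) < 1e-9 * controller$u_max) u <- 0
  u
}

#' Plot the membership functions of a fuzzy controller
#'
#' @param controller A [fuzzy_controller()].
#' @return A ggplot object (input functions when calibrated, plus output
#'   functions).
#' @export
plot_memberships <- function(controller) {
  mk <- function(mfs, universe) {
    purrr::map_dfr(mfs, function(mf) {
      v <- sort(unique(c(seq(universe[1], universe[2], length.out = 201), mf$bp)))
      tibble(v = v, degree = mf_eval(mf, v), label = mf$label)
    })
  }
  out_d <- mk(controller$output_mfs, c(-controller$u_max, controller$u_max))
  out_d$panel <- "output (u)"
  d <- out_d
  if (!is.null(controller$input_mfs)) {
    in_d <- mk(controller$input_mfs, controller$universe_in)
    in_d$panel <- "input (valence)"
    d <- dplyr::bind_rows(in_d, out_d)
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$v, .data$degree, colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "degree of membership", colour = NULL) +
    ggplot2::theme_minimal()
}
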