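#' Build a bank of virtual subjects
#'
#' Each subject is a [valence_params()] set (jittered around a common
#' template) plus a subject-specific [stimulus_model()]. The stimulus models
#' are built by fitting the 100-harmonic model to the first difference of a
#' smooth reference valence path for each class: a rise to the class level
#' (+`delta` for HV, -`delta` for LV) over `transition_len_s`, a hold with
#' small subject-specific oscillation for half the reference, and a smooth
#' return to baseline in the second half. Fitting on a reference twice as
#' long as the session segment lets the DC-free harmonic reconstruction hold
#' its level over a replayed half-session.
#'
#' Virtual subjects use a modest process noise (`sigma_eps2 = 1e-4` by
#' default) relative to the stimulus-driven swings, emulating emotionally
#' responsive subjects with a clear LV/HV contrast (subjects without such
#' contrast are excluded from controller evaluation, as flagged by
#' [calibrate_controller()]).
#'
#' @param n_subjects Number of subjects (default 10).
#' @param seed Integer seed for the subject-level jitter.
#' @param delta Class level of the reference valence path (default 1).
#' @param segment_bins Bins per session half the model will be replayed over
#'   (default 600, i.e. 5 min at 0.5 s bins).
#' @param transition_len_s Rise time of the reference path (default 20 s).
#' @param base_params Template [valence_params()]; per-subject values jitter
#'   `alpha`, `beta` and the variances by `jitter` (uniform, relative).
#' @param jitter Relative jitter amplitude (default 0.1).
#' @param n_components Harmonics per class (default 100).
#' @return A list of subjects, each a list with `id`, `params` and `stim`.
#' @export
make_subject_bank <- function(n_subjects = 10, seed = 1, delta = 1,
                              segment_bins = 600, transition_len_s = 20,
                              base_params = valence_params(
                                alpha = 0.3, beta = 0.5, sigma_eps2 = 1e-4,
                                sigma_omega2 = 0.01, gamma = -1, x0 = 0
                              ),
                              jitter = 0.1, n_components = 100) {
  bin_len_s <- 0.5
  run_seeded(seed, function() {
    lapply(seq_len(n_subjects), function(i) {
      jit <- function(v) v * (1 + runif(1, -jitter, jitter))
      params <- valence_params(
        alpha = jit(base_params$alpha), beta = jit(base_params$beta),
        sigma_eps2 = jit(base_params$sigma_eps2),
        sigma_omega2 = jit(base_params$sigma_omega2),
        gamma = base_params$gamma, x0 = base_params$x0
      )
      stim <- stimulus_model(
        hv = fit_harmonics(reference_stimulus(delta, segment_bins,
                                              transition_len_s, bin_len_s),
                           n_components),
        lv = fit_harmonics(reference_stimulus(-delta, segment_bins,
                                              transition_len_s, bin_len_s),
                           n_components),
        bin_len_s = bin_len_s
      )
      list(id = i, params = params, stim = stim)
    })
  })
}

# Reference class path: smoothstep rise to `level` over the transition, hold
# (with a small random low-frequency oscillation) until `segment_bins`, then
# smoothstep return to 0 over the second half of a 2*segment_bins reference.
# Returns its first difference, length 2*segment_bins.
reference_stimulus <- function(level, segment_bins, transition_len_s, bin_len_s) {
  L <- 2 * segment_bins
  tb <- max(2L, as.integer(round(transition_len_s / bin_len_s)))
  t <- seq_len(L + 1) - 1
  smoothstep <- function(x) {
    x <- pmin(pmax(x, 0), 1)
    x^2 * (3 - 2 * x)
  }
  up <- smoothstep(t / tb)
  down <- smoothstep((t - segment_bins) / tb)
  path <- level * (up - down)
  n_osc <- 3
  fr <- sample(3:12, n_osc)
  amp <- runif(n_osc, 0.02, 0.06) * abs(level)
  ph <- runif(n_osc, 0, 2 * pi)
  osc <- rowSums(sapply(seq_len(n_osc), function(j) {
    amp[j] * sin(2 * pi * fr[j] * t / L + ph[j])
  }))
  # confine the oscillation to the hold period
  path <- path + osc * (up - down)
  diff(path)
}

#' Run one open- or closed-loop scenario for a virtual subject
#'
#' Simulates a session of `duration_s` split into two equal halves (LV then
#' HV or vice versa). Per bin: the stimulus is synthesized from the
#' subject's harmonic model, observations are emitted from the current true
#' state, the mixed filter updates online, the controller (if any) computes
#' the control effort from the filtered-state history (zero in open-loop
#' mode and during the first `warmup_s` of every run), and the state steps
#' forward. All noise is drawn up front from `seed`, so open- and
#' closed-loop runs with the same seed share identical draws and differ only
#' through the control input.
#'
#' @param subject A subject from [make_subject_bank()] (a list with `params`
#'   and `stim`).
#' @param mode `"open"`, `"inhibitory"` or `"excitatory"`.
#' @param order `"lvhv"` (LV first) or `"hvlv"`.
#' @param seed Integer seed for the noise draws.
#' @param duration_s Session length in seconds (default 600).
#' @param controller A calibrated [fuzzy_controller()]; required for closed
#'   modes (calibrate it on this subject's open-loop run with the same seed
#'   and order).
#' @param warmup_s Controller suspension period (default 60 s); also the
#'   span excluded from the per-period summaries.
#' @return An object of class `scenario_result`: list with `trajectory`
#'   (tibble `k, t_s, label, s, u, x_true, n, z, x_filt, v_filt`), `mode`,
#'   `order`, `seed`, `warmup_s` and `summaries` (from
#'   [summarize_halves()]).
#' @export
run_scenario <- function(subject, mode = c("open", "inhibitory", "excitatory"),
                         order = c("lvhv", "hvlv"), seed = 1,
                         duration_s = 600, controller = NULL, warmup_s = 60) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  params <- subject$params
  stim <- subject$stim
  bin <- stim$bin_len_s
  if (mode != "open") {
    if (is.null(controller) || is.null(controller$input_mfs)) {
      abort(paste("closed-loop modes need a controller calibrated on this",
                  "subject's open-loop run; run mode='open' first and call",
                  "calibrate_controller()"),
            class = "valenceloop_calibration_error")
    }
    if (controller$mode != mode) {
      abort(sprintf("controller mode '%s' does not match scenario mode '%s'",
                    controller$mode, mode))
    }
  }
  labels <- if (order == "lvhv") c("LV", "HV") else c("HV", "LV")
  sched <- tibble(label = labels, duration_s = duration_s / 2)
  stim_seq <- synthesize_schedule(stim, sched)
  K <- nrow(stim_seq)
  draws <- run_seeded(seed, function() {
    list(eps = rnorm(K, 0, sqrt(params$sigma_eps2)),
         omega = rnorm(K, 0, sqrt(params$sigma_omega2)),
         ub = runif(K))
  })
  x_true <- numeric(K); nn <- integer(K); zz <- numeric(K)
  x_filt <- numeric(K); v_filt <- numeric(K); uu <- numeric(K)
  x <- params$x0
  fstate <- NULL
  for (k in seq_len(K)) {
    x_true[k] <- x
    p <- spike_prob(x, params$gamma)
    nn[k] <- as.integer(draws$ub[k] < p)
    zz[k] <- params$alpha + params$beta * x + draws$omega[k]
    fstate <- mixed_filter_step(fstate, nn[k], zz[k], params)
    x_filt[k] <- fstate$x_filt
    v_filt[k] <- fstate$v_filt
    t_s <- (k - 1) * bin
    uu[k] <- if (mode == "open") 0 else {
      control_step(controller, x_filt[seq_len(k)], t_s)
    }
    x <- x + draws$eps[k] + stim_seq$s[k] + uu[k]
  }
  trajectory <- tibble(
    k = seq_len(K), t_s = (seq_len(K) - 1) * bin, label = stim_seq$label,
    s = stim_seq$s, u = uu, x_true = x_true, n = nn, z = zz,
    x_filt = x_filt, v_filt = v_filt
  )
  res <- structure(
    list(trajectory = trajectory, mode = mode, order = order, seed = seed,
         warmup_s = warmup_s, bin_len_s = bin),
    class = "scenario_result"
  )
  res$summaries <- summarize_halves(res)
  res
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> mode=%s order=%s seed=%d, %d bins\n",
              x$mode, x$order, x$seed, nrow(x$trajectory)))
  print(x$summaries)
  invisible(x)
}

#' Per-period spike counts and mean estimated valence
#'
#' Summarizes each labeled period of a scenario, excluding warm-up bins:
#' `spike_count` is the number of binary spikes and `mean_valence` the mean
#' of the *estimated* (filtered) state over the period.
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @return A tibble with columns `period`, `spike_count`, `mean_valence`.
#' @export
summarize_halves <- function(result) {
  tr <- result$trajectory
  tr <- tr[tr$t_s >= result$warmup_s, , drop = FALSE]
  tr |>
    group_by(period = .data$label) |>
    summarise(spike_count = sum(.data$n),
              mean_valence = mean(.data$x_filt), .groups = "drop")
}

#' Run all scenarios for a subject bank
#'
#' For every subject and stimulus order: runs the open-loop scenario,
#' calibrates one controller per closed mode on that open-loop run, then
#' runs the closed-loop scenarios with the same seed (common random
#' numbers).
#'
#' @param subjects A list from [make_subject_bank()].
#' @param orders Stimulus orders to run (default both).
#' @param modes Closed-loop modes to run (default both).
#' @param duration_s Session length in seconds (default 600).
#' @param seed Base seed; subject `i` uses `seed + i`.
#' @param u_max,warmup_s Controller settings (see [fuzzy_controller()]).
#' @param keep_trajectories Keep full trajectories in the result (default
#'   `FALSE`: summaries only, lighter).
#' @return A tibble with one row per (subject, order, mode, period):
#'   `subject, order, mode, period, spike_count, mean_valence`, plus a
#'   `result` list-column when `keep_trajectories = TRUE`.
#' @export
run_bank <- function(subjects, orders = c("lvhv", "hvlv"),
                     modes = c("inhibitory", "excitatory"),
                     duration_s = 600, seed = 100, u_max = 0.1,
                     warmup_s = 60, keep_trajectories = FALSE) {
  rows <- list()
  for (subj in subjects) {
    sseed <- seed + subj$id
    for (ord in orders) {
      open <- run_scenario(subj, "open", ord, seed = sseed,
                           duration_s = duration_s, warmup_s = warmup_s)
      runs <- list(open = open)
      for (m in modes) {
        ctrl <- calibrate_controller(
          fuzzy_controller(m, u_max = u_max, warmup_s = warmup_s,
                           bin_len_s = subj$stim$bin_len_s),
          open
        )
        runs[[m]] <- run_scenario(subj, m, ord, seed = sseed,
                                  duration_s = duration_s, controller = ctrl,
                                  warmup_s = warmup_s)
      }
      for (m in names(runs)) {
        sm <- runs[[m]]$summaries
        sm$subject <- subj$id
        sm$order <- ord
        sm$mode <- m
        if (keep_trajectories) sm$result <- rep(list(runs[[m]]), nrow(sm))
        rows[[length(rows) + 1]] <- sm
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out[, c("subject", "order", "mode", "period", "spike_count", "mean_valence",
          intersect("result", names(out)))]
}

#' Paired open- vs closed-loop evaluation across a subject bank
#'
#' For each (closed mode, order, period, metric) cell, performs a paired
#' two-tailed t-test of the per-subject closed-loop values against the
#' same-seed open-loop values, reporting the mean difference
#' (closed - open) and the p-value. When the paired differences have zero
#' variance the p-value is reported as exactly 1 if all differences are 0
#' and 0 otherwise (with a warning).
#'
#' @param bank A tibble from [run_bank()].
#' @return A tibble with columns `mode, order, period, metric, mean_diff,
#'   p_value, n_subjects`.
#' @export
evaluate_bank <- function(bank) {
  closed_modes <- setdiff(unique(bank$mode), "open")
  grid <- expand.grid(
    mode = closed_modes, order = unique(bank$order),
    period = unique(bank$period),
    metric = c("spike_count", "mean_valence"),
    stringsAsFactors = FALSE
  )
  purrr::pmap_dfr(grid, function(mode, order, period, metric) {
    md <- mode; od <- order; pd <- period
    sel <- bank$order == od & bank$period == pd
    op <- bank[sel & bank$mode == "open", ]
    cl <- bank[sel & bank$mode == md, ]
    op <- op[base::order(op$subject), ]
    cl <- cl[base::order(cl$subject), ]
    d <- cl[[metric]] - op[[metric]]
    if (length(d) < 3) abort("need at least 3 paired subjects per cell")
    p <- paired_t_p(d)
    tibble(mode = md, order = od, period = pd, metric = metric,
           mean_diff = mean(d), p_value = p, n_subjects = length(d))
  })
}

paired_t_p <- function(d) {
  if (sd(d) == 0) {
    warn("zero-variance paired differences; degenerate p-value convention used")
    return(if (all(d == 0)) 1 else 0)
  }
  t.test(d)$p.value
}

#' Plot a scenario trajectory
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot with stimulus, control effort, spikes and the true vs
#'   estimated state stacked in facets.
#' @method autoplot scenario_result
#' @export
autoplot.scenario_result <- function(object, ...) {
  tr <- object$trajectory
  d <- dplyr::bind_rows(
    tibble(t_s = tr$t_s, value = tr$s, panel = "stimulus s"),
    tibble(t_s = tr$t_s, value = tr$u, panel = "control u"),
    tibble(t_s = tr$t_s, value = as.numeric(tr$n), panel = "spikes n"),
    tibble(t_s = tr$t_s, value = tr$x_true, panel = "state (true)"),
    tibble(t_s = tr$t_s, value = tr$x_filt, panel = "state (estimated)")
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$t_s, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("%s / %s", object$mode, object$order)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
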