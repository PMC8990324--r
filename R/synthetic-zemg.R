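#' Specification for a synthetic zEMG recording
#'
#' Describes a ground-truth-known surrogate of a facial-EMG session: a bank
#' of one-minute HV/LV trials whose latent valence level modulates the
#' envelope of band-limited (20--240 Hz) EMG-like noise, contaminated with
#' 50 Hz line interference and weak harmonics.
#'
#' @param fs Sampling rate in Hz (> 500; default 512).
#' @param trial_plan A data frame with columns `label` (`"HV"`/`"LV"`) and
#'   `duration_s`. Default: 40 alternating one-minute trials (20 LV, 20 HV).
#' @param levels Named latent targets per label (default `LV = -1`,
#'   `HV = +1`).
#' @param wander_sd Within-trial random-walk standard deviation of the
#'   latent level, per 0.5 s bin (default 0.05); the walk restarts at the
#'   trial target at each trial onset.
#' @param envelope_gain Strictly increasing positive function mapping the
#'   latent level to an envelope amplitude (default `exp(0.5 * x)`).
#' @param line_noise_amp Amplitude of the 50 Hz interference (default 0.2;
#'   harmonics at 100/150 Hz are added at 30%/15% of it).
#' @param bin_len_s Latent bin length in seconds (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fs = 512,
                           trial_plan = tibble(
                             label = rep(c("LV", "HV"), 20), duration_s = 60
                           ),
                           levels = c(LV = -1, HV = 1), wander_sd = 0.05,
                           envelope_gain = function(x) exp(0.5 * x),
                           line_noise_amp = 0.2, bin_len_s = 0.5, seed = 1) {
  if (fs <= 500) abort("fs must exceed 500 Hz", class = "valenceloop_unrepresentable_band")
  stopifnot(all(trial_plan$duration_s > 0),
            all(trial_plan$label %in% names(levels)))
  structure(
    list(fs = fs, trial_plan = as_tibble(trial_plan), levels = levels,
         wander_sd = wander_sd, envelope_gain = envelope_gain,
         line_noise_amp = line_noise_amp, bin_len_s = bin_len_s, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic zEMG recording with known ground truth
#'
#' The latent valence path is the per-trial target plus a within-trial
#' random walk at the bin rate. The emitted signal is band-limited Gaussian
#' noise (20--240 Hz) multiplied by the envelope gain of the latent path
#' (linearly interpolated to the sample rate), plus 50 Hz line interference
#' and weak harmonics.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `emg` (tibble `t_s, emg, trial, label`), `truth`
#'   (tibble `k, t_start_s, trial, label, x` at the bin rate) and `trials`
#'   (tibble `trial, label, start_index, end_index`, half-open sample
#'   intervals).
#' @examples
#' rec <- generate_recording(synthetic_spec(
#'   trial_plan = tibble::tibble(label = c("LV", "HV"), duration_s = 5),
#'   seed = 42
#' ))
#' @export
generate_recording <- function(spec) {
  fs <- spec$fs
  bins_per_trial <- as.integer(round(spec$trial_plan$duration_s / spec$bin_len_s))
  samples_per_bin <- as.integer(round(fs * spec$bin_len_s))
  run_seeded(spec$seed, function() {
    x <- unlist(lapply(seq_len(nrow(spec$trial_plan)), function(i) {
      nb <- bins_per_trial[i]
      spec$levels[[spec$trial_plan$label[i]]] +
        cumsum(c(0, rnorm(nb - 1, 0, spec$wander_sd)))
    }))
    K <- length(x)
    N <- K * samples_per_bin
    carrier <- rnorm(N)
    bpf <- signal::butter(3, c(20, 240) / (fs / 2), type = "pass")
    carrier <- signal::filtfilt(bpf, carrier)
    env_bin <- spec$envelope_gain(x)
    env <- stats::approx(
      x = (seq_len(K) - 0.5) * samples_per_bin,
      y = env_bin, xout = seq_len(N), rule = 2
    )$y
    t <- (seq_len(N) - 1) / fs
    line <- spec$line_noise_amp *
      (sin(2 * pi * 50 * t) + 0.3 * sin(2 * pi * 100 * t) +
         0.15 * sin(2 * pi * 150 * t))
    emg <- carrier * env + line
    trial_bin <- rep(seq_len(nrow(spec$trial_plan)), bins_per_trial)
    label_bin <- spec$trial_plan$label[trial_bin]
    trial_sample <- rep(trial_bin, each = samples_per_bin)
    ends <- cumsum(bins_per_trial) * samples_per_bin
    list(
      emg = tibble(t_s = t, emg = emg, trial = trial_sample,
                   label = spec$trial_plan$label[trial_sample]),
      truth = tibble(k = seq_len(K), t_start_s = (seq_len(K) - 1) * spec$bin_len_s,
                     trial = trial_bin, label = label_bin, x = x),
      trials = tibble(trial = seq_len(nrow(spec$trial_plan)),
                      label = spec$trial_plan$label,
                      start_index = c(1L, head(ends, -1) + 1L),
                      end_index = ends)
    )
  })
}

#' Generate model-exact feature data for parameter-recovery experiments
#'
#' Simulates the state equation (with `u = 0`) and both observation
#' channels directly at the bin rate, bypassing the raw-EMG layer. The
#' stimulus sequence `s` is exogenous.
#'
#' @param params A [valence_params()] object.
#' @param s Stimulus sequence (scalar or length `K`).
#' @param K Number of bins.
#' @param seed Integer seed.
#' @return A tibble with columns `k, x, s, n, z` (`x` is the ground-truth
#'   latent state).
#' @export
generate_feature_data <- function(params, s = 0, K, seed = NULL) {
  sim <- simulate_valence(params, K = K, s = s, u = 0, seed = seed)
  sim[, c("k", "x", "s", "n", "z")]
}

#' Simulate a trial-structured session with a restoring environment
#'
#' Emulates an affect-elicitation session: `n_trials` trials of
#' `trial_len_s` seconds with alternating (or given) LV/HV labels. The
#' environmental stimulus pulls the latent state toward the active trial's
#' target level, `s[k] = kappa * (target[k] - x[k])`, mimicking how media
#' stimuli keep valence bounded near the elicited level; observations follow
#' the binary and continuous channels. This is the generator behind the EM
#' parameter-recovery experiments.
#'
#' @param params A [valence_params()] object.
#' @param n_trials Number of trials (default 40).
#' @param trial_len_s Trial length in seconds (default 60).
#' @param bin_len_s Bin length in seconds (default 0.5).
#' @param levels Named targets (default `LV = -0.25`, `HV = +0.25`; within
#'   the near-linear range of the logistic link so that the empirical
#'   spike-rate anchor for `gamma` is accurate).
#' @param kappa Restoring gain per bin (default 0.1).
#' @param labels Optional character vector of trial labels; defaults to
#'   alternating `LV`, `HV`.
#' @param seed Integer seed.
#' @return A tibble with columns `k, trial, label, target, x, s, n, z`.
#' @export
simulate_session <- function(params, n_trials = 40, trial_len_s = 60,
                             bin_len_s = 0.5, levels = c(LV = -0.25, HV = 0.25),
                             kappa = 0.1, labels = NULL, seed = NULL) {
  if (is.null(labels)) labels <- rep(c("LV", "HV"), length.out = n_trials)
  stopifnot(length(labels) == n_trials, all(labels %in% names(levels)))
  bins_per_trial <- as.integer(round(trial_len_s / bin_len_s))
  K <- n_trials * bins_per_trial
  trial <- rep(seq_len(n_trials), each = bins_per_trial)
  lab <- labels[trial]
  target <- unname(levels[lab])
  run_seeded(seed, function() {
    eps <- rnorm(K, 0, sqrt(params$sigma_eps2))
    omega <- rnorm(K, 0, sqrt(params$sigma_omega2))
    ub <- runif(K)
    x <- numeric(K); s <- numeric(K)
    x[1] <- params$x0
    for (k in seq_len(K)) {
      s[k] <- kappa * (target[k] - x[k])
      if (k < K) x[k + 1] <- x[k] + eps[k] + s[k]
    }
    p <- spike_prob(x, params$gamma)
    tibble(k = seq_len(K), trial = trial, label = lab, target = target,
           x = x, s = s, n = as.integer(ub < p),
           z = params$alpha + params$beta * x + omega)
  })
}
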