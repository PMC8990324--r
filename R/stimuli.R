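#' Derive an environmental-stimulus sequence from an estimated state
#'
#' The stimulus is the first difference of the (smoothed) state estimate:
#' `s[k] = x_sm[k + 1] - x_sm[k]`, so its cumulative sum plus the initial
#' state reconstructs the state exactly.
#'
#' @param state A data frame with a column `x_sm` (or `x`), or a numeric
#'   vector, of length at least 2.
#' @return A tibble with columns `k` and `s`, of length one less than the
#'   input.
#' @examples
#' derive_stimuli(c(1, 2, 4))
#' @export
derive_stimuli <- function(state) {
  x <- if (is.numeric(state)) {
    as.numeric(state)
  } else if ("x_sm" %in% names(state)) {
    state$x_sm
  } else if ("x" %in% names(state)) {
    state$x
  } else {
    abort("state must be numeric or contain an 'x_sm' (or 'x') column")
  }
  if (length(x) < 2) {
    abort("need at least 2 state values to difference",
          class = "valenceloop_too_short")
  }
  tibble(k = seq_len(length(x) - 1), s = diff(x))
}

#' Select representative high- and low-valence trials
#'
#' Ranks trials inside each label class by the sum of their rank by mean
#' state and rank by state standard deviation -- descending for HV (largest
#' mean and spread) and ascending for LV -- and returns the top six of each
#' class. Ties are broken by trial id.
#'
#' @param summaries A data frame with columns `trial_id`,
#'   `label` (`"HV"`/`"LV"`), `mean_state` and `sd_state`.
#' @param n_per_class Number of trials to keep per class (default 6).
#' @return A tibble of the selected trials with their combined rank
#'   (`rank_sum`), `n_per_class` rows per label.
#' @export
select_trials <- function(summaries, n_per_class = 6) {
  stopifnot(all(c("trial_id", "label", "mean_state", "sd_state") %in%
                  names(summaries)))
  out <- lapply(c("HV", "LV"), function(lab) {
    d <- summaries[summaries$label == lab, , drop = FALSE]
    if (nrow(d) < n_per_class) {
      abort(sprintf("fewer than %d %s trials available (%d)",
                    n_per_class, lab, nrow(d)),
            class = "valenceloop_insufficient_trials")
    }
    sgn <- if (lab == "HV") -1 else 1 # descending for HV, ascending for LV
    r <- rank(sgn * d$mean_state, ties.method = "average") +
      rank(sgn * d$sd_state, ties.method = "average")
    ord <- order(r, d$trial_id)
    d <- d[ord, , drop = FALSE]
    d$rank_sum <- r[ord]
    d[seq_len(n_per_class), , drop = FALSE]
  })
  as_tibble(dplyr::bind_rows(out))
}

#' Fit a truncated harmonic (sinusoidal) model to a stimulus sequence
#'
#' Takes the discrete Fourier transform of `s`, keeps the `n_components`
#' frequency bins of largest magnitude (excluding the zero-frequency term),
#' and converts each to an amplitude/frequency/phase triple so that
#' `sum(rho * sin(zeta * k + phi))` evaluated at `k = 0, ..., L - 1` is the
#' corresponding band-limited reconstruction of `s`.
#'
#' @param s Numeric stimulus sequence (length at least `2 * n_components`).
#' @param n_components Number of harmonics to keep (default 100).
#' @return A tibble with columns `j`, `rho` (amplitude, >= 0), `zeta`
#'   (angular frequency in radians per bin, >= 0) and `phi` (phase), ordered
#'   by decreasing magnitude, with the original length `L` stored in
#'   attribute `period`.
#' @examples
#' k <- 0:511
#' s <- 2 * sin(2 * pi * 5 * k / 512) + sin(2 * pi * 11 * k / 512 + 0.3)
#' h <- fit_harmonics(s, n_components = 10)
#' max(abs(synthesize_harmonics(h, k) - s)) < 1e-10
#' @export
fit_harmonics <- function(s, n_components = 100) {
  L <- length(s)
  if (L < 2 * n_components) {
    abort(sprintf("sequence of length %d cannot support %d harmonic components",
                  L, n_components),
          class = "valenceloop_too_short")
  }
  X <- fft(s)
  half <- 2:(floor(L / 2) + 1) # positive-frequency bins, DC excluded
  mag <- Mod(X[half])
  keep <- half[order(mag, decreasing = TRUE)][seq_len(n_components)]
  f <- keep - 1
  is_nyq <- (L %% 2 == 0) & (f == L / 2)
  scale <- ifelse(is_nyq, 1 / L, 2 / L)
  A <- scale * Re(X[keep]) # cosine coefficient
  B <- -scale * Im(X[keep]) # sine coefficient
  rho <- sqrt(A^2 + B^2)
  phi <- atan2(A, B) # A cos + B sin = rho * sin(theta + phi)
  structure(
    tibble(j = seq_len(n_components), rho = rho, zeta = 2 * pi * f / L,
           phi = phi, freq_bin = f),
    period = L
  )
}

#' Evaluate a harmonic model
#'
#' @param harmonics A tibble from [fit_harmonics()].
#' @param k Integer bin positions (0-based, matching the FFT convention used
#'   at fit time).
#' @return Numeric vector `sum_j rho_j * sin(zeta_j * k + phi_j)`.
#' @export
synthesize_harmonics <- function(harmonics, k) {
  if (nrow(harmonics) == 0) return(numeric(length(k)))
  drop(sin(outer(k, harmonics$zeta) +
             matrix(harmonics$phi, length(k), nrow(harmonics), byrow = TRUE)) %*%
         harmonics$rho)
}

#' Bundle the per-class harmonic stimulus models
#'
#' @param hv,lv Harmonic tibbles from [fit_harmonics()] for the high- and
#'   low-valence classes.
#' @param bin_len_s Bin length in seconds (default 0.5).
#' @param transition_s Duration of the linear transition ramp inserted
#'   between segments of different classes (default 0.5 s, i.e. one bin).
#' @return An object of class `stimulus_model`.
#' @export
stimulus_model <- function(hv, lv, bin_len_s = 0.5, transition_s = 0.5) {
  structure(list(hv = hv, lv = lv, bin_len_s = bin_len_s,
                 transition_s = transition_s),
            class = "stimulus_model")
}

#' @export
print.stimulus_model <- function(x, ...) {
  cat(sprintf("<stimulus_model> %d HV + %d LV harmonics, %g s bins, %g s ramps\n",
              nrow(x$hv), nrow(x$lv), x$bin_len_s, x$transition_s))
  invisible(x)
}

#' Synthesize a stimulus schedule from a fitted stimulus model
#'
#' Emits each segment's class harmonic sum on consecutive bins (the harmonic
#' phase restarts at the beginning of each segment), bridging each boundary
#' between different segments with a linear ramp of `transition_s` duration
#' blending the outgoing and incoming class signals.
#'
#' @param model A [stimulus_model()].
#' @param schedule A data frame with columns `label` (`"HV"`/`"LV"`) and
#'   `duration_s`; durations must be multiples of the model's bin length.
#' @return A tibble with columns `k`, `t_s`, `label` and `s`.
#' @export
synthesize_schedule <- function(model, schedule) {
  stopifnot(all(c("label", "duration_s") %in% names(schedule)))
  if (!all(schedule$label %in% c("HV", "LV"))) {
    abort("schedule labels must be 'HV' or 'LV'", class = "valenceloop_config_error")
  }
  nb <- schedule$duration_s / model$bin_len_s
  if (any(abs(nb - round(nb)) > 1e-9)) {
    abort("segment durations must be multiples of the bin length",
          class = "valenceloop_config_error")
  }
  nb <- as.integer(round(nb))
  w <- as.integer(round(model$transition_s / model$bin_len_s))
  segs <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    h <- if (schedule$label[i] == "HV") model$hv else model$lv
    kk <- seq_len(nb[i]) - 1
    s <- synthesize_harmonics(h, kk)
    if (i > 1 && schedule$label[i] != schedule$label[i - 1] && w > 0) {
      # blend the first w bins with the previous class continued past its end
      hp <- if (schedule$label[i - 1] == "HV") model$hv else model$lv
      prev_cont <- synthesize_harmonics(hp, nb[i - 1] + seq_len(w) - 1)
      lam <- seq_len(w) / (w + 1)
      idx <- seq_len(min(w, nb[i]))
      s[idx] <- (1 - lam[idx]) * prev_cont[idx] + lam[idx] * s[idx]
    }
    segs[[i]] <- tibble(label = schedule$label[i], s = s)
  }
  out <- dplyr::bind_rows(segs)
  out$k <- seq_len(nrow(out))
  out$t_s <- (out$k - 1) * model$bin_len_s
  out[, c("k", "t_s", "label", "s")]
}
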