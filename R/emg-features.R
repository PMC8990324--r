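#' Band-pass and notch filter a raw EMG recording
#'
#' Applies a third-order Butterworth band-pass (default 10--250 Hz) followed
#' by second-order IIR notch filters at the power-line frequency and its
#' harmonics (default 50, 100, 150, 200, 250 Hz, quality factor 30). All
#' filters are run zero-phase (forward--backward), so the effective
#' attenuation in dB is twice the single-pass design and the envelope is not
#' phase-distorted.
#'
#' @param data A data frame with a numeric column `emg`, or a numeric vector
#'   of raw samples.
#' @param fs Sampling rate in Hz. Must exceed twice the upper band edge
#'   (i.e. `fs > 500` for the default band).
#' @param band Length-2 numeric, pass-band edges in Hz.
#' @param notch_freqs Numeric vector of notch centre frequencies in Hz.
#' @param notch_q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @return A tibble with columns `t_s` (time of each sample in seconds) and
#'   `y` (the filtered signal), same length as the input.
#' @examples
#' x <- sin(2 * pi * 80 * seq(0, 1, by = 1 / 512))
#' filt <- bandpass_notch(tibble::tibble(emg = x), fs = 512)
#' @export
bandpass_notch <- function(data, fs, band = c(10, 250),
                           notch_freqs = c(50, 100, 150, 200, 250),
                           notch_q = 30) {
  x <- emg_samples(data)
  if (length(x) == 0) {
    abort("empty EMG input: no samples to filter", class = "valenceloop_empty_input")
  }
  if (!all(is.finite(x))) {
    abort("EMG samples must all be finite")
  }
  if (fs <= 2 * band[2]) {
    abort(
      sprintf(
        "sampling rate %g Hz cannot represent the %g-%g Hz band (need fs > %g Hz)",
        fs, band[1], band[2], 2 * band[2]
      ),
      class = "valenceloop_unrepresentable_band"
    )
  }
  bp <- signal::butter(3, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bp, x)
  for (f0 in notch_freqs) {
    nf <- iir_notch(f0, fs, notch_q)
    y <- signal::filtfilt(signal::Arma(b = nf$b, a = nf$a), y)
  }
  tibble(t_s = (seq_along(y) - 1) / fs, y = y)
}

# Second-order IIR notch (constrained pole-zero design): unit-circle zeros at
# +-f0, poles pulled inward by the quality factor.
iir_notch <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Frequency response of the preprocessing filter cascade
#'
#' Returns the effective (zero-phase, i.e. squared) magnitude response of the
#' band-pass + notch cascade used by [bandpass_notch()], evaluated at the
#' requested frequencies. Useful as an analytic check of attenuation
#' properties.
#'
#' @inheritParams bandpass_notch
#' @param freqs_hz Frequencies (Hz) at which to evaluate the response.
#' @return A tibble with columns `freq_hz`, `mag` (linear magnitude of the
#'   zero-phase cascade) and `mag_db`.
#' @export
filter_cascade_response <- function(freqs_hz, fs, band = c(10, 250),
                                    notch_freqs = c(50, 100, 150, 200, 250),
                                    notch_q = 30) {
  w <- 2 * pi * freqs_hz / fs
  bp <- signal::butter(3, band / (fs / 2), type = "pass")
  h <- freq_response(bp$b, bp$a, w)
  for (f0 in notch_freqs) {
    nf <- iir_notch(f0, fs, notch_q)
    h <- h * freq_response(nf$b, nf$a, w)
  }
  mag <- Mod(h)^2 # zero-phase application squares the magnitude
  tibble(freq_hz = freqs_hz, mag = mag, mag_db = 20 * log10(pmax(mag, 1e-300)))
}

freq_response <- function(b, a, w) {
  z <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- drop(z %*% b)
  z <- exp(-1i * outer(w, seq_along(a) - 1))
  den <- drop(z %*% a)
  num / den
}

#' Segment a filtered signal into non-overlapping bins
#'
#' @param filtered A tibble from [bandpass_notch()] (column `y`) or a numeric
#'   vector.
#' @param fs Sampling rate in Hz.
#' @param bin_len_s Bin length in seconds (default 0.5 s). A trailing partial
#'   bin is discarded.
#' @return A tibble with one row per bin: `k` (1-based bin index),
#'   `t_start_s` and a list-column `samples`.
#' @export
bin_signal <- function(filtered, fs, bin_len_s = 0.5) {
  y <- emg_samples(filtered, col = "y")
  if (bin_len_s <= 0) abort("bin_len_s must be positive")
  L <- round(fs * bin_len_s)
  if (length(y) < L) {
    abort(
      sprintf("signal (%d samples) is shorter than one %g s bin (%d samples)",
              length(y), bin_len_s, L),
      class = "valenceloop_too_short"
    )
  }
  K <- floor(length(y) / L)
  idx <- rep(seq_len(K), each = L)
  tibble(
    k = seq_len(K),
    t_start_s = (seq_len(K) - 1) * bin_len_s,
    samples = unname(split(y[seq_len(K * L)], idx))
  )
}

#' Extract the binary (spike) feature from a filtered EMG signal
#'
#' The filtered signal is rectified (absolute value), smoothed with a
#' Gaussian kernel, and normalized by its global maximum so the per-bin mean
#' amplitude lies in \[0, 1\]. The spike probability in bin `k` is
#' `q_k = a * y_k` (clipped to \[0, 1\]) and the binary feature is a
#' Bernoulli draw `n_k ~ Bern(q_k)`.
#'
#' @inheritParams bin_signal
#' @param a Scaling coefficient mapping normalized bin amplitude to spike
#'   probability (default 0.5).
#' @param kernel_sd_s Standard deviation of the Gaussian smoothing kernel in
#'   seconds (default 25 ms).
#' @param seed Optional integer seed for the Bernoulli draws.
#' @return A tibble with columns `k`, `y_bin` (normalized per-bin amplitude),
#'   `q` and `n`.
#' @export
extract_binary <- function(filtered, fs, bin_len_s = 0.5, a = 0.5,
                           kernel_sd_s = 0.025, seed = NULL) {
  if (a <= 0) abort("scaling coefficient a must be positive")
  y <- emg_samples(filtered, col = "y")
  sm <- gaussian_smooth(abs(y), sd_samples = kernel_sd_s * fs)
  m <- max(sm)
  if (m > 0) sm <- sm / m
  bins <- bin_signal(sm, fs, bin_len_s)
  y_bin <- purrr::map_dbl(bins$samples, mean)
  q <- pmin(1, pmax(0, a * y_bin))
  n <- run_seeded(seed, function() as.integer(runif(length(q)) < q))
  tibble(k = bins$k, y_bin = y_bin, q = q, n = n)
}

# Gaussian smoothing by direct convolution with reflected edges (zero padding
# beyond the first/last sample when the kernel radius exceeds the signal).
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  r <- ceiling(4 * sd_samples)
  kern <- exp(-0.5 * ((-r:r) / sd_samples)^2)
  kern <- kern / sum(kern)
  n <- length(x)
  re <- min(r, n - 1)
  left <- if (re > 0) x[(re + 1):2] else numeric(0)
  right <- if (re > 0) x[(n - 1):(n - re)] else numeric(0)
  pad <- c(rep(0, r - re), left, x, right, rep(0, r - re))
  out <- stats::convolve(pad, rev(kern), type = "open")
  out[(2 * r + 1):(2 * r + n)]
}

#' Extract the continuous (log-bandpower) feature
#'
#' For each non-overlapping bin, estimates the Welch power spectral density
#' (Hann windows of half the bin length, 75% overlap), integrates it over the
#' pass band, takes the natural log, and finally min--max normalizes the
#' per-bin values over the whole recording to \[0, 1\].
#'
#' @inheritParams extract_binary
#' @param band Integration band in Hz (default 10--250).
#' @return A tibble with columns `k`, `bandpower`, `log_power` and `z` (the
#'   normalized feature). If all bins have identical log power the normalized
#'   value is defined as 0.5.
#' @export
extract_continuous <- function(filtered, fs, bin_len_s = 0.5, band = c(10, 250)) {
  bins <- bin_signal(emg_samples(filtered, col = "y"), fs, bin_len_s)
  bp <- purrr::map_dbl(bins$samples, welch_bandpower, fs = fs, band = band)
  if (any(bp <= 0)) {
    warn("zero bandpower in at least one bin; flooring before log")
    bp <- pmax(bp, 1e-20)
  }
  lp <- log(bp)
  rng <- range(lp)
  z <- if (diff(rng) == 0) rep(0.5, length(lp)) else (lp - rng[1]) / diff(rng)
  tibble(k = bins$k, bandpower = bp, log_power = lp, z = z)
}

# Welch PSD bandpower: Hann-tapered overlapping segments, one-sided density
# scaling, trapezoidal integration over the requested band.
welch_bandpower <- function(x, fs, band, window_len = NULL, overlap = 0.75) {
  n <- length(x)
  if (is.null(window_len)) window_len <- max(8, floor(n / 2))
  window_len <- min(window_len, n)
  step <- max(1, round(window_len * (1 - overlap)))
  w <- signal::hanning(window_len)
  U <- sum(w^2)
  starts <- seq(1, n - window_len + 1, by = step)
  nf <- floor(window_len / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + window_len - 1)] * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * fs * U)
  # one-sided: double everything except DC (and Nyquist when window_len even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (window_len %% 2 == 0) dbl[nf] <- 1
  pxx <- pxx * dbl
  freq <- (seq_len(nf) - 1) * fs / window_len
  sel <- freq >= band[1] & freq <= band[2]
  if (sum(sel) < 2) return(sum(pxx[sel]) * fs / window_len)
  pracma::trapz(freq[sel], pxx[sel])
}

#' Full EMG front end: filter, bin, and extract both observation features
#'
#' Convenience wrapper chaining [bandpass_notch()], [extract_binary()] and
#' [extract_continuous()].
#'
#' @inheritParams bandpass_notch
#' @inheritParams extract_binary
#' @inheritParams extract_continuous
#' @return A tibble with columns `k`, `t_start_s`, `n`, `q`, `z`.
#' @examples
#' rec <- generate_recording(synthetic_spec(
#'   trial_plan = tibble::tibble(label = c("LV", "HV"), duration_s = 10),
#'   seed = 1
#' ))
#' feats <- extract_features(rec$emg, fs = 512, seed = 1)
#' @export
extract_features <- function(data, fs, bin_len_s = 0.5, a = 0.5,
                             kernel_sd_s = 0.025, band = c(10, 250),
                             notch_freqs = c(50, 100, 150, 200, 250),
                             notch_q = 30, seed = NULL) {
  filt <- bandpass_notch(data, fs, band = band, notch_freqs = notch_freqs,
                         notch_q = notch_q)
  bin_feat <- extract_binary(filt, fs, bin_len_s, a = a,
                             kernel_sd_s = kernel_sd_s, seed = seed)
  cont <- extract_continuous(filt, fs, bin_len_s, band = band)
  tibble(
    k = bin_feat$k,
    t_start_s = (bin_feat$k - 1) * bin_len_s,
    n = bin_feat$n,
    q = bin_feat$q,
    z = cont$z
  )
}

#' Read a raw EMG CSV/TSV file
#'
#' Expects a numeric column `emg` and optional `trial` / `label` columns.
#' The sampling rate is not inferred from the file and must be supplied by
#' the caller wherever the samples are used.
#'
#' @param path Path to a delimited text file.
#' @return A tibble.
#' @export
read_emg_csv <- function(path) {
  readr::read_delim(path, delim = guess_delim(path), show_col_types = FALSE)
}

guess_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

emg_samples <- function(data, col = "emg") {
  if (is.numeric(data)) return(as.numeric(data))
  if (is.data.frame(data)) {
    for (nm in unique(c(col, "emg", "y"))) {
      if (nm %in% names(data)) return(as.numeric(data[[nm]]))
    }
    abort(sprintf("data frame must contain a numeric '%s' column", col))
  }
  abort("expected a numeric vector or a data frame of samples")
}
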