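#' High-pass detrend a fluorescence trace
#'
#' Removes slow drift by subtracting a moving-average baseline whose
#' window is `1/cutoff_hz` seconds (a simple high-pass above ~`cutoff_hz`).
#' Edges use partial windows, so a constant trace maps to exactly zero.
#'
#' @param trace A [fluor_trace()].
#' @param cutoff_hz High-pass cutoff in Hz (default 0.1).
#' @return The detrended `fluor_trace`.
#' @export
detrend <- function(trace, cutoff_hz = 0.1) {
  rate <- trace_rate(trace)
  n <- nrow(trace)
  win <- max(3L, round(rate / cutoff_hz))
  if (n < 3 / cutoff_hz * rate / 10 || n <= 3L) {
    abort_invalid("trace too short to detrend at this cutoff")
  }
  half <- win %/% 2
  cs <- cumsum(c(0, trace$f))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  baseline <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  out <- trace
  out$f <- trace$f - baseline
  out
}

#' Z-normalize a trace on a baseline window
#'
#' Standardizes the trace using the mean and SD of the samples inside
#' `window` (default the 1-6 s interval at the start of the recording).
#' A zero-variance window is flagged degenerate: the output is all zeros
#' with attribute `degenerate = TRUE`, and a warning is raised.
#'
#' @param trace A [fluor_trace()].
#' @param window Length-2 numeric, window start/end in seconds.
#' @return The z-normalized `fluor_trace`.
#' @export
znorm <- function(trace, window = c(1, 6)) {
  if (window[1] >= window[2]) abort_invalid("`window` must be increasing.")
  if (max(trace$time_s) < window[2]) {
    abort_invalid("trace does not cover the z-normalization window.")
  }
  in_win <- trace$time_s >= window[1] & trace$time_s < window[2]
  mu <- mean(trace$f[in_win])
  s <- sd(trace$f[in_win])
  out <- trace
  if (!is.finite(s) || s == 0) {
    warn("zero variance in z-normalization window; trace flagged degenerate")
    out$f <- numeric(nrow(trace))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out$f <- (trace$f - mu) / s
  out
}

#' Resample the trace derivative onto the stimulus-alignment clock
#'
#' Takes the finite-difference time derivative of the trace and linearly
#' interpolates it onto a uniform `target_rate` clock (500 Hz, the LED
#' update rate), yielding `floor(duration * target_rate)` samples.
#'
#' @param trace A [fluor_trace()].
#' @param target_rate Alignment clock rate in Hz (default 500).
#' @return A tibble with columns `time_s`, `deriv` (input units per
#'   second), attribute `rate = target_rate`.
#' @export
resample_derivative <- function(trace, target_rate = 500) {
  rate <- trace_rate(trace)
  if (rate > target_rate) abort_invalid("trace rate exceeds the alignment rate.")
  n <- nrow(trace)
  d <- diff(trace$f) * rate
  t_mid <- (trace$time_s[-1] + trace$time_s[-n]) / 2
  dur <- n / rate
  t_out <- (seq_len(floor(dur * target_rate)) - 1) / target_rate
  deriv <- approx(t_mid, d, xout = t_out, rule = 2)$y
  out <- tibble::tibble(time_s = t_out, deriv = deriv)
  attr(out, "rate") <- target_rate
  out
}

#' Detect calcium events by derivative thresholding
#'
#' Every alignment-clock sample whose derivative exceeds
#' `threshold_sd` x SD(noise window) becomes one event, weighted by the
#' derivative value at that sample (the steepness of the transient).
#' The baseline noise SD is taken from the derivative inside
#' `noise_window` — the same 1-6 s interval used for z-normalization.
#'
#' @param deriv Output of [resample_derivative()].
#' @param threshold_sd Threshold in baseline-noise SDs (default 0.7).
#' @param noise_window Length-2 numeric window (seconds) defining
#'   baseline noise.
#' @return A tibble of class `event_series` with columns `time_s`,
#'   `weight` (strictly positive) and attribute `n_events`.
#' @export
detect_events <- function(deriv, threshold_sd = 0.7, noise_window = c(1, 6)) {
  in_win <- deriv$time_s >= noise_window[1] & deriv$time_s < noise_window[2]
  if (!any(in_win)) abort_invalid("noise window contains no samples.")
  noise_sd <- sd(deriv$deriv[in_win])
  thr <- threshold_sd * noise_sd
  keep <- is.finite(deriv$deriv) & deriv$deriv > thr & deriv$deriv > 0
  out <- tibble::tibble(time_s = deriv$time_s[keep], weight = deriv$deriv[keep])
  attr(out, "n_events") <- nrow(out)
  attr(out, "threshold") <- thr
  class(out) <- c("event_series", class(out))
  out
}
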