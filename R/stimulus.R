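#' Tetrachromatic binary noise stimulus
#'
#' Generates the full-field "natural spectrum" white-noise stimulus: four
#' LED channels (red, green, blue, UV) flickered independently in a random
#' binary sequence. The default timing — 6.4 Hz frame rate for 258 s —
#' yields 1651 frames. Channel photon weights (red 100%, green 50%,
#' blue 13%, UV 6%) are carried as metadata; reverse correlation operates
#' on the raw binary sequence itself.
#'
#' @param duration_s Stimulus duration in seconds.
#' @param frame_rate Update rate in Hz. The fractional trailing frame is
#'   dropped, so the frame count is `floor(duration_s * frame_rate)`.
#' @param weights Named 4-vector of relative photon weights per channel.
#' @param seed Integer seed; the same seed reproduces the same sequence.
#'
#' @return A tibble of class `noise_stimulus` with columns `frame`,
#'   `time_s` (frame onset) and one 0/1 column per channel (`R`, `G`, `B`,
#'   `UV`), with `frame_rate` and `channel_weights` attributes.
#' @export
#' @examples
#' stim <- noise_stimulus(duration_s = 10, seed = 1)
#' colMeans(stim_matrix(stim))
noise_stimulus <- function(duration_s = 258, frame_rate = 6.4,
                           weights = natural_white_weights(), seed = 1L) {
  check_positive_scalar(duration_s, "duration_s")
  check_positive_scalar(frame_rate, "frame_rate")
  if (length(weights) != 4L || any(!is.finite(weights)) || any(weights <= 0)) {
    abort_invalid("`weights` must be 4 positive finite values.")
  }
  n_frames <- floor(duration_s * frame_rate)
  if (n_frames < 1L) abort_invalid("stimulus would contain no frames")
  values <- withr::with_seed(seed, {
    matrix(rbinom(n_frames * 4L, 1L, 0.5), ncol = 4L)
  })
  colnames(values) <- channel_order()
  out <- tibble::tibble(
    frame = seq_len(n_frames),
    time_s = (seq_len(n_frames) - 1) / frame_rate
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  attr(out, "frame_rate") <- frame_rate
  attr(out, "channel_weights") <- setNames(as.numeric(weights), channel_order())
  class(out) <- c("noise_stimulus", class(out))
  out
}

#' Extract the frames-by-channels binary matrix of a stimulus
#'
#' @param stim A `noise_stimulus`.
#' @return Integer matrix, frames x 4, columns in channel order.
#' @export
stim_matrix <- function(stim) {
  as.matrix(stim[, channel_order()])
}

#' Stimulus frame rate
#' @param stim A `noise_stimulus`.
#' @return Frame rate in Hz.
#' @export
stim_frame_rate <- function(stim) attr(stim, "frame_rate")

#' Stimulus value at arbitrary times (zero-order hold)
#'
#' LED state persists between frame updates, so the stimulus at time `t`
#' is the value of the frame active at `t`. Times outside the stimulus
#' span return `NA`.
#'
#' @param stim A `noise_stimulus`.
#' @param times Numeric vector of query times in seconds.
#' @return Numeric matrix `length(times)` x 4.
#' @export
stim_at <- function(stim, times) {
  fr <- stim_frame_rate(stim)
  values <- stim_matrix(stim)
  idx <- floor(times * fr) + 1
  idx[times < 0 | idx > nrow(values)] <- NA_integer_
  out <- values[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Achromatic chirp stimulus waveform
#'
#' A deterministic single-channel luminance waveform in which all four
#' LEDs are driven together: baseline, a light step, an accelerating
#' frequency sweep, and an amplitude (contrast) sweep at fixed frequency,
#' padded with baseline to the canonical 2,499-sample window at 1 kHz.
#' The exact segment durations are configurable stand-ins; downstream
#' code depends only on the 2,499-sample response window, never on the
#' waveform's shape.
#'
#' @param baseline_s,step_s,freq_sweep_s,contrast_sweep_s Segment durations
#'   in seconds (defaults 0.3, 0.5, 1.0, 0.5).
#' @param f0_hz,f1_hz Frequency sweep range in Hz (linear in frequency).
#' @param contrast_hz Frequency of the contrast sweep in Hz.
#' @param contrast Peak contrast in `[0, 1]`; 0 gives a constant waveform.
#' @param total_ms Total length in milliseconds (default 2499).
#'
#' @return A tibble with columns `time_s` and `value` (luminance in
#'   `[0, 1]`), `total_ms` rows at 1 kHz.
#' @export
chirp_stimulus <- function(baseline_s = 0.3, step_s = 0.5, freq_sweep_s = 1.0,
                           contrast_sweep_s = 0.5, f0_hz = 0.5, f1_hz = 8,
                           contrast_hz = 2, contrast = 1, total_ms = 2499L) {
  dt <- 1e-3
  seg <- function(n, v) rep_len(v, n)
  n_base <- round(baseline_s / dt)
  n_step <- round(step_s / dt)
  n_freq <- round(freq_sweep_s / dt)
  n_con <- round(contrast_sweep_s / dt)
  t_freq <- seq_len(n_freq) * dt
  # linear frequency ramp: phase = 2*pi*(f0*t + (f1-f0)*t^2/(2*T))
  phase <- 2 * pi * (f0_hz * t_freq + (f1_hz - f0_hz) * t_freq^2 / (2 * freq_sweep_s))
  t_con <- seq_len(n_con) * dt
  wave <- c(
    seg(n_base, 0.5),
    seg(n_step, 0.5 + 0.5 * contrast),
    0.5 + 0.5 * contrast * sin(phase),
    0.5 + 0.5 * contrast * (t_con / contrast_sweep_s) * sin(2 * pi * contrast_hz * t_con)
  )
  if (length(wave) >= total_ms) {
    wave <- wave[seq_len(total_ms)]
  } else {
    wave <- c(wave, seg(total_ms - length(wave), 0.5))
  }
  tibble::tibble(time_s = (seq_len(total_ms) - 1) * dt, value = wave)
}
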