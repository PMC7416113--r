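#' Event-triggered average stimulus (raw spectral kernels)
#'
#' Computes, for each LED channel l and lag tau on the canonical grid,
#'
#'   F(l, tau) = (1/M) * sum_i  w_i * S(l, t_i + tau)
#'
#' where t_i are the calcium event times, w_i the event weights (trace
#' derivative at the event), and S the binary stimulus sampled with
#' zero-order hold (the LED state persists between frame updates).
#' Events whose full lag window leaves the stimulus span are dropped and
#' M decremented, which avoids biased edges.
#'
#' @param events An [detect_events()] `event_series`.
#' @param stim A [noise_stimulus()].
#' @param lags Lag grid in seconds (default [lag_grid()]).
#' @return A list of class `raw_kernel_set`: `kernels` (649 x 4 matrix),
#'   `lag_s`, `n_events` (M after edge dropping).
#' @export
triggered_average <- function(events, stim, lags = lag_grid()) {
  fr <- stim_frame_rate(stim)
  dur <- nrow(stim) / fr
  keep <- events$time_s + lags[1] >= 0 &
    events$time_s + lags[length(lags)] < dur
  times <- events$time_s[keep]
  w <- events$weight[keep]
  m <- length(times)
  if (m == 0L) {
    abort("no usable calcium events: ROI is non-responsive",
          class = "chromarg_no_events")
  }
  values <- stim_matrix(stim)
  clock <- 500
  m_idx <- times * clock
  on_clock <- all(abs(m_idx - round(m_idx)) < 1e-9)
  o <- lags * clock
  uniform_frac <- diff(range(o - floor(o))) < 1e-9
  if (on_clock && uniform_frac && m > 200L) {
    # event times sit on the 500 Hz alignment clock and all lags share
    # one fractional sample offset, so the sum is an exact correlation
    # of a dense weight series with the clock-sampled stimulus
    n500 <- floor(dur * clock)
    wd <- numeric(n500)
    pos <- round(m_idx) + 1L
    for (i in seq_len(m)) wd[pos[i]] <- wd[pos[i]] + w[i]
    frac <- o[1] - floor(o[1])
    t_shift <- (seq_len(n500) - 1 + frac) / clock
    sv <- stim_at(stim, t_shift)
    sv[is.na(sv)] <- 0
    o_min <- floor(o[1])
    kernels <- vapply(1:4, function(ch) {
      lagged_inner_sum(sv[, ch], wd, o_min)[seq_along(lags)] / m
    }, numeric(length(lags)))
  } else {
    # direct sum: M x n_lags stimulus frame lookup at t_i + tau
    idx <- floor(outer(times, lags, `+`) * fr) + 1
    idx <- pmin(pmax(idx, 1L), nrow(values))
    kernels <- vapply(1:4, function(ch) {
      s <- matrix(values[idx, ch], nrow = m)
      as.numeric(crossprod(w, s)) / m
    }, numeric(length(lags)))
  }
  colnames(kernels) <- channel_order()
  structure(list(kernels = kernels, lag_s = lags, n_events = m),
            class = "raw_kernel_set")
}

#' Baseline-normalize a raw kernel set
#'
#' Converts each channel to z-scores of its own baseline: the mean and SD
#' of the first 50 ms of the lag axis (the 25 earliest samples) are
#' subtracted/divided out. Two quality measures are attached per channel:
#' `quality` — the peak-to-peak amplitude of the normalized kernel in
#' baseline SDs (the 10-SD responsiveness gate operates on this) — and
#' `quality_sd`, the standard deviation of the normalized kernel over the
#' whole lag axis (the clustering QC gate at 5 operates on its maximum
#' across channels). A zero-variance baseline flags the channel
#' degenerate: the channel is zeroed and both qualities set to 0.
#'
#' @param raw A `raw_kernel_set` from [triggered_average()].
#' @param baseline_n Number of earliest lag samples forming the baseline
#'   (default 25, i.e. 50 ms at dt = 2 ms).
#' @return A list of class `kernel_set`: `kernels` (normalized, 649 x 4),
#'   `lag_s`, `quality`, `quality_sd`, `polarity` (via
#'   [classify_polarity()]; `NA` for degenerate channels), `n_events`.
#' @export
normalize_kernels <- function(raw, baseline_n = 25L) {
  k <- raw$kernels
  quality <- numeric(4)
  quality_sd <- numeric(4)
  polarity <- rep(NA_character_, 4)
  for (ch in 1:4) {
    base <- k[seq_len(baseline_n), ch]
    s <- sd(base)
    if (!is.finite(s) || s == 0) {
      k[, ch] <- 0
      next
    }
    k[, ch] <- (k[, ch] - mean(base)) / s
    quality[ch] <- max(k[, ch]) - min(k[, ch])
    quality_sd[ch] <- sd(k[, ch])
    polarity[ch] <- tryCatch(classify_polarity(k[, ch]),
                             chromarg_degenerate = function(e) NA_character_)
  }
  names(quality) <- names(quality_sd) <- names(polarity) <- channel_order()
  structure(
    list(kernels = k, lag_s = raw$lag_s, quality = quality,
         quality_sd = quality_sd, polarity = polarity,
         n_events = raw$n_events),
    class = "kernel_set"
  )
}

#' Estimate spectral kernels for one trace
#'
#' The full per-ROI chain: detrend, z-normalize on the 1-6 s window,
#' resample the derivative to the 500 Hz alignment clock, threshold at
#' `threshold_sd` baseline SDs, event-triggered average against the
#' stimulus, and baseline-normalize. A degenerate or event-free trace
#' yields a `kernel_set` of zeros with zero quality rather than an error.
#'
#' @param trace A [fluor_trace()].
#' @param stim A [noise_stimulus()].
#' @param threshold_sd Event threshold in baseline SDs (default 0.7).
#' @param window Baseline window in seconds for z-normalization and
#'   derivative noise (default `c(1, 6)`).
#' @return A `kernel_set` (see [normalize_kernels()]).
#' @export
estimate_kernels <- function(trace, stim, threshold_sd = 0.7, window = c(1, 6)) {
  empty <- function() {
    z <- matrix(0, 649, 4, dimnames = list(NULL, channel_order()))
    structure(list(kernels = z, lag_s = lag_grid(),
                   quality = setNames(numeric(4), channel_order()),
                   quality_sd = setNames(numeric(4), channel_order()),
                   polarity = setNames(rep(NA_character_, 4), channel_order()),
                   n_events = 0L),
              class = "kernel_set")
  }
  pre <- withCallingHandlers(
    znorm(detrend(trace), window = window),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (isTRUE(attr(pre, "degenerate"))) return(empty())
  deriv <- resample_derivative(pre)
  events <- detect_events(deriv, threshold_sd = threshold_sd,
                          noise_window = window)
  raw <- tryCatch(triggered_average(events, stim),
                  chromarg_no_events = function(e) NULL)
  if (is.null(raw)) return(empty())
  normalize_kernels(raw)
}

#' Estimate kernels for every ROI of a population
#'
#' @param rois A population tibble with a `trace` list-column (see
#'   [make_population()]), or any tibble of `fluor_trace`s.
#' @param stim The shared [noise_stimulus()].
#' @param ... Passed to [estimate_kernels()].
#' @return The input tibble without its `trace` column, plus a
#'   `kernel_set` list-column and per-ROI `quality` (max peak-to-peak
#'   across channels), `quality_sd_max` (max kernel SD across channels,
#'   the clustering QC statistic) and `n_events` columns.
#' @export
estimate_population_kernels <- function(rois, stim, ...) {
  ks <- purrr::map(rois$trace, estimate_kernels, stim = stim, ...)
  out <- dplyr::select(rois, -"trace")
  out$kernel_set <- ks
  out$quality <- purrr::map_dbl(ks, ~ max(.x$quality))
  out$quality_sd_max <- purrr::map_dbl(ks, ~ max(.x$quality_sd))
  out$n_events <- purrr::map_int(ks, ~ as.integer(.x$n_events))
  out
}

#' Average chirp trials into the canonical response window
#'
#' Upsamples each trial to 1 kHz by linear interpolation, takes the
#' pointwise mean across trials, and crops or baseline-pads to exactly
#' 2,499 samples.
#'
#' @param trials A list of `fluor_trace`s (or numeric vectors with
#'   `rate`), each one trial of the chirp response.
#' @param rate Sampling rate of plain-vector trials, in Hz.
#' @param n_out Output length (default 2499 samples at 1 kHz).
#' @return A tibble of class `chirp_response` with columns `time_s`,
#'   `mean_f`, attribute `n_trials`.
#' @export
average_chirp <- function(trials, rate = NULL, n_out = 2499L) {
  if (length(trials) < 1L) abort_invalid("need at least one trial.")
  t_out <- (seq_len(n_out) - 1) * 1e-3
  up <- purrr::map(trials, function(tr) {
    if (is.numeric(tr)) {
      if (is.null(rate)) abort_invalid("plain-vector trials need `rate`.")
      tr <- fluor_trace(tr, rate)
    }
    approx(tr$time_s, tr$f, xout = t_out, rule = 2)$y
  })
  m <- rowMeans(do.call(cbind, up))
  out <- tibble::tibble(time_s = t_out, mean_f = m)
  attr(out, "n_trials") <- length(trials)
  class(out) <- c("chirp_response", class(out))
  out
}
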